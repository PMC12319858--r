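#' TCM algorithm configuration
#'
#' Bundles all tunable parameters of the temporal coherence mapping
#' algorithm. The defaults (`w = 30`, `r = 0.3`, `g = 1`,
#' `dia_s = floor(w/3)`, `dia_e = w`) are the configuration the method's
#' reference results were computed with for 1200-timepoint resting-state
#' fMRI series.
#'
#' @param w Embedding vector length in samples. Each embedding vector is a
#'   window of `w` consecutive samples; `w` controls how much of the local
#'   signal shape one "transit state" captures. Must be at least 2.
#' @param r Correlation threshold in (0, 1) used to binarize the TCM matrix
#'   for the diagonal-line metrics MLP and MLN. Entries with `cc > r` form
#'   the positive binary matrix, entries with `cc < -r` the negative one
#'   (both strict; `cc` exactly equal to the threshold is 0 in both).
#' @param g Gap: integer stride, in samples, between the start points of
#'   adjacent embedding vectors, and equally the stride between evaluated
#'   diagonals. `g = 1` uses every window.
#' @param dia_s First diagonal (in vector-index units) included in the
#'   metric sums; diagonals closer to the main diagonal are excluded
#'   because near-zero delays carry trivially high correlations (in fMRI,
#'   from hemodynamic smoothing). Default `floor(w/3)`, within the
#'   empirically supported band `[w/4, w/2]`. The main diagonal itself is
#'   never included.
#' @param dia_e Number of trailing (longest-delay) diagonals excluded;
#'   those diagonals hold too few pairs to support stable line-segment
#'   statistics. Default `w`.
#' @param corr_kind `"pearson"` (default) or `"spearman"`. Spearman
#'   correlates within-window ranks (average ranks on ties) and is robust
#'   to slow monotone baseline drift at extra ranking cost.
#' @param convention `"algorithm"` (default) normalizes TC/TAC by
#'   `Totnum_cc = nv(nv-1)/2 - dia_e(dia_e+1)/2` over the included
#'   diagonals, the convention the reference implementation uses.
#'   `"text"` selects a compatibility variant for TC/TAC only: all
#'   off-diagonal pairs (both triangles, no diagonal exclusion) divided by
#'   `M = (N-w+1)(N-w)`; MLP/MLN always follow the algorithm convention.
#'
#' @return An object of class `tcm_config` (a validated list).
#' @examples
#' cfg <- tcm_config()
#' cfg
#' tcm_config(w = 20, r = 0.5)
#' @export
tcm_config <- function(w = 30, r = 0.3, g = 1,
                       dia_s = floor(w / 3), dia_e = w,
                       corr_kind = c("pearson", "spearman"),
                       convention = c("algorithm", "text")) {
  corr_kind <- match.arg(corr_kind)
  convention <- match.arg(convention)
  w <- as.integer(w); g <- as.integer(g)
  dia_s <- as.integer(dia_s); dia_e <- as.integer(dia_e)
  if (is.na(w) || w < 2L) stop("`w` must be an integer >= 2", call. = FALSE)
  if (is.na(g) || g < 1L) stop("`g` must be an integer >= 1", call. = FALSE)
  if (!is.finite(r) || r <= 0 || r >= 1)
    stop("`r` must lie strictly between 0 and 1", call. = FALSE)
  if (is.na(dia_s) || dia_s < 0L) stop("`dia_s` must be >= 0", call. = FALSE)
  if (is.na(dia_e) || dia_e < 0L) stop("`dia_e` must be >= 0", call. = FALSE)
  structure(list(w = w, r = r, g = g, dia_s = dia_s, dia_e = dia_e,
                 corr_kind = corr_kind, convention = convention),
            class = "tcm_config")
}

#' @export
print.tcm_config <- function(x, ...) {
  cat(sprintf(
    "TCM configuration: w=%d, r=%g, gap=%d, dia_s=%d, dia_e=%d, %s correlation (%s convention)\n",
    x$w, x$r, x$g, x$dia_s, x$dia_e, x$corr_kind, x$convention))
  invisible(x)
}

check_series <- function(x, arg = "x") {
  if (!is.numeric(x)) stop("`", arg, "` must be a numeric vector", call. = FALSE)
  if (length(x) < 2L) stop("`", arg, "` must have at least 2 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("`", arg, "` contains non-finite values", call. = FALSE)
  invisible(as.numeric(x))
}

#' Extract temporal-embedding vectors from a time series
#'
#' Expands a one-dimensional series `x` of length `N` into its set of
#' embedding vectors: windows of `w` consecutive samples whose start
#' points advance in steps of `g`. Vector `i` (1-based) covers samples
#' `(i-1)*g + 1` through `(i-1)*g + w`, and the number of vectors is
#' `nv = floor((N - w + 1) / g)`.
#'
#' @param x Numeric time series.
#' @param w Embedding vector length in samples.
#' @param g Gap between adjacent vector start points, in samples.
#' @return An `nv x w` numeric matrix, one embedding vector per row, with
#'   attributes `w`, `g`, and `n` (the source length).
#' @examples
#' e <- extract_embeddings(sin(1:100), w = 30, g = 3)
#' nrow(e)  # 23
#' @export
extract_embeddings <- function(x, w, g = 1L) {
  x <- check_series(x)
  w <- as.integer(w); g <- as.integer(g)
  n <- length(x)
  if (w < 2L) stop("`w` must be >= 2", call. = FALSE)
  if (w >= n) stop("series too short: need N > w (N=", n, ", w=", w, ")",
                   call. = FALSE)
  nv <- (n - w + 1L) %/% g
  if (nv < 2L)
    stop("series too short for two embedding vectors with w=", w, ", g=", g,
         call. = FALSE)
  starts <- (seq_len(nv) - 1L) * g
  e <- matrix(x[rep(starts, each = w) + seq_len(w)], nrow = nv, ncol = w,
              byrow = TRUE)
  structure(e, w = w, g = g, n = n)
}

#' Correlation between two embedding vectors
#'
#' Pearson or Spearman correlation of two equal-length vectors. Spearman
#' is Pearson on within-vector ranks with average ranks on ties. If
#' either vector has zero variance the correlation is undefined and
#' `NaN` is returned as a sentinel; downstream metric computations treat
#' such pairs as contributing zero while remaining in the denominator.
#'
#' @param u,v Numeric vectors of equal length.
#' @param corr_kind `"pearson"` or `"spearman"`.
#' @return A number in `[-1, 1]`, or `NaN` if undefined.
#' @examples
#' embedding_corr(c(1, 2, 3), c(1, 3, 2))  # 0.5
#' @export
embedding_corr <- function(u, v, corr_kind = c("pearson", "spearman")) {
  corr_kind <- match.arg(corr_kind)
  if (length(u) != length(v)) stop("vectors must have equal length", call. = FALSE)
  if (corr_kind == "spearman") { u <- rank(u); v <- rank(v) }
  if (stats::var(u) == 0 || stats::var(v) == 0) return(NaN)
  min(1, max(-1, stats::cor(u, v)))
}

#' Full TCM matrix (reference path)
#'
#' Materializes the complete symmetric `nv x nv` matrix of correlations
#' between all pairs of embedding vectors. Memory grows as `nv^2`, so this
#' path exists for inspection, plotting and verification on small inputs;
#' [tcm_metrics()] computes the same metrics diagonal-by-diagonal without
#' ever building this matrix.
#'
#' @param x Numeric time series.
#' @param cfg A [tcm_config()].
#' @return A symmetric matrix of class `tcm_matrix` with unit main
#'   diagonal, `NaN` sentinels where a correlation is undefined, and the
#'   config and source length stored as attributes.
#' @examples
#' m <- tcm_matrix_full(sin(2 * pi * (0:99) / 10), tcm_config(w = 10))
#' dim(m)
#' @export
tcm_matrix_full <- function(x, cfg = tcm_config()) {
  stopifnot(inherits(cfg, "tcm_config"))
  e <- extract_embeddings(x, cfg$w, cfg$g)
  nv <- nrow(e)
  method <- cfg$corr_kind
  suppressWarnings(m <- stats::cor(t(e), method = method))
  # zero-variance vectors yield NA from cor(); keep NaN as the sentinel
  m[is.na(m)] <- NaN
  m[!is.nan(m)] <- pmin(1, pmax(-1, m[!is.nan(m)]))
  ok <- apply(e, 1L, stats::var) > 0
  diag(m)[ok] <- 1
  structure(m, class = c("tcm_matrix", class(m)), config = cfg,
            n = length(x), nv = nv)
}

#' Maximal runs along a binarized diagonal
#'
#' Finds maximal runs of 1s of length at least 2 in a binary sequence
#' taken from one diagonal of the thresholded TCM matrix. Isolated single
#' 1s denote transit states that do not persist and are dropped; a run
#' still open at the end of the diagonal is closed there.
#'
#' @param bits Logical or 0/1 vector.
#' @return A data frame with columns `start`, `end` (inclusive, 1-based)
#'   and `length`, one row per retained segment, in order.
#' @examples
#' diagonal_runs(c(1, 1, 1, 0, 1, 0, 0))  # one segment of length 3
#' @export
diagonal_runs <- function(bits) {
  bits <- as.logical(bits)
  if (anyNA(bits)) bits[is.na(bits)] <- FALSE
  r <- rle(bits)
  ends <- cumsum(r$lengths)
  keep <- r$values & r$lengths >= 2L
  data.frame(start = (ends - r$lengths + 1L)[keep],
             end = ends[keep],
             length = r$lengths[keep])
}

# Shared bookkeeping: which diagonals (vector-index delay d) enter the
# metric sums, and the normalization constants.
included_diagonals <- function(nv, cfg) {
  d_lo <- max(cfg$dia_s, 1L)
  d_hi <- nv - cfg$dia_e          # exclusive
  if (d_hi <= d_lo)
    stop("no diagonals left after exclusion: nv=", nv, ", dia_s=", cfg$dia_s,
         ", dia_e=", cfg$dia_e,
         " (need dia_s < nv - dia_e); shorten w or reduce the exclusions",
         call. = FALSE)
  seq.int(d_lo, d_hi - 1L)
}

totnum_cc <- function(nv, dia_e) nv * (nv - 1) / 2 - dia_e * (dia_e + 1) / 2

# Assemble a tcm_metrics object from raw sums/counts.
build_metrics <- function(raw, cfg, n) {
  nv <- raw$nv
  tot <- totnum_cc(nv, cfg$dia_e)
  m_text <- (n - cfg$w + 1) * (n - cfg$w)
  tc_alg <- raw$sum_pos / tot
  tac_alg <- raw$sum_neg / tot
  # text variant: all off-diagonal ordered pairs = 2 * upper triangle
  tc_text <- 2 * raw$sum_pos_all / m_text
  tac_text <- 2 * raw$sum_neg_all / m_text
  if (cfg$convention == "text") { tc <- tc_text; tac <- tac_text }
  else { tc <- tc_alg; tac <- tac_alg }
  mlp <- raw$mlp_total / tot
  mln <- raw$mln_total / tot
  out <- list(
    tc = tc, tac = tac, cab1 = tc - tac,
    mlp = mlp, mln = mln, cab2 = mlp - mln,
    totnum_cc = tot, n_pairs = raw$n_pairs, m_text = m_text,
    n_pos = raw$n_pos, n_neg = raw$n_neg, n_undefined = raw$n_undefined,
    nv = nv, n = n,
    tc_algorithm = tc_alg, tac_algorithm = tac_alg,
    tc_text = tc_text, tac_text = tac_text,
    mean_seg_len_pos = if (raw$n_seg_pos > 0) raw$mlp_total / raw$n_seg_pos else 0,
    mean_seg_len_neg = if (raw$n_seg_neg > 0) raw$mln_total / raw$n_seg_neg else 0,
    n_seg_pos = raw$n_seg_pos, n_seg_neg = raw$n_seg_neg,
    config = cfg)
  if (raw$n_undefined > 0)
    warning(raw$n_undefined, " of ", raw$n_pairs,
            " embedding-vector pairs had undefined correlation ",
            "(zero-variance window); they contribute 0 and stay in the denominator",
            call. = FALSE)
  structure(out, class = "tcm_metrics")
}

#' @export
print.tcm_metrics <- function(x, digits = 4, ...) {
  cat("TCM metrics (N =", x$n, ", nv =", x$nv, "embedding vectors)\n")
  cat(sprintf("  TC   = %.*f   TAC  = %.*f   CAB1 = %+.*f\n",
              digits, x$tc, digits, x$tac, digits, x$cab1))
  cat(sprintf("  MLP  = %.*f   MLN  = %.*f   CAB2 = %+.*f\n",
              digits, x$mlp, digits, x$mln, digits, x$cab2))
  cat(sprintf("  pairs evaluated %d / Totnum_cc %d; %d positive, %d negative\n",
              as.integer(x$n_pairs), as.integer(x$totnum_cc),
              as.integer(x$n_pos), as.integer(x$n_neg)))
  invisible(x)
}

#' @export
as.data.frame.tcm_metrics <- function(x, ...) {
  data.frame(tc = x$tc, tac = x$tac, cab1 = x$cab1,
             mlp = x$mlp, mln = x$mln, cab2 = x$cab2,
             totnum_cc = x$totnum_cc, n_pairs = x$n_pairs,
             n_pos = x$n_pos, n_neg = x$n_neg,
             n_undefined = x$n_undefined, nv = x$nv, n = x$n)
}

#' Six TCM metrics from a precomputed full matrix
#'
#' Computes TC, TAC, CAB1, MLP, MLN and CAB2 from an explicit
#' [tcm_matrix_full()] result. TC is the mean positive correlation and
#' TAC the mean magnitude of negative correlation over the included
#' upper-triangle diagonals, both normalized by
#' `Totnum_cc = nv(nv-1)/2 - dia_e(dia_e+1)/2`; CAB1 = TC - TAC. MLP and
#' MLN binarize the included entries at `cc > r` and `cc < -r`, sum the
#' lengths of maximal diagonal runs of at least 2, normalize by
#' `Totnum_cc`; CAB2 = MLP - MLN. `NaN` sentinel entries contribute 0 and
#' remain in the denominator.
#'
#' @param mat A `tcm_matrix` from [tcm_matrix_full()].
#' @param cfg A [tcm_config()]; defaults to the one stored in `mat`.
#' @return A `tcm_metrics` object; see [tcm_metrics()] for fields.
#' @examples
#' x <- as.numeric(1:50)
#' m <- tcm_matrix_full(x, tcm_config(w = 10, dia_s = 0, dia_e = 0))
#' tcm_metrics_from_matrix(m)$tc  # ramp: all correlations are +1
#' @export
tcm_metrics_from_matrix <- function(mat, cfg = attr(mat, "config")) {
  stopifnot(inherits(mat, "tcm_matrix"), inherits(cfg, "tcm_config"))
  nv <- attr(mat, "nv")
  n <- attr(mat, "n")
  dd <- included_diagonals(nv, cfg)
  sum_pos <- sum_neg <- mlp_total <- mln_total <- 0
  n_pos <- n_neg <- n_undef <- n_pairs <- 0
  n_seg_pos <- n_seg_neg <- 0
  sum_pos_all <- sum_neg_all <- 0
  for (d in seq_len(nv - 1L)) {
    i <- seq_len(nv - d)
    cc <- mat[cbind(i, i + d)]
    und <- is.nan(cc)
    cc[und] <- 0
    sum_pos_all <- sum_pos_all + sum(cc[cc > 0])
    sum_neg_all <- sum_neg_all + sum(-cc[cc < 0])
    if (!(d %in% dd)) next
    n_pairs <- n_pairs + length(cc)
    n_undef <- n_undef + sum(und)
    n_pos <- n_pos + sum(cc > 0)
    n_neg <- n_neg + sum(cc < 0)
    sum_pos <- sum_pos + sum(cc[cc > 0])
    sum_neg <- sum_neg + sum(-cc[cc < 0])
    rp <- diagonal_runs(cc > cfg$r)
    rn <- diagonal_runs(cc < -cfg$r)
    mlp_total <- mlp_total + sum(rp$length)
    mln_total <- mln_total + sum(rn$length)
    n_seg_pos <- n_seg_pos + nrow(rp)
    n_seg_neg <- n_seg_neg + nrow(rn)
  }
  build_metrics(list(sum_pos = sum_pos, sum_neg = sum_neg,
                     sum_pos_all = sum_pos_all, sum_neg_all = sum_neg_all,
                     mlp_total = mlp_total, mln_total = mln_total,
                     n_pos = n_pos, n_neg = n_neg, n_undefined = n_undef,
                     n_pairs = n_pairs,
                     n_seg_pos = n_seg_pos, n_seg_neg = n_seg_neg,
                     nv = nv),
                cfg, n)
}

#' Six TCM metrics by diagonal streaming
#'
#' The production path: computes the same six metrics as
#' [tcm_metrics_from_matrix()] applied to [tcm_matrix_full()], but
#' diagonal-by-diagonal with rolling Pearson window sums, so peak memory
#' stays `O(N)` and the full `nv x nv` matrix is never materialized. In
#' the TCM matrix each diagonal holds all embedding-vector pairs at one
#' fixed delay, so streaming over diagonals is streaming over delays.
#'
#' Fields of the returned object: `tc`, `tac`, `cab1`, `mlp`, `mln`,
#' `cab2` (the six metrics); `totnum_cc` (the normalization constant),
#' `n_pairs` (pairs actually evaluated — differs from `totnum_cc` by the
#' `dia_s` near-diagonal exclusion, which the normalization deliberately
#' does not subtract), `m_text` (the all-off-diagonal pair count
#' `(N-w+1)(N-w)`), `n_pos`/`n_neg`/`n_undefined` counts,
#' `tc_text`/`tac_text` (the compatibility-convention values),
#' `mean_seg_len_pos`/`mean_seg_len_neg` (auxiliary per-segment mean run
#' lengths, not used in CAB2), and the `config` echo.
#'
#' A constant (zero-variance) series yields all-undefined correlations:
#' every metric is 0 and a warning is raised, so flat voxels never abort
#' a whole-volume run.
#'
#' @param x Numeric time series of length `N > w`.
#' @param cfg A [tcm_config()].
#' @return A `tcm_metrics` object.
#' @examples
#' x <- gen_pink_noise(300, seed = 1)
#' tcm_metrics(x, tcm_config(w = 20))
#' @export
tcm_metrics <- function(x, cfg = tcm_config()) {
  stopifnot(inherits(cfg, "tcm_config"))
  x <- check_series(x)
  n <- length(x)
  if (cfg$w >= n) stop("series too short: need N > w", call. = FALSE)
  nv <- (n - cfg$w + 1L) %/% cfg$g
  if (nv < 2L) stop("series too short for two embedding vectors", call. = FALSE)
  included_diagonals(nv, cfg)   # validates the exclusion bounds
  raw <- .tcm_stream_cpp(x, cfg$w, cfg$g, cfg$r, cfg$dia_s, cfg$dia_e,
                         cfg$corr_kind == "spearman")
  build_metrics(raw, cfg, n)
}

#' Predicted pair-evaluation counts
#'
#' Informational cost model for progress reporting and planning: the
#' number of embedding-vector pairs in the evaluated upper triangle, the
#' floating-point work of the naive per-pair correlation (each pair costs
#' `O(w)`), and of the rolling-sum streaming path (each pair costs
#' `O(g)`), multiplied across voxels.
#'
#' @param n Timepoints per series.
#' @param w Embedding vector length.
#' @param g Gap (default 1).
#' @param n_voxels Number of series (default 1).
#' @return A list with `nv`, `n_pairs`, `naive_ops`, `streaming_ops`.
#' @examples
#' complexity_estimate(1200, 30)$n_pairs  # 1171 * 1170 / 2
#' @export
complexity_estimate <- function(n, w, g = 1L, n_voxels = 1L) {
  nv <- (n - w + 1L) %/% g
  if (nv < 2L) stop("no pairs: series too short", call. = FALSE)
  pairs <- nv * (nv - 1) / 2
  list(nv = nv,
       n_pairs = n_voxels * pairs,
       naive_ops = n_voxels * pairs * w,
       streaming_ops = n_voxels * pairs * g)
}
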