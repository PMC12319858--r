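#' Intraclass correlation from a ratings table
#'
#' Single-measure ICC from the two-way ANOVA decomposition of an
#' `n x k` table (targets by raters; here typically voxels or subjects
#' by sessions). `"icc31"` (default) is the two-way mixed, consistency,
#' single-measure coefficient `(MSR - MSE) / (MSR + (k-1) MSE)` — the
#' natural choice when the two sessions are fixed repetitions.
#' `"icc21"` is the two-way random, absolute-agreement variant, which
#' additionally penalizes a systematic session offset.
#'
#' @param ratings Numeric matrix, one row per target, one column per
#'   rater/session. Rows containing non-finite values are dropped.
#' @param model `"icc31"` or `"icc21"`.
#' @return A single ICC value (<= 1), or `NaN` when the between-target
#'   variance is degenerate.
#' @examples
#' tab <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
#' icc(tab, "icc31")
#' @export
icc <- function(ratings, model = c("icc31", "icc21")) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  ratings <- ratings[stats::complete.cases(ratings) &
                       apply(is.finite(ratings), 1L, all), , drop = FALSE]
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3L) stop("need at least 3 complete targets", call. = FALSE)
  if (k < 2L) stop("need at least 2 raters/sessions", call. = FALSE)
  grand <- mean(ratings)
  rowm <- rowMeans(ratings)
  colm <- colMeans(ratings)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  den <- switch(model,
    icc31 = msr + (k - 1) * mse,
    icc21 = msr + (k - 1) * mse + k / n * (msc - mse))
  if (!is.finite(den) || den <= 0) {
    warning("degenerate variance: ICC undefined", call. = FALSE)
    return(NaN)
  }
  (msr - mse) / den
}

#' Test-retest ICC between repeated metric maps
#'
#' Two sampling frames are supported. With one map per session
#' (3D arrays), the ICC is computed across in-mask voxels, treating
#' voxels as targets and the two sessions as raters — the desk-scale
#' frame for a single subject. With a list of per-subject maps per
#' session, the ICC is computed per voxel across subjects, yielding a 3D
#' reliability map as in multi-subject test-retest studies.
#'
#' @param rest1,rest2 Either two 3D arrays, or two lists of 3D arrays
#'   (same length, one per subject), on a common grid.
#' @param model ICC variant, see [icc()].
#' @param mask Optional 3D logical array; defaults to voxels finite in
#'   all inputs.
#' @return A scalar ICC (single-map frame) or a 3D array of voxelwise
#'   ICC values, `NaN` outside the mask or where degenerate (class
#'   `tcm_icc_map`).
#' @export
icc_map <- function(rest1, rest2, model = c("icc31", "icc21"), mask = NULL) {
  model <- match.arg(model)
  if (is.list(rest1) && !is.array(rest1)) {
    stopifnot(is.list(rest2), length(rest1) == length(rest2),
              length(rest1) >= 3L)
    dims <- dim(rest1[[1]])
    all_maps <- c(rest1, rest2)
    for (m in all_maps)
      if (!identical(dim(m), dims)) stop("map grids differ", call. = FALSE)
    if (is.null(mask)) {
      mask <- Reduce(`&`, lapply(all_maps, is.finite))
    }
    flat <- which(mask)
    s1 <- vapply(rest1, function(m) m[flat], numeric(length(flat)))
    s2 <- vapply(rest2, function(m) m[flat], numeric(length(flat)))
    out <- array(NaN, dim = dims)
    vals <- rep(NaN, length(flat))
    n_degen <- 0L
    for (v in seq_along(flat)) {
      tab <- cbind(s1[v, ], s2[v, ])
      val <- withCallingHandlers(icc(tab, model),
                                 warning = function(w) invokeRestart("muffleWarning"))
      if (is.nan(val)) n_degen <- n_degen + 1L
      vals[v] <- val
    }
    if (n_degen > 0)
      warning(n_degen, " voxel(s) had degenerate variance; ICC is NaN there",
              call. = FALSE)
    out[flat] <- vals
    return(structure(out, class = c("tcm_icc_map", class(out)), model = model))
  }
  stopifnot(is.array(rest1), is.array(rest2),
            identical(dim(rest1), dim(rest2)))
  if (is.null(mask)) mask <- is.finite(rest1) & is.finite(rest2)
  flat <- which(mask)
  if (length(flat) < 3L) stop("need at least 3 in-mask voxels", call. = FALSE)
  icc(cbind(rest1[flat], rest2[flat]), model)
}

# strict local maxima with a minimum-prominence filter
find_peaks <- function(x, min_prominence) {
  n <- length(x)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    # walk left/right to the nearest strictly higher sample (or boundary),
    # tracking the lowest valley on the way
    lmin <- x[i]; t <- i
    while (t > 1 && x[t] <= x[i]) { t <- t - 1L; lmin <- min(lmin, x[t]) }
    rmin <- x[i]; t <- i
    while (t < n && x[t] <= x[i]) { t <- t + 1L; rmin <- min(rmin, x[t]) }
    prom <- x[i] - max(lmin, rmin)
    keep[j] <- prom >= min_prominence
  }
  cand[keep]
}

#' Respiration or heart rate from a raw physiological recording
#'
#' Extracts the mean breathing/cardiac cycle from a high-frequency
#' recording (the reference acquisition samples at 400 Hz): the signal is
#' zero-phase low-pass filtered (cutoff 5 Hz for respiration, 10 Hz for
#' cardiac; 4th-order Butterworth run forward and backward so peak times
#' are not shifted), strict local maxima with prominence of at least 10%
#' of the filtered signal's range are taken as cycle peaks, first
#' differences of the peak times give inter-peak intervals, interval
#' outliers beyond median +/- 3 scaled MAD are removed, and the remaining
#' intervals are averaged. A recording is excluded when the mean
#' respiration cycle exceeds 10 s or the mean cardiac cycle exceeds 4 s
#' (strictly; cycles exactly at the boundary are kept), or when fewer
#' than 3 peaks survive.
#'
#' @param samples Numeric vector, the raw recording.
#' @param fs Sampling rate in Hz (default 400).
#' @param kind `"respiration"` or `"cardiac"`.
#' @return A `tcm_rate`: list with `mean_cycle` (seconds), `rate`
#'   (cycles/minute), `n_peaks_used`, `excluded` (logical), `reason`.
#' @examples
#' beat <- sin(2 * pi * 1.0 * seq(0, 60, by = 1 / 400))
#' physio_rate(beat, fs = 400, kind = "cardiac")$rate  # 60 bpm
#' @export
physio_rate <- function(samples, fs = 400, kind = c("respiration", "cardiac")) {
  kind <- match.arg(kind)
  if (!is.finite(fs) || fs <= 0) stop("`fs` must be positive", call. = FALSE)
  samples <- check_series(samples, "samples")
  if (length(samples) < 2 * fs)
    stop("recording shorter than 2 seconds", call. = FALSE)
  cutoff <- if (kind == "respiration") 5 else 10
  if (cutoff < fs / 2) {
    bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
    filt <- signal::filtfilt(bf, samples)
  } else {
    filt <- samples            # already band-limited below the cutoff
  }
  rng <- diff(range(filt))
  result <- function(mean_cycle, n_used, excluded, reason = NA_character_) {
    structure(list(mean_cycle = mean_cycle,
                   rate = if (is.finite(mean_cycle)) 60 / mean_cycle else NaN,
                   n_peaks_used = n_used, excluded = excluded,
                   reason = reason, kind = kind, fs = fs),
              class = "tcm_rate")
  }
  if (rng == 0) return(result(NaN, 0L, TRUE, "flat recording"))
  pk <- find_peaks(filt, 0.1 * rng)
  if (length(pk) < 3L) return(result(NaN, length(pk), TRUE, "insufficient peaks"))
  gaps <- diff((pk - 1) / fs)
  med <- stats::median(gaps)
  s <- stats::mad(gaps)        # scaled MAD (consistent with the normal sd)
  # with zero MAD any interval off the median is an outlier
  gaps <- gaps[abs(gaps - med) <= 3 * s]
  if (!length(gaps)) return(result(NaN, 0L, TRUE, "insufficient peaks"))
  mc <- mean(gaps)
  limit <- if (kind == "respiration") 10 else 4
  if (mc > limit)
    return(result(mc, length(gaps) + 1L, TRUE,
                  sprintf("mean %s cycle %.2f s exceeds %g s", kind, mc, limit)))
  result(mc, length(gaps) + 1L, FALSE)
}

#' @export
print.tcm_rate <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("%s recording EXCLUDED (%s)\n", x$kind, x$reason))
  } else {
    cat(sprintf("%s: mean cycle %.3f s, rate %.1f /min (%d peaks)\n",
                x$kind, x$mean_cycle, x$rate, x$n_peaks_used))
  }
  invisible(x)
}
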