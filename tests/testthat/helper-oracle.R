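# Brute-force reference computation of the six TCM metrics, written from
# the definitions: one cor() call per embedding-vector pair and an explicit
# run scan. Independent of both package code paths; only usable at small N.

oracle_run_lengths <- function(bits) {
  out <- integer(0)
  cur <- 0L
  for (b in bits) {
    if (isTRUE(b)) cur <- cur + 1L
    else {
      if (cur >= 2L) out <- c(out, cur)
      cur <- 0L
    }
  }
  if (cur >= 2L) out <- c(out, cur)
  out
}

oracle_metrics <- function(x, w, r = 0.3, g = 1, dia_s = floor(w / 3),
                           dia_e = w, corr_kind = "pearson") {
  n <- length(x)
  nv <- (n - w + 1) %/% g
  vecs <- lapply(seq_len(nv), function(i) x[((i - 1) * g + 1):((i - 1) * g + w)])
  tot <- nv * (nv - 1) / 2 - dia_e * (dia_e + 1) / 2
  d_lo <- max(dia_s, 1)
  d_hi <- nv - dia_e
  stopifnot(d_hi > d_lo)
  sum_pos <- sum_neg <- mlp <- mln <- 0
  n_pairs <- n_pos <- n_neg <- 0
  for (d in d_lo:(d_hi - 1)) {
    cc <- vapply(seq_len(nv - d), function(i) {
      u <- vecs[[i]]; v <- vecs[[i + d]]
      if (corr_kind == "spearman") { u <- rank(u); v <- rank(v) }
      if (stats::sd(u) == 0 || stats::sd(v) == 0) 0
      else stats::cor(u, v)
    }, numeric(1))
    n_pairs <- n_pairs + length(cc)
    n_pos <- n_pos + sum(cc > 0); n_neg <- n_neg + sum(cc < 0)
    sum_pos <- sum_pos + sum(cc[cc > 0])
    sum_neg <- sum_neg + sum(-cc[cc < 0])
    mlp <- mlp + sum(oracle_run_lengths(cc > r))
    mln <- mln + sum(oracle_run_lengths(cc < -r))
  }
  list(tc = sum_pos / tot, tac = sum_neg / tot,
       cab1 = (sum_pos - sum_neg) / tot,
       mlp = mlp / tot, mln = mln / tot, cab2 = (mlp - mln) / tot,
       totnum_cc = tot, n_pairs = n_pairs, n_pos = n_pos, n_neg = n_neg)
}

metric_fields <- c("tc", "tac", "cab1", "mlp", "mln", "cab2")

expect_metrics_equal <- function(a, b, tol = 1e-10,
                                 fields = c(metric_fields, "totnum_cc",
                                            "n_pairs", "n_pos", "n_neg")) {
  for (f in fields)
    expect_equal(a[[f]], b[[f]], tolerance = tol, label = f,
                 expected.label = paste("reference", f))
}
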