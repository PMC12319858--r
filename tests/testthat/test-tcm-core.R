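test_that("embedding extraction yields the defined count and window content", {
  x <- as.numeric(1:10)
  e <- extract_embeddings(x, w = 3, g = 1)
  expect_equal(nrow(e), 8)
  expect_equal(e[1, ], c(1, 2, 3))
  expect_equal(e[8, ], c(8, 9, 10))
  expect_equal(nrow(extract_embeddings(rnorm(1200), 30, 1)), 1171)
  expect_equal(nrow(extract_embeddings(rnorm(100), 30, 3)), 23)
  # stride: vector i starts at sample (i-1)*g + 1
  e3 <- extract_embeddings(x, w = 3, g = 3)
  expect_equal(e3[2, ], c(4, 5, 6))
  expect_error(extract_embeddings(rnorm(10), w = 10), "too short")
})

test_that("embedding correlation matches closed forms and flags degeneracy", {
  u <- c(0.3, -1.2, 2.5, 0.1)
  expect_equal(embedding_corr(u, u), 1)
  expect_equal(embedding_corr(u, -u + 7), -1)
  expect_equal(embedding_corr(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_true(is.nan(embedding_corr(c(1, 1, 1), u[1:3])))
  # spearman is pearson on ranks, with average ranks on ties
  a <- c(1, 5, 2, 2, 9); b <- c(3, 1, 4, 4, 2)
  expect_equal(embedding_corr(a, b, "spearman"), cor(a, b, method = "spearman"))
})

test_that("full TCM matrix is symmetric with unit diagonal and sign structure", {
  cfg <- tcm_config(w = 3, dia_s = 0, dia_e = 0)
  m <- tcm_matrix_full(as.numeric(1:6), cfg)
  expect_equal(unclass(m)[upper.tri(m)], rep(1, 6), tolerance = 1e-12,
               ignore_attr = TRUE)  # collinear ramp embeddings
  x <- gen_pink_noise(60, 4)
  mm <- tcm_matrix_full(x, tcm_config(w = 5))
  expect_identical(unclass(mm), t(unclass(mm)))
  expect_equal(diag(mm), rep(1, nrow(mm)), ignore_attr = TRUE)
  expect_true(all(abs(mm) <= 1))
  # alternating series: two-point embeddings correlate -1 at odd delays
  alt <- tcm_matrix_full(c(1, -1, 1, -1, 1, -1), tcm_config(w = 2, dia_s = 0, dia_e = 0))
  i <- 1:4
  expect_equal(alt[cbind(i, i + 1)], rep(-1, 4), tolerance = 1e-12)
  expect_equal(alt[cbind(1:3, 3:5)], rep(1, 3), tolerance = 1e-12)
})

test_that("matrix-path metrics reproduce hand-enumerated small cases", {
  # ramp with no exclusions: every correlation is +1
  cfg <- tcm_config(w = 3, dia_s = 0, dia_e = 0)
  m <- tcm_metrics_from_matrix(tcm_matrix_full(as.numeric(1:6), cfg))
  expect_equal(m$tc, 1); expect_equal(m$tac, 0); expect_equal(m$cab1, 1)
  # alternating +-1: 10 upper-triangle pairs, 4 positive (delays 2,4),
  # 6 negative (delays 1,3)
  cfg2 <- tcm_config(w = 2, dia_s = 0, dia_e = 0)
  m2 <- tcm_metrics_from_matrix(tcm_matrix_full(c(1, -1, 1, -1, 1, -1), cfg2))
  expect_equal(m2$totnum_cc, 10)
  expect_equal(m2$tc, 0.4); expect_equal(m2$tac, 0.6)
  expect_equal(m2$cab1, -0.2)
  expect_equal(m2$n_pos, 4); expect_equal(m2$n_neg, 6)
})

test_that("diagonal run extraction drops isolated points and closes at the end", {
  r <- diagonal_runs(c(1, 1, 1, 0, 1, 0, 0))
  expect_equal(nrow(r), 1); expect_equal(r$length, 3)
  expect_equal(nrow(diagonal_runs(c(0, 0, 0, 0))), 0)
  expect_equal(diagonal_runs(c(1, 1, 0, 1, 1))$length, c(2, 2))
  expect_equal(diagonal_runs(c(1, 1, 1, 1))$length, 4)  # run closed at the boundary
  expect_equal(diagonal_runs(c(0, 1, 1))$start, 2)
})

test_that("streaming metrics equal the brute-force definition on random cases", {
  set.seed(123)
  for (rep in 1:12) {
    n <- sample(60:160, 1)
    w <- sample(4:20, 1)
    g <- sample(1:3, 1)
    nv <- (n - w + 1) %/% g
    dia_e <- sample(0:3, 1)
    dia_s <- sample(0:min(5, nv - dia_e - 2), 1)
    r <- runif(1, 0.1, 0.6)
    x <- switch(sample(3, 1),
                rnorm(n),
                gen_pink_noise(n, rep),
                gen_sinusoid(sample(5:20, 1), n) + 0.3 * rnorm(n))
    cfg <- tcm_config(w = w, r = r, g = g, dia_s = dia_s, dia_e = dia_e)
    got <- tcm_metrics(x, cfg)
    ref <- oracle_metrics(x, w, r, g, dia_s, dia_e)
    expect_metrics_equal(got, ref, tol = 1e-10)
  }
})

test_that("streaming and full-matrix paths agree for spearman too", {
  set.seed(7)
  x <- round(gen_pink_noise(140, 2), 1)   # rounding forces rank ties
  cfg <- tcm_config(w = 11, r = 0.25, corr_kind = "spearman")
  a <- tcm_metrics(x, cfg)
  b <- tcm_metrics_from_matrix(tcm_matrix_full(x, cfg))
  expect_metrics_equal(a, b, tol = 1e-10)
  ref <- oracle_metrics(x, 11, 0.25, 1, floor(11 / 3), 11, "spearman")
  expect_metrics_equal(a, ref, tol = 1e-10)
})

test_that("metrics are invariant to affine rescaling, sign flip, and time reversal", {
  x <- gen_pink_noise(400, 21)
  cfg <- tcm_config(w = 25)
  base <- tcm_metrics(x, cfg)
  for (y in list(3.7 * x + 11, -2 * x + 5, rev(x))) {
    m <- tcm_metrics(y, cfg)
    for (f in metric_fields)
      expect_equal(m[[f]], base[[f]], tolerance = 1e-10, label = f)
  }
})

test_that("MLP and MLN are non-increasing in the threshold r", {
  x <- gen_pink_noise(600, 5)
  prev <- NULL
  for (r in seq(0.1, 0.7, 0.1)) {
    m <- tcm_metrics(x, tcm_config(w = 20, r = r))
    if (!is.null(prev)) {
      expect_lte(m$mlp, prev$mlp)
      expect_lte(m$mln, prev$mln)
    }
    prev <- m
  }
})

test_that("metric ranges hold across signal classes", {
  cfg <- tcm_config(w = 15)
  for (x in list(gen_sinusoid(12, 300), gen_pink_noise(300, 1),
                 gen_gaussian_noise(300, 2))) {
    m <- tcm_metrics(x, cfg)
    expect_gte(m$tc, 0); expect_lte(m$tc, 1)
    expect_gte(m$tac, 0); expect_lte(m$tac, 1)
    expect_gte(m$cab1, -1); expect_lte(m$cab1, 1)
    expect_gte(m$mlp, 0); expect_gte(m$mln, 0)
    expect_gt(m$totnum_cc, 0)
  }
})

test_that("sinusoid TC plateaus near the period and coherent beats white noise", {
  # embedding windows shorter than one cycle inflate TC; at or beyond the
  # period TC settles onto a plateau (variation far below the w < p drop)
  p <- 40
  tc <- vapply(c(p / 2, p, 2 * p),
               function(w) tcm_metrics(gen_sinusoid(p, 1200), tcm_config(w = w))$tc,
               numeric(1))
  expect_gt(tc[1], tc[2] + 0.01)
  expect_lt(abs(tc[2] - tc[3]), 0.005)
  # long-range-correlated noise scores higher TC than white noise
  wins <- 0
  for (s in 1:20) {
    a <- tcm_metrics(gen_pink_noise(1200, s), tcm_config())$tc
    b <- tcm_metrics(gen_gaussian_noise(1200, s + 500), tcm_config())$tc
    wins <- wins + (a > b)
  }
  expect_gte(wins, 19)
})

test_that("degenerate and near-degenerate inputs are handled, not fatal", {
  expect_warning(m <- tcm_metrics(rep(1, 100), tcm_config(w = 10)),
                 "undefined correlation")
  for (f in metric_fields) expect_equal(m[[f]], 0)
  # flat stretch inside an otherwise varying series: sentinel pairs count
  # in the denominator but contribute nothing
  x <- c(rnorm(40), rep(2, 30), rnorm(40))
  expect_warning(m2 <- tcm_metrics(x, tcm_config(w = 12, dia_s = 4, dia_e = 4)),
                 "undefined correlation")
  expect_gt(m2$n_undefined, 0)
  ref <- oracle_metrics(x, 12, 0.3, 1, 4, 4)
  expect_metrics_equal(m2, ref, tol = 1e-10,
                       fields = c(metric_fields, "totnum_cc"))
})

test_that("configuration validation rejects impossible settings", {
  expect_error(tcm_config(w = 1), "w")
  expect_error(tcm_config(r = 0), "r")
  expect_error(tcm_config(r = 1), "r")
  expect_error(tcm_config(g = 0), "g")
  # over-aggressive exclusions leave no diagonals
  expect_error(tcm_metrics(rnorm(50), tcm_config(w = 10, dia_s = 35, dia_e = 10)),
               "no diagonals")
  expect_error(tcm_metrics(rnorm(20), tcm_config(w = 30)), "too short")
})

test_that("text-equation compatibility convention is exposed for TC/TAC", {
  x <- gen_pink_noise(120, 9)
  cfg <- tcm_config(w = 10, dia_s = 0, dia_e = 0, convention = "text")
  m <- tcm_metrics(x, cfg)
  n <- 120; w <- 10; nv <- n - w + 1
  expect_equal(m$m_text, (n - w + 1) * (n - w))
  # with no exclusions, text TC is the upper-triangle positive sum over
  # half of m_text; reproduce from the full matrix directly
  mat <- tcm_matrix_full(x, cfg)
  up <- mat[upper.tri(mat)]
  expect_equal(m$tc, sum(up[up > 0]) / (m$m_text / 2), tolerance = 1e-10)
  expect_equal(m$tac, sum(-up[up < 0]) / (m$m_text / 2), tolerance = 1e-10)
  # algorithm-convention values ride along regardless of the switch
  alg <- tcm_metrics(x, tcm_config(w = 10, dia_s = 0, dia_e = 0))
  expect_equal(m$tc_algorithm, alg$tc)
})

test_that("complexity estimates follow the handshake count", {
  est <- complexity_estimate(1200, 30)
  expect_equal(est$nv, 1171)
  expect_equal(est$n_pairs, 1171 * 1170 / 2)
  expect_equal(complexity_estimate(1200, 30, n_voxels = 2)$n_pairs,
               2 * est$n_pairs)
  expect_equal(complexity_estimate(100, 99)$n_pairs, 1)
  expect_equal(est$naive_ops, est$n_pairs * 30)
})

test_that("single-series CSV round trip preserves the metrics", {
  td <- withr::local_tempdir()
  x <- gen_pink_noise(200, 3)
  fin <- file.path(td, "series.csv")
  write.csv(data.frame(bold = x), fin, row.names = FALSE)
  fout <- file.path(td, "metrics.json")
  m <- tcm_metrics_csv(fin, tcm_config(w = 15), out = fout)
  j <- jsonlite::read_json(fout)
  expect_equal(j$tc, m$tc, tolerance = 1e-12)
  expect_equal(j$cab2, m$cab2, tolerance = 1e-12)
  expect_equal(j$config$w, 15)
})
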