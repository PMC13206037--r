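cfg <- estimator_config()

test_that("KSG mutual information matches Gaussian closed forms", {
  set.seed(101)
  x <- rnorm(2000); y <- rnorm(2000)
  expect_lt(abs(mi_knn(x, y, cfg)), 0.05)            # independence -> ~0

  n <- 5000
  x <- rnorm(n); y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  expect_equal(mi_knn(x, y, cfg), gauss_mi_bits(0.6), tolerance = 0.05 / 0.32)

  expect_error(mi_knn(rnorm(10), rnorm(9), cfg), "equal length")
  expect_error(mi_knn(rnorm(5), rnorm(5), cfg), "k \\+ 2")
})

test_that("KSG MI agrees with the exact plug-in value on a discrete joint", {
  set.seed(102)
  p <- matrix(c(0.20, 0.05, 0.05, 0.02,
                0.05, 0.15, 0.03, 0.02,
                0.02, 0.05, 0.12, 0.04,
                0.02, 0.03, 0.05, 0.10), 4, byrow = TRUE)
  truth <- plugin_mi(p)
  s <- sample_discrete_pair(5000, p)
  expect_equal(mi_knn(s$x, s$y, cfg), truth, tolerance = 0.05 / truth)
})

test_that("conditional MI matches its Gaussian and Markov oracles", {
  set.seed(103)
  n <- 5000
  # z independent of (x, y): CMI reduces to MI
  x <- rnorm(n); y <- 0.5 * x + sqrt(0.75) * rnorm(n); z <- rnorm(n)
  expect_equal(cmi_knn(x, y, z, cfg), mi_knn(x, y, cfg), tolerance = 0.05 / 0.2)

  # Markov chain x -> z -> y: conditioning on z removes all dependence
  x <- rnorm(n)
  z <- 0.8 * x + 0.6 * rnorm(n)
  y <- 0.7 * z + sqrt(1 - 0.49) * rnorm(n)
  expect_lt(abs(cmi_knn(x, y, z, cfg)), 0.05)

  # trivariate Gaussian: partial-correlation closed form
  S <- matrix(c(1, 0.5, 0.3,
                0.5, 1, 0.4,
                0.3, 0.4, 1), 3)
  M <- rmvn(n, S)
  expect_equal(cmi_knn(M[, 1], M[, 2], M[, 3], cfg), gauss_cmi_bits(S),
               tolerance = 0.05 / 0.15)
})

test_that("MI and CMI track closed forms over random Gaussian systems", {
  set.seed(104)
  for (i in 1:10) {
    S <- random_corr3()
    M <- rmvn(5000, S)
    expect_lt(abs(mi_knn(M[, 1], M[, 2], cfg) - gauss_mi_bits(S[1, 2])),
              0.05)
    expect_lt(abs(cmi_knn(M[, 1], M[, 2], M[, 3], cfg) - gauss_cmi_bits(S)),
              0.05)
  }
})

test_that("the chain-rule identity holds exactly for the plug-in oracle", {
  set.seed(105)
  for (i in 1:5) {
    p <- array(runif(2 * 3 * 2), c(2, 3, 2))
    p <- p / sum(p)
    # I(X;Y) - I(X;Y|Z) must equal I(X;Z) - I(X;Z|Y) exactly
    lhs <- plugin_mi(apply(p, c(1, 2), sum)) - plugin_cmi(p)
    pz <- aperm(p, c(1, 3, 2))
    rhs <- plugin_mi(apply(pz, c(1, 2), sum)) - plugin_cmi(pz)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("the chain-rule residual of the KSG estimates stays small", {
  set.seed(106)
  for (i in 1:6) {
    S <- random_corr3()
    M <- rmvn(3000, S)
    x1 <- M[, 1]; x0 <- M[, 2]; c0 <- M[, 3]
    ntic_self <- mi_knn(x1, x0, cfg) - cmi_knn(x1, x0, c0, cfg)
    ntic_ctx <- mi_knn(x1, c0, cfg) - cmi_knn(x1, c0, x0, cfg)
    expect_lt(abs(ntic_self - ntic_ctx), 0.1)
  }
})

test_that("info_triple builds the lagged system and closes its identity", {
  set.seed(107)
  n <- 3001
  x <- ar1_series(n, 0.8)
  ctx_vals <- ar1_series(n, 0.8)
  s <- cell_series(1L, 1:n, x, transformed = TRUE)
  ctx <- context_series(1L, 1:n, ctx_vals, transformed = TRUE)
  tr <- info_triple(s, ctx, cfg)
  expect_equal(tr$ntic, tr$mi_self - tr$cmi_self_given_ctx, tolerance = 1e-12)
  expect_lt(abs(tr$ntic), 0.05)                      # irrelevant context
  expect_lt(abs((tr$mi_self - tr$cmi_self_given_ctx) -
                  (tr$mi_ctx - tr$cmi_ctx_given_self)), 0.1)

  # context identical to the series: conditioning on X removes everything
  ctx_same <- context_series(1L, 1:n, x, transformed = TRUE)
  tr2 <- info_triple(s, ctx_same, cfg)
  expect_lt(tr2$cmi_self_given_ctx, 0.1)
  expect_equal(tr2$ntic, tr2$mi_self, tolerance = 0.15)

  bad <- context_series(1L, 2:(n + 1), ctx_vals, transformed = TRUE)
  expect_error(info_triple(s, bad, cfg), "aligned")
})

test_that("info_triple matches Gaussian closed forms on a constructed triple", {
  set.seed(108)
  # jointly Gaussian (X_t, X_{t+1}, C_t) with known covariance: build an
  # AR(1) plus a context correlated with the current state only
  n <- 5001
  a <- 0.7
  x <- ar1_series(n, a)
  c0 <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n) * sd(x)
  s <- cell_series(1L, 1:n, x, transformed = TRUE)
  ctx <- context_series(1L, 1:n, c0, transformed = TRUE)
  tr <- info_triple(s, ctx, cfg)
  r1 <- a; rc <- 0.5; r2 <- a * 0.5     # corr(X', C) = a * corr(X, C)
  S <- matrix(c(1, r1, r2,
                r1, 1, rc,
                r2, rc, 1), 3)
  expect_lt(abs(tr$mi_self - gauss_mi_bits(r1)), 0.05)
  expect_lt(abs(tr$mi_ctx - gauss_mi_bits(r2)), 0.05)
  expect_lt(abs(tr$cmi_self_given_ctx - gauss_cmi_bits(S)), 0.05)
  SS <- S[c(1, 3, 2), c(1, 3, 2)]
  expect_lt(abs(tr$cmi_ctx_given_self - gauss_cmi_bits(SS)), 0.05)
})

test_that("per-cell NTIC estimates are stable across neighbour counts", {
  set.seed(109)
  lin <- simulate_lineage(3, 22500, seed = 5)
  specs <- list(`0` = regime_spec("coupled"),
                `1` = regime_spec("coupled"),
                `2` = regime_spec("independent"),
                `3` = regime_spec("coupled"))
  bun <- simulate_community(lin, specs, seed = 5)
  ls <- bundle_log_series(bun)
  ids <- as.character(3:14)   # generations 2 and 3: wide NTIC range
  ntic_k <- sapply(c(5L, 8L, 10L, 12L), function(k) {
    sapply(ids, function(id) {
      s <- ls[[id]]
      seg <- segment_phases(s, window_samples = min(3000L, length(s$values)))
      sl <- phase_slice(s, seg, "middle")
      ctx <- mean_field(ls, as.integer(id), frames = sl$frames)
      info_triple(sl, ctx, estimator_config(k = k))$ntic
    })
  })
  cors <- cor(ntic_k)
  expect_true(all(cors[upper.tri(cors)] >= 0.9))
})

test_that("estimates are deterministic given the jitter seed", {
  set.seed(110)
  x <- rnorm(500); y <- rnorm(500)
  expect_identical(mi_knn(x, y, cfg), mi_knn(x, y, cfg))
  cfg2 <- estimator_config(jitter_scale = 1e-6, seed = 9)
  expect_identical(mi_knn(x, y, cfg2), mi_knn(x, y, cfg2))
})
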