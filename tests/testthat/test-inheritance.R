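test_that("jsd matches hand-computed values and its analytic bounds", {
  # point mass vs (1/2, 1/2):
  # 0.5*log2(4/3) + 0.25*log2(2/3) + 0.25*log2(2) = 0.31128
  expect_equal(jsd(c(1, 0), c(0.5, 0.5)),
               0.5 * log2(4 / 3) + 0.25 * log2(2 / 3) + 0.25, tolerance = 1e-12)
  expect_equal(jsd(c(1, 0), c(0.5, 0.5)), 0.311278, tolerance = 1e-6)

  expect_equal(jsd(c(0.2, 0.8), c(0.2, 0.8)), 0)     # identical -> 0
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)             # disjoint -> 1 (base 2)

  set.seed(21)
  for (i in 1:20) {
    p <- runif(8); p <- p / sum(p)
    q <- runif(8); q <- q / sum(q)
    d <- jsd(p, q)
    expect_equal(d, jsd(q, p))                       # symmetric
    expect_gte(d, 0)
    expect_lte(d, 1)
  }
})

test_that("ke_distribution is a proper probability vector on shared bins", {
  set.seed(2)
  s <- cell_series(1L, 1:400, rnorm(400), transformed = TRUE)
  edges <- shared_log_ke_bins(list(s), n_bins = 50L)
  d <- ke_distribution(s, edges)
  expect_equal(sum(d$probabilities), 1, tolerance = 1e-12)
  expect_true(all(d$probabilities >= 0))
  expect_equal(length(d$probabilities), 50L)

  const <- cell_series(2L, 1:100, rep(0.7, 100), transformed = TRUE)
  dc <- ke_distribution(const, edges)
  expect_equal(max(dc$probabilities), 1)             # single occupied bin

  short <- cell_series(3L, 1:10, rnorm(10), transformed = TRUE)
  expect_warning(ds <- ke_distribution(short, edges), "flagged")
  expect_true(ds$flagged)

  s2 <- cell_series(4L, 1:400, rnorm(400) + 1, transformed = TRUE)
  e2 <- shared_log_ke_bins(list(s2), n_bins = 50L)
  expect_error(jsd(ke_distribution(s, edges), ke_distribution(s2, e2)),
               "bin edges")
})

test_that("pairwise clustering yields a symmetric matrix and sane cuts", {
  mk <- function(id, probs) structure(
    list(cell_id = id, bin_edges = 0:3, probabilities = probs,
         n_samples = 100L, flagged = FALSE), class = "ke_distribution")
  same1 <- mk(1L, c(0.5, 0.5, 0))
  same2 <- mk(2L, c(0.5, 0.5, 0))
  other <- mk(3L, c(0, 0, 1))
  cl <- pairwise_jsd_cluster(list(same1, same2, other), cut_height = 0.3)
  expect_true(isSymmetric(cl$matrix))
  expect_equal(diag(cl$matrix), setNames(rep(0, 3), rownames(cl$matrix)))
  expect_equal(length(unique(cl$clusters)), 2L)      # identical pair vs outlier
  expect_equal(cl$clusters[["1"]], cl$clusters[["2"]])

  set.seed(5)
  gen <- lapply(1:4, function(i) {
    p <- runif(3); mk(i, p / sum(p))
  })
  cl0 <- pairwise_jsd_cluster(gen, cut_height = 0)
  expect_equal(length(unique(cl0$clusters)), 4L)     # cut 0: singletons
})

test_that("rank-biserial effect size reproduces the printed arithmetic", {
  expect_equal(rank_biserial(304, 37, 26), 1 - 608 / 962)
  expect_equal(round(rank_biserial(304, 37, 26), 2), 0.37)
})

test_that("rank-biserial r and U are mutually consistent", {
  set.seed(31)
  for (i in 1:10) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    u <- sample(0:(n1 * n2), 1)
    r <- rank_biserial(u, n1, n2)
    expect_equal(round((1 - r) * n1 * n2 / 2), u)    # invert back to integer U
  }
})

test_that("fidelity_by_regime computes grouped tests with Bonferroni", {
  set.seed(41)
  pairs <- tibble::tibble(
    jsd = c(rnorm(20, 0.15, 0.02), rnorm(20, 0.30, 0.02),
            rnorm(20, 0.20, 0.02)),
    category = rep(c("coupled", "information_closure", "independent"),
                   each = 20))
  fs <- fidelity_by_regime(pairs)
  expect_equal(nrow(fs$groups), 3L)
  expect_equal(nrow(fs$pairwise), 3L)
  expect_true(all(fs$pairwise$p_corr >= fs$pairwise$p_raw))
  expect_true(all(fs$pairwise$p_corr <= 1))
  expect_equal(fs$pairwise$p_corr, pmin(1, 3 * fs$pairwise$p_raw))
  # clearly separated groups: large H, strong coupled-vs-IC effect
  expect_gt(fs$kruskal_h, 10)
  row <- fs$pairwise[fs$pairwise$group1 == "coupled" &
                       fs$pairwise$group2 == "information_closure", ]
  expect_gt(row$effect_r, 0.8)

  # identical groups: H near 0 and all corrected p at 1
  same <- tibble::tibble(jsd = rep(c(0.1, 0.2, 0.3, 0.4), 3),
                         category = rep(c("coupled", "information_closure",
                                          "independent"), each = 4))
  fs0 <- fidelity_by_regime(same)
  expect_lt(fs0$kruskal_h, 0.5)
  expect_equal(fs0$pairwise$p_corr, rep(1, 3))

  # synergistic / anomalous rows are ignored
  extra <- rbind(pairs, tibble::tibble(jsd = 0.5,
                                       category = c("anomalous", "synergistic")))
  expect_equal(fidelity_by_regime(extra)$groups$n, fs$groups$n)
})

test_that("generation_fidelity pools transitions and correlates IC fraction", {
  p1 <- tibble::tibble(parent_id = 0L, daughter_id = 1:2,
                       transition = "gen0->1", jsd = c(0.2, 0.4))
  p2 <- tibble::tibble(parent_id = 0L, daughter_id = 1:2,
                       transition = "gen0->1", jsd = c(0.1, 0.3))
  gf <- generation_fidelity(list(a = p1, b = p2))
  expect_equal(gf$by_transition$mean_jsd, 0.25)
  expect_equal(gf$by_transition$n, 4L)

  # single pair per transition: mean equals the pair, sd undefined
  single <- tibble::tibble(parent_id = 0L, daughter_id = 1L,
                           transition = "gen0->1", jsd = 0.37)
  gs <- generation_fidelity(list(only = single))
  expect_equal(gs$by_transition$mean_jsd, 0.37)
  expect_true(is.na(gs$by_transition$sd_jsd))

  # permuting series labels leaves pooled means unchanged
  gf2 <- generation_fidelity(list(b = p2, a = p1))
  expect_equal(gf2$by_transition, gf$by_transition)

  # constructed proportionality: Pearson r of 1
  tabs <- lapply(1:5, function(i) {
    tibble::tibble(parent_id = 0L, daughter_id = 1L,
                   transition = "gen0->1", jsd = 0.1 * i)
  })
  names(tabs) <- paste0("s", 1:5)
  icf <- setNames(seq(0.1, 0.5, by = 0.1), names(tabs))
  gc <- generation_fidelity(tabs, ic_fractions = icf)
  expect_equal(gc$ic_correlation$r, 1, tolerance = 1e-12)
})
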