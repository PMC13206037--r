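# Independent oracles used across the estimator tests.

# Closed-form mutual information (bits) of a bivariate Gaussian
gauss_mi_bits <- function(rho) -0.5 * log2(1 - rho^2)

# Closed-form conditional MI (bits) of a trivariate Gaussian via the
# partial correlation of (1, 2) given 3
gauss_cmi_bits <- function(S) {
  pc <- (S[1, 2] - S[1, 3] * S[2, 3]) /
    sqrt((1 - S[1, 3]^2) * (1 - S[2, 3]^2))
  -0.5 * log2(1 - pc^2)
}

# draw n samples from a zero-mean Gaussian with correlation matrix S
rmvn <- function(n, S) {
  L <- chol(S)
  matrix(rnorm(n * nrow(S)), n) %*% L
}

# random positive-definite 3x3 correlation matrix with moderate
# correlations (so closed forms stay well-conditioned)
random_corr3 <- function() {
  repeat {
    r <- runif(3, -0.7, 0.7)
    S <- matrix(c(1, r[1], r[2],
                  r[1], 1, r[3],
                  r[2], r[3], 1), 3)
    if (min(eigen(S, only.values = TRUE)$values) > 0.05) return(S)
  }
}

# exact plug-in MI (bits) from a discrete joint probability table
plugin_mi <- function(p) {
  p <- p / sum(p)
  px <- rowSums(p)
  py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  s
}

# exact plug-in CMI I(X;Y|Z) (bits) from a 3-way probability array
plugin_cmi <- function(p) {
  p <- p / sum(p)
  s <- 0
  for (k in seq_len(dim(p)[3])) {
    pz <- sum(p[, , k])
    if (pz > 0) s <- s + pz * plugin_mi(p[, , k] / pz)
  }
  s
}

# jittered samples from a discrete joint: returns continuous x, y whose
# dependence structure matches the table (jitter << category spacing)
sample_discrete_pair <- function(n, p, jitter = 0.05) {
  p <- p / sum(p)
  cells <- which(p > 0, arr.ind = TRUE)
  probs <- p[p > 0]
  pick <- sample(nrow(cells), n, replace = TRUE, prob = probs)
  list(x = cells[pick, 1] + runif(n, -jitter, jitter),
       y = cells[pick, 2] + runif(n, -jitter, jitter))
}

# stationary AR(1) series with unit innovations
ar1_series <- function(n, a, burn = 100L) {
  e <- rnorm(n + burn)
  x <- numeric(n + burn)
  x[1] <- e[1] / sqrt(1 - a^2)
  for (t in 2:(n + burn)) x[t] <- a * x[t - 1] + e[t]
  x[(burn + 1):(burn + n)]
}

# small community bundle for fast structural tests
tiny_bundle <- function(regime = "independent", seed = 1L, fpg = 1500L,
                        generations = 2L) {
  lin <- simulate_lineage(generations, fpg, seed = seed)
  simulate_community(lin, regime_spec(regime), seed = seed)
}
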