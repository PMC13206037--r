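#' Estimator configuration
#'
#' Bundles the settings of the k-nearest-neighbour information estimators.
#' All estimates are reported in bits.
#'
#' @param k Neighbour count of the Kraskov estimator (default 8).
#' @param lag Prediction lag in samples of the (resampled) analysis grid
#'   (default 1, i.e. 0.5 s on the standard stride-5 grid).
#' @param jitter_scale Relative magnitude of the deterministic tie-breaking
#'   jitter: each variable receives uniform noise of half-width
#'   `jitter_scale * sd(variable)` before estimation.  The k-NN estimator
#'   assumes continuous data; near-stationary log-KE series can contain
#'   exact ties, which the jitter resolves reproducibly.
#' @param theiler Theiler (dynamic-correlation) exclusion window, in
#'   samples of the analysis grid: samples within `theiler` steps of a
#'   query point are never counted as its neighbours.  Serially correlated
#'   series otherwise let temporal neighbours pose as statistical ones,
#'   biasing the estimates and de-calibrating the permutation surrogates.
#'   The default 10 covers the correlation time of kinetic-energy series
#'   at the standard 0.5 s resampling; set 0 for independent draws.
#' @param seed Seed of the tie-breaking jitter.
#' @return An object of class `estimator_config`.
#' @export
estimator_config <- function(k = 8L, lag = 1L, jitter_scale = 1e-10,
                             theiler = 10L, seed = 1L) {
  if (k < 1L) abort("`k` must be >= 1.")
  if (lag < 1L) abort("`lag` must be >= 1.")
  if (jitter_scale < 0) abort("`jitter_scale` must be >= 0.")
  if (theiler < 0L) abort("`theiler` must be >= 0.")
  structure(list(k = as.integer(k), lag = as.integer(lag),
                 jitter_scale = jitter_scale, theiler = as.integer(theiler),
                 seed = as.integer(seed)),
            class = "estimator_config")
}

#' @export
print.estimator_config <- function(x, ...) {
  cat(sprintf("<estimator_config> k = %d, lag = %d, theiler = %d, jitter %g, seed %d\n",
              x$k, x$lag, x$theiler, x$jitter_scale, x$seed))
  invisible(x)
}

# deterministic tie-breaking jitter, one column at a time
.jitter <- function(cols, config) {
  if (config$jitter_scale == 0) return(cols)
  set.seed(derive_seed(config$seed, "jitter", length(cols[[1L]])))
  lapply(cols, function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) s <- 1
    v + runif(length(v), -1, 1) * config$jitter_scale * s
  })
}

.check_pair <- function(x, y, config) {
  if (length(x) != length(y)) abort("sample vectors must have equal length.")
  need <- config$k + 2L * config$theiler + 2L
  if (length(x) < need) {
    abort(sprintf("need at least k + 2*theiler + 2 = %d samples, got %d.",
                  need, length(x)))
  }
}

#' Mutual information by the Kraskov k-NN estimator
#'
#' Kraskov-Stoegbauer-Grassberger (algorithm 1) estimate of `I(X; Y)` for
#' continuous samples, using the max-norm in the joint space.  Estimates
#' are *not* clipped at zero: small negative values are legitimate
#' fluctuations of the estimator and are handled downstream by surrogate
#' thresholds; clipping would bias the surrogate null.
#'
#' @param x,y Numeric sample vectors of equal length.
#' @param config An [estimator_config()].
#' @return The estimate in bits.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(2000); y <- 0.6 * x + 0.8 * rnorm(2000)
#' mi_knn(x, y, estimator_config())  # approx 0.32 bits
mi_knn <- function(x, y, config = estimator_config()) {
  .check_pair(x, y, config)
  j <- .jitter(list(x = x, y = y), config)
  .ksg_mi_cpp(j$x, j$y, config$k, config$theiler) / log(2)
}

#' Conditional mutual information by the Frenzel-Pompe k-NN estimator
#'
#' Estimates `I(X; Y | Z)` for continuous samples with the k-NN method of
#' Frenzel and Pompe (neighbour counts in the `(x,z)`, `(y,z)` and `z`
#' subspaces at the joint k-th neighbour radius).
#'
#' @param x,y,z Numeric sample vectors of equal length.
#' @param config An [estimator_config()].
#' @return The estimate in bits.
#' @export
cmi_knn <- function(x, y, z, config = estimator_config()) {
  .check_pair(x, y, config)
  .check_pair(x, z, config)
  j <- .jitter(list(x = x, y = y, z = z), config)
  .ksg_cmi_cpp(j$x, j$y, j$z, config$k, config$theiler) / log(2)
}

#' Lagged information quantities of a cell against its sibling context
#'
#' Builds the lagged triple `(X_t, X_{t+lag}, C_t)` from a cell's
#' (log-scale) series and its aligned sibling mean-field, and estimates the
#' five quantities of the closure analysis, all in bits:
#'
#' * `mi_self = I(X_{t+lag}; X_t)` — self-predictive information;
#' * `mi_ctx = I(X_{t+lag}; C_t)` — context information about the future;
#' * `cmi_self_given_ctx = I(X_{t+lag}; X_t | C_t)`;
#' * `cmi_ctx_given_self = I(X_{t+lag}; C_t | X_t)` — the transfer entropy
#'   `TE(C -> X)`;
#' * `ntic = mi_self - cmi_self_given_ctx` — non-trivial information
#'   closure, the part of self-prediction redundant with the context.
#'
#' By the chain rule the identity
#' `mi_self - cmi_self_given_ctx = mi_ctx - cmi_ctx_given_self`
#' holds exactly for true information quantities; for k-NN estimates it
#' holds up to estimator fluctuation.
#'
#' @param series A transformed [cell_series()].
#' @param context A [context_series()] aligned to the same frames.
#' @param config An [estimator_config()].
#' @return An object of class `info_triple` (a named list of the five
#'   quantities plus `n`, the number of lagged samples used).
#' @export
info_triple <- function(series, context, config = estimator_config()) {
  stopifnot(inherits(series, "cell_series"),
            inherits(context, "context_series"))
  if (length(series$frames) != length(context$frames) ||
      any(series$frames != context$frames)) {
    abort("series and context must be aligned on identical frames.")
  }
  lag <- config$lag
  n <- length(series$values)
  if (n - lag < config$k + 2L * config$theiler + 2L) {
    abort("series too short for the requested lag, k and theiler window.")
  }
  x0 <- series$values[seq_len(n - lag)]
  x1 <- series$values[seq_len(n - lag) + lag]
  c0 <- context$values[seq_len(n - lag)]
  j <- .jitter(list(x1 = x1, x0 = x0, c0 = c0), config)
  ln2 <- log(2)
  tw <- config$theiler
  mi_self <- .ksg_mi_cpp(j$x1, j$x0, config$k, tw) / ln2
  mi_ctx <- .ksg_mi_cpp(j$x1, j$c0, config$k, tw) / ln2
  cmi_self_given_ctx <- .ksg_cmi_cpp(j$x1, j$x0, j$c0, config$k, tw) / ln2
  cmi_ctx_given_self <- .ksg_cmi_cpp(j$x1, j$c0, j$x0, config$k, tw) / ln2
  structure(list(
    mi_self = mi_self,
    mi_ctx = mi_ctx,
    cmi_self_given_ctx = cmi_self_given_ctx,
    cmi_ctx_given_self = cmi_ctx_given_self,
    ntic = mi_self - cmi_self_given_ctx,
    n = n - lag
  ), class = "info_triple")
}

#' @export
print.info_triple <- function(x, ...) {
  cat(sprintf(paste0(
    "<info_triple> (bits, n = %d)\n",
    "  I(X';X) %.4f | I(X';C) %.4f | I(X';X|C) %.4f | TE(C->X) %.4f\n",
    "  NTIC %.4f\n"),
    x$n, x$mi_self, x$mi_ctx, x$cmi_self_given_ctx,
    x$cmi_ctx_given_self, x$ntic))
  invisible(x)
}
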