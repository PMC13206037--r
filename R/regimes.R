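#' Permutation-surrogate null for one cell
#'
#' Builds the per-cell surrogate null of the closure analysis: the context
#' sample order is permuted uniformly at random (the focal series is held
#' fixed) and `I(X'; C_perm)` and `NTIC_perm` are recomputed for each of
#' `n_perm` permutations.  Because a permutation preserves the context's
#' marginal distribution exactly, the null captures the estimator's
#' fluctuation for *this* cell's noise level, which is why thresholds are
#' per-cell rather than pooled.
#'
#' Percentiles use the `(n+1)p` plotting position (type 6): under
#' exchangeability the probability that an independent context exceeds the
#' 95th percentile of 50 surrogates is then exactly the nominal 5\%.
#'
#' @param series A transformed [cell_series()].
#' @param context A [context_series()] aligned to the same frames.
#' @param config An [estimator_config()].
#' @param n_perm Number of surrogate permutations (default 50).
#' @param seed Seed of the permutation draw.
#' @param null Which surrogate null distributions to compute: `"both"`
#'   (default; needed for classification), or `"ntic"` / `"mi"` alone,
#'   e.g. for false-positive audits of a single test.
#' @return An object of class `surrogate_result` with the observed
#'   [info_triple()], the two null distributions, and the thresholds
#'   `mi_threshold` (95th percentile of null `mi_ctx`), `ntic_upper` /
#'   `ntic_lower` (95th / 5th percentiles of null NTIC).  The `category`
#'   field is `NA` until [classify_cell()] is applied.
#' @export
surrogate_null <- function(series, context, config = estimator_config(),
                           n_perm = 50L, seed = 1L,
                           null = c("both", "ntic", "mi")) {
  null <- match.arg(null)
  if (n_perm < 20L) {
    warn("fewer than 20 permutations: percentile thresholds are unstable.")
  }
  observed <- info_triple(series, context, config)
  lag <- config$lag
  n <- length(series$values)
  x0 <- series$values[seq_len(n - lag)]
  x1 <- series$values[seq_len(n - lag) + lag]
  c0 <- context$values[seq_len(n - lag)]
  j <- .jitter(list(x1 = x1, x0 = x0, c0 = c0), config)

  set.seed(derive_seed(seed, "perm"))
  perms <- vapply(seq_len(n_perm), function(i) sample(j$c0),
                  numeric(length(j$c0)))
  ln2 <- log(2)
  null_mi_ctx <- NULL
  null_ntic <- NULL
  if (null %in% c("both", "mi")) {
    null_mi_ctx <- as.numeric(
      .ksg_mi_batch_cpp(j$x1, perms, config$k, config$theiler)) / ln2
  }
  if (null %in% c("both", "ntic")) {
    null_cmi <- as.numeric(
      .ksg_cmi_batch_cpp(j$x1, j$x0, perms, config$k, config$theiler)) / ln2
    null_ntic <- observed$mi_self - null_cmi
  }
  q6 <- function(v, p) if (is.null(v)) NA_real_
                       else unname(quantile(v, p, type = 6))

  structure(list(
    cell_id = series$cell_id,
    phase = NA_character_,
    observed = observed,
    null_mi_ctx = null_mi_ctx,
    null_ntic = null_ntic,
    mi_threshold = q6(null_mi_ctx, 0.95),
    ntic_upper = q6(null_ntic, 0.95),
    ntic_lower = q6(null_ntic, 0.05),
    category = NA_character_,
    seed = as.integer(seed)
  ), class = "surrogate_result")
}

#' @export
print.surrogate_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<surrogate_result> cell %d%s (%d permutations)\n",
    "  MI(X';C) %.4f vs threshold %.4f | NTIC %.4f vs [%.4f, %.4f]\n",
    "  category: %s\n"),
    x$cell_id,
    if (is.na(x$phase)) "" else paste0(", ", x$phase, " phase"),
    length(x$null_mi_ctx), x$observed$mi_ctx, x$mi_threshold,
    x$observed$ntic, x$ntic_lower, x$ntic_upper,
    if (is.na(x$category)) "(unclassified)" else x$category))
  invisible(x)
}

#' Classify a cell into an informational regime
#'
#' Applies the two surrogate tests to a [surrogate_null()] result.
#' `MI(X';C)` is significant when it exceeds the cell's 95th-percentile
#' surrogate threshold; NTIC is compared against the closed interval
#' between the cell's 5th and 95th surrogate percentiles (ties resolve
#' toward the less extreme category):
#'
#' | MI significant | NTIC vs bounds | category |
#' |---|---|---|
#' | yes | above upper       | `coupled` |
#' | yes | within bounds     | `information_closure` |
#' | yes | below lower       | `synergistic` |
#' | no  | within bounds     | `independent` |
#' | no  | outside bounds    | `anomalous` (estimation noise; excluded downstream) |
#'
#' @param result A [surrogate_null()] result.
#' @return The result with `category` filled in.
#' @export
classify_cell <- function(result) {
  stopifnot(inherits(result, "surrogate_result"))
  ntic <- result$observed$ntic
  mi_sig <- result$observed$mi_ctx > result$mi_threshold
  within <- ntic >= result$ntic_lower && ntic <= result$ntic_upper
  result$category <- if (mi_sig) {
    if (within) "information_closure"
    else if (ntic > result$ntic_upper) "coupled"
    else "synergistic"
  } else {
    if (within) "independent" else "anomalous"
  }
  result
}

#' Classify every cell of a community across life-history phases
#'
#' Runs the full per-cell pipeline on a simulated or ingested community:
#' log-transform and resample each KE series, segment lifetimes into
#' early / middle / last terciles, compute the sibling mean-field in the
#' log domain, build the 50-permutation surrogate null, and classify.
#' Cells without contemporaries (the founder alone in its chamber) have no
#' context and are excluded.
#'
#' @param bundle A [simulate_community()] result, or a list with elements
#'   `lineage` and `series` (raw-KE [cell_series()] named by cell id).
#' @param config An [estimator_config()].
#' @param phases Phases to classify (default all three).
#' @param generations Optional subset of generations to classify.
#' @param stride Analysis stride for [log_resample()] (default 5).
#' @param n_perm Surrogate permutations per cell (default 50).
#' @param seed Master seed for the permutation draws; per-cell seeds are
#'   derived from it.
#' @return A tibble with one row per classified (cell, phase): observed
#'   quantities, thresholds, category and sample count.
#' @export
classify_bundle <- function(bundle, config = estimator_config(),
                            phases = c("early", "middle", "last"),
                            generations = NULL, stride = 5L, n_perm = 50L,
                            seed = 1L) {
  lineage <- bundle$lineage
  phases <- match.arg(phases, c("early", "middle", "last"),
                      several.ok = TRUE)
  log_series <- lapply(bundle$series, log_resample, stride = stride)
  gens <- generations %||% unique(lineage$generation)
  rows <- list()
  for (g in gens) {
    cohort <- lineage$cell_id[lineage$generation == g]
    if (length(cohort) < 2L) next   # no contemporaries, context undefined
    for (id in cohort) {
      key <- as.character(id)
      s <- log_series[[key]]
      seg <- segment_phases(s, window_samples = min(3000L, length(s$values)))
      for (ph in phases) {
        slice <- phase_slice(s, seg, ph)
        ctx <- mean_field(log_series, id, frames = slice$frames)
        if (length(ctx$frames) < length(slice$frames)) {
          keep <- slice$frames %in% ctx$frames
          slice <- cell_series(slice$cell_id, slice$frames[keep],
                               slice$values[keep], dt = slice$dt,
                               stride = slice$stride, transformed = TRUE)
        }
        res <- surrogate_null(slice, ctx, config, n_perm = n_perm,
                              seed = derive_seed(seed, "surr", id, ph))
        res$phase <- ph
        res <- classify_cell(res)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          cell_id = id, generation = g, phase = ph,
          n = res$observed$n,
          mi_self = res$observed$mi_self,
          mi_ctx = res$observed$mi_ctx,
          cmi_self_given_ctx = res$observed$cmi_self_given_ctx,
          te_ctx_to_self = res$observed$cmi_ctx_given_self,
          ntic = res$observed$ntic,
          mi_threshold = res$mi_threshold,
          ntic_lower = res$ntic_lower,
          ntic_upper = res$ntic_upper,
          category = res$category
        )
      }
    }
  }
  if (!length(rows)) abort("no classifiable cells (need >= 2 contemporaries).")
  dplyr::bind_rows(rows)
}

#' Phase-by-category classification table
#'
#' Aggregates per-cell classifications into row-normalized fractions per
#' life-history phase, with counts alongside.
#'
#' @param results A tibble from [classify_bundle()] (possibly pooled over
#'   several communities).
#' @return A tibble with one row per (phase, category): `n_cells`,
#'   `fraction` (fractions sum to 1 within each phase).
#' @export
phase_regime_table <- function(results) {
  if (!nrow(results)) abort("empty classification table.")
  cats <- c("coupled", "information_closure", "synergistic",
            "independent", "anomalous")
  results |>
    dplyr::mutate(category = factor(.data$category, levels = cats)) |>
    dplyr::count(.data$phase, .data$category, name = "n_cells",
                 .drop = FALSE) |>
    dplyr::group_by(.data$phase) |>
    dplyr::mutate(fraction = .data$n_cells / sum(.data$n_cells)) |>
    dplyr::ungroup()
}
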