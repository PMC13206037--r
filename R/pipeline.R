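#' Pipeline configuration
#'
#' Resolves a pipeline configuration from a YAML file or a nested list,
#' filling defaults for everything unspecified.  The resolved configuration
#' is fully serializable and is embedded verbatim in every run manifest,
#' together with the master seed from which all stage seeds derive.
#'
#' @param config Path to a YAML file, a list, or `NULL` for all defaults.
#' @param ... Named overrides applied on top (e.g. `seed = 7`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = NULL, ...) {
  defaults <- list(
    seed = 1L,
    out_dir = "nticell-run",
    community = list(
      generations = 3L,
      frames_per_generation = 45000L,
      regimes = list(`0` = "coupled", `1` = "coupled",
                     `2` = "information_closed", `3` = "information_closed")
    ),
    estimator = list(k = 8L, lag = 1L, jitter_scale = 1e-10,
                     theiler = 10L),
    surrogate = list(n_perm = 50L),
    analysis = list(stride = 5L, window_samples = 3000L,
                    phases = c("early", "middle", "last")),
    histogram = list(n_bins = 50L),
    sweep = list(blocks = c(1L, 5L, 10L, 20L, 50L))
  )
  user <- if (is.character(config)) yaml::read_yaml(config)
          else config %||% list()
  cfg <- utils::modifyList(defaults, user)
  cfg <- utils::modifyList(cfg, list(...))
  structure(cfg, class = c("pipeline_config", "list"))
}

resolve_specs <- function(cfg) {
  lapply(cfg$community$regimes, function(r) {
    if (inherits(r, "regime_spec")) r else regime_spec(r)
  })
}

write_manifest <- function(cfg, dir, stage) {
  manifest <- list(stage = stage, config = unclass(cfg),
                   package = "nticell",
                   version = as.character(utils::packageVersion("nticell")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest,
                       file.path(dir, paste0("manifest-", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run a pipeline stage
#'
#' Configuration-driven entry point tying the stages together.  All outputs
#' are plain text (CSV / JSON) under `config$out_dir`, each stage writes a
#' manifest embedding the resolved configuration, and a rerun with an
#' identical configuration reproduces identical artifacts.
#'
#' * `simulate` — generate the synthetic community and write its artifacts;
#' * `classify` — per-cell surrogate classification table
#'   (`classification.csv`);
#' * `inherit` — parent-daughter fidelity pairs, regime-grouped statistics
#'   and the pairwise divergence matrix;
#' * `sweep` — coarse-graining robustness table (`sweep.csv`);
#' * `report` — phase-by-category table assembled from the classification.
#'
#' @param config A [pipeline_config()] (or anything it accepts).
#' @param command One of `"simulate"`, `"classify"`, `"inherit"`,
#'   `"sweep"`, `"report"`.
#' @return The stage's main result, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = NULL,
                         command = c("simulate", "classify", "inherit",
                                     "sweep", "report")) {
  command <- match.arg(command)
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir <- cfg$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  load_bundle <- function() {
    if (!file.exists(file.path(dir, "series.csv"))) {
      abort(sprintf("no community found: %s does not exist; run `simulate` first.",
                    file.path(dir, "series.csv")))
    }
    read_bundle(dir)
  }
  econf <- estimator_config(k = cfg$estimator$k, lag = cfg$estimator$lag,
                            jitter_scale = cfg$estimator$jitter_scale,
                            theiler = cfg$estimator$theiler,
                            seed = derive_seed(cfg$seed, "estimator"))

  result <- switch(command,
    simulate = {
      lin <- simulate_lineage(cfg$community$generations,
                              cfg$community$frames_per_generation,
                              seed = derive_seed(cfg$seed, "lineage"))
      bundle <- simulate_community(lin, resolve_specs(cfg),
                                   seed = derive_seed(cfg$seed, "community"))
      write_bundle(bundle, dir)
      bundle
    },
    classify = {
      bundle <- load_bundle()
      res <- classify_bundle(bundle, econf,
                             phases = cfg$analysis$phases,
                             stride = cfg$analysis$stride,
                             n_perm = cfg$surrogate$n_perm,
                             seed = derive_seed(cfg$seed, "classify"))
      res <- pid_annotate(res)
      readr::write_csv(res, file.path(dir, "classification.csv"))
      res
    },
    inherit = {
      bundle <- load_bundle()
      cls_path <- file.path(dir, "classification.csv")
      if (!file.exists(cls_path)) {
        abort(sprintf("missing %s; run `classify` first.", cls_path))
      }
      cls <- readr::read_csv(cls_path, show_col_types = FALSE)
      dists <- bundle_distributions(bundle,
                                    stride = cfg$analysis$stride,
                                    n_bins = cfg$histogram$n_bins,
                                    window_samples = cfg$analysis$window_samples)
      pairs <- fidelity_pairs(bundle$lineage, dists)
      mid <- cls[cls$phase == "middle", c("cell_id", "category")]
      pairs <- dplyr::left_join(pairs, mid,
                                by = c(daughter_id = "cell_id"))
      readr::write_csv(pairs, file.path(dir, "fidelity.csv"))
      cl <- pairwise_jsd_cluster(dists)
      readr::write_csv(tibble::as_tibble(cl$matrix, rownames = "cell_id"),
                       file.path(dir, "jsd_matrix.csv"))
      stats <- tryCatch(fidelity_by_regime(pairs), error = function(e) NULL)
      if (!is.null(stats)) {
        jsonlite::write_json(
          list(groups = stats$groups, kruskal_h = stats$kruskal_h,
               kruskal_p = stats$kruskal_p, pairwise = stats$pairwise),
          file.path(dir, "fidelity_stats.json"),
          auto_unbox = TRUE, pretty = TRUE, digits = NA)
      }
      list(pairs = pairs, stats = stats, clusters = cl)
    },
    sweep = {
      bundle <- load_bundle()
      sw <- sweep_scales(bundle, econf, blocks = cfg$sweep$blocks,
                         phases = cfg$analysis$phases,
                         stride = cfg$analysis$stride,
                         n_perm = cfg$surrogate$n_perm,
                         seed = derive_seed(cfg$seed, "classify"))
      readr::write_csv(sw$summary, file.path(dir, "sweep.csv"))
      sw
    },
    report = {
      cls_path <- file.path(dir, "classification.csv")
      if (!file.exists(cls_path)) {
        abort(sprintf("missing %s; run `classify` first.", cls_path))
      }
      cls <- readr::read_csv(cls_path, show_col_types = FALSE)
      tab <- phase_regime_table(cls)
      readr::write_csv(tab, file.path(dir, "phase_regimes.csv"))
      tab
    }
  )
  write_manifest(cfg, dir, command)
  invisible(result)
}
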