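#' Write a simulated community to disk
#'
#' Writes the standard plain-text artifacts of a simulated community:
#' `lineage.csv` (`cell_id,parent_id,generation,birth_frame,division_frame,
#' end_frame`), `series.csv` (long form `cell_id,frame,ke`), a JSON
#' manifest with the regime specifications, seed and ground-truth labels,
#' and optionally `tracks.csv` with synthetic trajectories.
#'
#' @param bundle A [simulate_community()] result.
#' @param dir Output directory (created if needed).
#' @param tracks Also write synthetic 2-D tracks (default FALSE).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, tracks = FALSE) {
  stopifnot(inherits(bundle, "series_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$lineage, file.path(dir, "lineage.csv"))
  long <- dplyr::bind_rows(lapply(bundle$series, function(s) {
    tibble::tibble(cell_id = s$cell_id, frame = s$frames, ke = s$values)
  }))
  readr::write_csv(long, file.path(dir, "series.csv"))
  manifest <- list(
    seed = bundle$seed, dt = bundle$dt, latent_stride = bundle$latent_stride,
    truth = as.list(bundle$truth),
    specs = lapply(bundle$specs, unclass)
  )
  jsonlite::write_json(manifest, file.path(dir, "community.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (tracks) {
    readr::write_csv(bundle_tracks(bundle), file.path(dir, "tracks.csv"))
  }
  invisible(dir)
}

#' Read a community written by [write_bundle()]
#'
#' @param dir Directory containing `lineage.csv`, `series.csv` and
#'   `community.json`.
#' @return A `series_bundle`.
#' @export
read_bundle <- function(dir) {
  lin_path <- file.path(dir, "lineage.csv")
  ser_path <- file.path(dir, "series.csv")
  man_path <- file.path(dir, "community.json")
  for (p in c(lin_path, ser_path)) {
    if (!file.exists(p)) abort(sprintf("missing input file: %s", p))
  }
  lineage <- read_lineage_csv(lin_path)
  manifest <- if (file.exists(man_path)) {
    jsonlite::read_json(man_path, simplifyVector = TRUE)
  } else list()
  dt <- manifest$dt %||% 0.1
  series <- read_series_csv(ser_path, dt = dt)
  truth <- unlist(manifest$truth) %||%
    setNames(rep(NA_character_, nrow(lineage)),
             as.character(lineage$cell_id))
  specs <- lapply(manifest$specs, function(s) {
    s$envelope <- as.list(s$envelope)
    structure(s, class = "regime_spec")
  })
  structure(list(lineage = lineage, series = series, truth = truth,
                 specs = specs, seed = manifest$seed %||% NA_integer_,
                 dt = dt,
                 latent_stride = manifest$latent_stride %||% 5L),
            class = "series_bundle")
}

#' Read a lineage table from CSV
#'
#' @param path CSV with header `cell_id,parent_id,generation,birth_frame,
#'   division_frame` (optionally `end_frame`).
#' @return A validated lineage tibble.
#' @export
read_lineage_csv <- function(path) {
  lin <- readr::read_csv(path, show_col_types = FALSE)
  if (!"end_frame" %in% names(lin)) {
    gmax <- max(lin$generation)
    span <- max(lin$division_frame, na.rm = TRUE) /
      max(1L, length(unique(lin$generation)) - 1L)
    lin$end_frame <- ifelse(is.na(lin$division_frame),
                            as.integer(lin$birth_frame + round(span)),
                            lin$division_frame)
  }
  validate_lineage(lin)
  lin
}

#' Read kinetic-energy series from long-form CSV
#'
#' @param path CSV with header `cell_id,frame,ke`.
#' @param dt Seconds per frame.
#' @return A named list of raw-KE [cell_series()].
#' @export
read_series_csv <- function(path, dt = 0.1) {
  long <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("cell_id", "frame", "ke")
  if (!all(need %in% names(long))) {
    abort("series CSV must have columns cell_id, frame, ke.")
  }
  ids <- sort(unique(long$cell_id))
  out <- lapply(ids, function(id) {
    d <- long[long$cell_id == id, ]
    d <- d[order(d$frame), ]
    cell_series(id, d$frame, d$ke, dt = dt)
  })
  setNames(out, as.character(ids))
}

#' Read 2-D tracks and convert to kinetic-energy series
#'
#' @param path CSV with header `frame,cell_id,x,y` (any column order).
#' @param dt Seconds per frame.
#' @return A named list of raw-KE [cell_series()].
#' @export
read_tracks_csv <- function(path, dt = 0.1) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("frame", "cell_id", "x", "y")
  if (!all(need %in% names(tr))) {
    abort("track CSV must have columns frame, cell_id, x, y.")
  }
  ids <- sort(unique(tr$cell_id))
  out <- lapply(ids, function(id) {
    kinetic_energy(tr[tr$cell_id == id, ], dt = dt)
  })
  setNames(out, as.character(ids))
}
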