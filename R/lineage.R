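#' Simulate a synchronized binary-fission lineage
#'
#' Builds the genealogy of a clonal community growing from a single founder
#' by synchronized binary fission: generation `g` contains `2^g` cells, so a
#' lineage with `G` completed generations holds `2^(G+1) - 1` cells in total
#' (e.g. 15 cells for `generations = 3`, the one-to-eight-cell stage).
#' Division times are synchronized within a generation up to a small uniform
#' jitter, so sibling cohorts stay contemporaneous without being artificially
#' simultaneous.
#'
#' @param generations Number of completed generations (`>= 0`); the returned
#'   tree has cells of generation `0 .. generations`.
#' @param frames_per_generation Nominal lifetime of a cell in recording
#'   frames (0.1 s per frame by convention).
#' @param seed Integer seed controlling the division-time jitter.
#' @param jitter_frac Half-width of the uniform division-time jitter as a
#'   fraction of `frames_per_generation` (default 2\%).
#' @param jitter_quantum Division jitters are rounded to multiples of this
#'   many frames (default 5, the standard analysis stride) so that resampled
#'   analysis grids of parents and daughters stay in phase.
#'
#' @return A tibble with one row per cell and columns `cell_id` (integer,
#'   founder is 0), `parent_id` (`NA` for the founder), `generation`,
#'   `birth_frame`, `division_frame` (`NA` for terminal cells) and
#'   `end_frame` (end of the cell's observed interval: the division frame,
#'   or the end of the recording for terminal cells).  Frames are 0-based
#'   and intervals are half-open `[birth, end)`.
#' @export
#' @examples
#' simulate_lineage(generations = 3, frames_per_generation = 600, seed = 1)
simulate_lineage <- function(generations, frames_per_generation, seed = 1L,
                             jitter_frac = 0.02, jitter_quantum = 5L) {
  if (length(generations) != 1L || generations < 0 ||
      generations != round(generations)) {
    abort("`generations` must be a single non-negative integer.")
  }
  if (length(frames_per_generation) != 1L || frames_per_generation <= 0 ||
      frames_per_generation != round(frames_per_generation)) {
    abort("`frames_per_generation` must be a single positive integer.")
  }
  fpg <- as.integer(frames_per_generation)
  n_cells <- 2L^(generations + 1L) - 1L
  cell_id <- seq_len(n_cells) - 1L
  generation <- floor(log2(cell_id + 1L))
  parent_id <- ifelse(cell_id == 0L, NA_integer_, (cell_id - 1L) %/% 2L)

  # division frame of each non-terminal cell: nominal boundary plus jitter
  division <- rep(NA_integer_, n_cells)
  birth <- rep(NA_integer_, n_cells)
  birth[1L] <- 0L
  if (generations > 0) {
    set.seed(derive_seed(seed, "lineage"))
    for (g in 0:(generations - 1L)) {
      idx <- which(generation == g)
      nominal <- (g + 1L) * fpg
      jit <- round(runif(length(idx), -jitter_frac, jitter_frac) * fpg /
                     jitter_quantum) * jitter_quantum
      division[idx] <- as.integer(nominal + jit)
      for (i in idx) {
        daughters <- c(2L * cell_id[i] + 1L, 2L * cell_id[i] + 2L)
        birth[daughters + 1L] <- division[i]
      }
    }
  }
  end_frame <- ifelse(is.na(division),
                      (generation + 1L) * fpg,
                      division)
  out <- tibble::tibble(
    cell_id = cell_id,
    parent_id = as.integer(parent_id),
    generation = as.integer(generation),
    birth_frame = as.integer(birth),
    division_frame = as.integer(division),
    end_frame = as.integer(end_frame)
  )
  validate_lineage(out)
  out
}

#' Validate a lineage table
#'
#' Checks the structural invariants of a binary-fission genealogy: a unique
#' founder without parent, exactly two daughters per dividing cell born at
#' the parent's division frame, and `birth_frame < end_frame` everywhere.
#'
#' @param lineage A lineage tibble as returned by [simulate_lineage()] or
#'   read from CSV.
#' @return The input, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_lineage <- function(lineage) {
  req <- c("cell_id", "parent_id", "generation", "birth_frame")
  missing <- setdiff(req, names(lineage))
  if (length(missing)) {
    abort(paste0("lineage table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"end_frame" %in% names(lineage)) {
    lineage$end_frame <- lineage$division_frame
  }
  if (anyDuplicated(lineage$cell_id)) abort("duplicated cell ids in lineage.")
  founders <- which(is.na(lineage$parent_id))
  if (length(founders) != 1L) {
    abort("lineage must contain exactly one founder (parent_id = NA).")
  }
  if (any(lineage$birth_frame >= lineage$end_frame, na.rm = TRUE)) {
    abort("every cell must satisfy birth_frame < end of its interval.")
  }
  kids <- lineage[!is.na(lineage$parent_id), ]
  if (nrow(kids)) {
    tab <- table(kids$parent_id)
    if (any(tab != 2L)) {
      abort("each dividing parent must have exactly two daughters.")
    }
    pidx <- match(kids$parent_id, lineage$cell_id)
    if (any(kids$birth_frame != lineage$division_frame[pidx])) {
      abort("daughter birth_frame must equal the parent's division_frame.")
    }
  }
  invisible(lineage)
}
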