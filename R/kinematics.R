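#' Construct a kinetic-energy series for one cell
#'
#' @param cell_id Integer cell identifier.
#' @param frames Integer frame grid, strictly increasing with constant step.
#' @param values Kinetic energy (arbitrary units, `>= 0`) or log-KE if
#'   `transformed = TRUE`.
#' @param dt Seconds per frame of the *original* recording grid
#'   (default 0.1 s).
#' @param stride Resampling factor already applied to `frames` (1 = raw).
#' @param transformed Whether `values` are on the log scale.
#' @return An object of class `cell_series`.
#' @export
cell_series <- function(cell_id, frames, values, dt = 0.1, stride = 1L,
                        transformed = FALSE) {
  frames <- as.integer(frames)
  if (length(frames) != length(values)) {
    abort("`frames` and `values` must have equal length.")
  }
  if (length(frames) > 1L) {
    steps <- diff(frames)
    if (any(steps <= 0L) || length(unique(steps)) != 1L) {
      abort("`frames` must be strictly increasing with a constant step.")
    }
  }
  if (!transformed && any(values < 0, na.rm = TRUE)) {
    abort("untransformed kinetic energy must be non-negative.")
  }
  structure(list(cell_id = as.integer(cell_id), frames = frames,
                 values = as.numeric(values), dt = dt,
                 stride = as.integer(stride), transformed = transformed),
            class = "cell_series")
}

#' @export
print.cell_series <- function(x, ...) {
  cat(sprintf("<cell_series> cell %d: %d samples, frames [%d, %d], dt %.3gs, stride %d%s\n",
              x$cell_id, length(x$values),
              if (length(x$frames)) min(x$frames) else NA_integer_,
              if (length(x$frames)) max(x$frames) else NA_integer_,
              x$dt, x$stride, if (x$transformed) ", log scale" else ""))
  invisible(x)
}

#' @export
length.cell_series <- function(x) length(x$values)

#' Sibling mean-field context aligned to a focal series
#'
#' @param focal_id Integer id of the focal cell.
#' @param frames Frame grid identical to the focal series'.
#' @param values Mean sibling (log-)KE at each frame.
#' @param transformed Whether values are on the log scale.
#' @return An object of class `context_series`.
#' @export
context_series <- function(focal_id, frames, values, transformed = FALSE) {
  if (length(frames) != length(values)) {
    abort("`frames` and `values` must have equal length.")
  }
  structure(list(focal_id = as.integer(focal_id),
                 frames = as.integer(frames),
                 values = as.numeric(values),
                 transformed = transformed),
            class = "context_series")
}

#' @export
print.context_series <- function(x, ...) {
  cat(sprintf("<context_series> focal %d: %d samples%s\n", x$focal_id,
              length(x$values), if (x$transformed) ", log scale" else ""))
  invisible(x)
}

#' Kinetic energy from a 2-D trajectory
#'
#' Converts a tracked trajectory to the kinetic-energy proxy
#' `KE(t) = 0.5 * |displacement(t -> t+1) / dt|^2` (unit mass).  Each KE
#' value is assigned to the earlier frame of its displacement pair, so the
#' output is one sample shorter than the input.
#'
#' @param track A data frame with columns `frame`, `x`, `y` (and optionally
#'   `cell_id`, used to label the output).
#' @param dt Seconds per frame (default 0.1).
#' @return A [cell_series()] of kinetic energies.
#' @export
#' @examples
#' tr <- data.frame(frame = 0:3, x = c(0, 0.3, 0.6, 0.9),
#'                  y = c(0, 0.4, 0.8, 1.2))
#' kinetic_energy(tr, dt = 1)$values  # speed 0.5 -> KE 0.125
kinetic_energy <- function(track, dt = 0.1) {
  if (nrow(track) < 2L) abort("a track needs at least 2 points.")
  o <- order(track$frame)
  track <- track[o, , drop = FALSE]
  steps <- diff(track$frame)
  if (length(unique(steps)) != 1L) {
    bad <- which(steps != steps[1L])[1L]
    abort(sprintf(
      "non-uniform frame spacing: first gap between frames %d and %d.",
      track$frame[bad], track$frame[bad + 1L]))
  }
  v2 <- (diff(track$x)^2 + diff(track$y)^2) / (dt * steps[1L])^2
  cell_series(cell_id = track$cell_id[1L] %||% 0L,
              frames = head(track$frame, -1L),
              values = 0.5 * v2, dt = dt, stride = as.integer(steps[1L]))
}

#' Resample and log-transform a kinetic-energy series
#'
#' Keeps every `stride`-th sample and applies the natural log of
#' `KE + epsilon`.  The epsilon guard is scale-free: by default it equals
#' `1e-6` times the median of the cell's positive KE values, so zero-KE
#' frames map to a finite floor without distorting the bulk of the
#' distribution.
#'
#' @param series A [cell_series()] of raw kinetic energies.
#' @param stride Keep every `stride`-th sample (default 5, i.e. 0.5 s at
#'   the standard 0.1 s frame interval).
#' @param epsilon Optional explicit epsilon; if `NULL` the scale-free rule
#'   above is used.
#' @return A transformed [cell_series()] (log scale, `stride` updated).
#' @export
log_resample <- function(series, stride = 5L, epsilon = NULL) {
  stopifnot(inherits(series, "cell_series"))
  if (stride < 1L || stride != round(stride)) {
    abort("`stride` must be a positive integer.")
  }
  if (length(series$values) == 0L) abort("cannot resample an empty series.")
  if (series$transformed) abort("series is already log-transformed.")
  keep <- seq(1L, length(series$values), by = stride)
  v <- series$values[keep]
  if (is.null(epsilon)) {
    pos <- v[v > 0]
    epsilon <- if (length(pos)) 1e-6 * median(pos) else 1e-12
  }
  cell_series(series$cell_id, series$frames[keep], log(v + epsilon),
              dt = series$dt, stride = series$stride * as.integer(stride),
              transformed = TRUE)
}

#' Segment a lifetime into life-history phases
#'
#' Partitions a cell's lifetime into early / middle / last terciles of
#' equal sample count (remainder samples go to the last tercile) and
#' locates the central distribution-estimation window, centered on the
#' midpoint between birth and division.
#'
#' @param series A [cell_series()] spanning the lifetime.
#' @param window_samples Size of the central window in samples of the
#'   series' own grid (default 3000, i.e. 25 min of stride-5 samples at
#'   0.1 s frames).
#' @return A list of class `phase_segmentation` with elements `early`,
#'   `middle`, `last` (index ranges into the series), `central_window`,
#'   and `clipped` (TRUE when the requested window exceeded the lifetime
#'   and was clipped).
#' @export
segment_phases <- function(series, window_samples = 3000L) {
  stopifnot(inherits(series, "cell_series"))
  n <- length(series$values)
  if (n < 3L) abort("lifetime must contain at least 3 samples.")
  third <- n %/% 3L
  early <- c(1L, third)
  middle <- c(third + 1L, 2L * third)
  last <- c(2L * third + 1L, n)
  mid <- (n + 1L) / 2
  half <- window_samples / 2
  w_lo <- max(1L, ceiling(mid - half))
  w_hi <- min(n, w_lo + window_samples - 1L)
  clipped <- (w_hi - w_lo + 1L) < window_samples
  if (clipped) {
    w_lo <- 1L
    w_hi <- n
    warn(sprintf(
      "central window of %d samples exceeds the %d-sample lifetime; clipped.",
      window_samples, n))
  }
  structure(list(early = early, middle = middle, last = last,
                 central_window = c(w_lo, w_hi), clipped = clipped),
            class = "phase_segmentation")
}

#' Extract one phase of a series
#'
#' @param series A [cell_series()].
#' @param segmentation A [segment_phases()] result for that series.
#' @param phase One of `"early"`, `"middle"`, `"last"`, `"central_window"`.
#' @return A [cell_series()] restricted to the phase.
#' @export
phase_slice <- function(series, segmentation,
                        phase = c("middle", "early", "last",
                                  "central_window")) {
  phase <- match.arg(phase)
  rg <- segmentation[[phase]]
  idx <- seq(rg[1L], rg[2L])
  cell_series(series$cell_id, series$frames[idx], series$values[idx],
              dt = series$dt, stride = series$stride,
              transformed = series$transformed)
}

#' Sibling mean-field of a focal cell
#'
#' Computes the contemporaneous sibling mean-field: at every frame of the
#' focal series, the mean (log-)KE of all other cells alive at that frame.
#' The context is returned in the same transform state as the focal series,
#' so information-theoretic analyses run entirely in one domain.
#'
#' @param series_list Named list of [cell_series()] on a common frame
#'   convention (names are cell ids); all must share the focal's transform
#'   state.
#' @param focal_id Id of the focal cell.
#' @param frames Optional frame subset; defaults to the focal series frames.
#' @return A [context_series()] defined on the frames where at least one
#'   contemporary exists; errors if there are none at all.
#' @export
mean_field <- function(series_list, focal_id, frames = NULL) {
  key <- as.character(focal_id)
  if (!key %in% names(series_list)) {
    abort(sprintf("no series for focal cell %s.", key))
  }
  focal <- series_list[[key]]
  frames <- frames %||% focal$frames
  others <- series_list[names(series_list) != key]
  if (!length(others)) {
    abort(sprintf("cell %s has no contemporaries: context undefined.", key))
  }
  acc <- numeric(length(frames))
  cnt <- integer(length(frames))
  for (s in others) {
    if (s$transformed != focal$transformed) {
      abort("all series must share the focal series' transform state.")
    }
    pos <- match(frames, s$frames)
    hit <- !is.na(pos)
    acc[hit] <- acc[hit] + s$values[pos[hit]]
    cnt[hit] <- cnt[hit] + 1L
  }
  keep <- cnt > 0L
  if (!any(keep)) {
    abort(sprintf("cell %s has no contemporaries on the requested frames.",
                  key))
  }
  context_series(focal_id, frames[keep], acc[keep] / cnt[keep],
                 transformed = focal$transformed)
}

#' Temporally coarse-grain a series
#'
#' Averages non-overlapping blocks of `block` consecutive samples; a
#' trailing partial block is dropped and the effective sampling interval is
#' multiplied by `block`.
#'
#' @param series A [cell_series()] (or [context_series()]).
#' @param block Block size (`>= 1`); `block = 1` returns the series
#'   unchanged.
#' @return The coarse-grained series of the same class.
#' @export
coarse_grain <- function(series, block) {
  if (block < 1L || block != round(block)) {
    abort("`block` must be a positive integer.")
  }
  block <- as.integer(block)
  n <- length(series$values)
  if (block > n) abort("`block` exceeds the series length.")
  if (block == 1L) return(series)
  m <- n %/% block
  idx <- seq_len(m * block)
  v <- colMeans(matrix(series$values[idx], nrow = block))
  f <- series$frames[seq(1L, m * block, by = block)]
  if (inherits(series, "cell_series")) {
    cell_series(series$cell_id, f, v, dt = series$dt,
                stride = series$stride * block,
                transformed = series$transformed)
  } else {
    context_series(series$focal_id, f, v, transformed = series$transformed)
  }
}
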