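#' Simulate kinetic-energy series for a whole lineage
#'
#' Generates per-cell kinetic-energy series for every cell of a
#' binary-fission lineage, with the informational regime of each generation
#' controlled by a [regime_spec()].  Latent log-KE dynamics run on a
#' `latent_stride`-frame grid (one step per 0.5 s at the defaults), are
#' linearly interpolated to the raw 0.1 s frame grid, pushed through the
#' regime's marginal transform to non-negative KE, and multiplied by the
#' early/late slow-down envelope.  Contemporaneous siblings share a single
#' community drive stream and interact through the live sibling mean-field,
#' so the ground-truth regime of each generation is realized by
#' construction.
#'
#' Daughters inherit the parent's final latent state and its heritable
#' log-KE location, perturbed by a draw of the regime's `divergence_sd`;
#' this is the generative knob for parent-daughter inheritance fidelity.
#'
#' @param lineage A lineage tibble from [simulate_lineage()].
#' @param specs A single [regime_spec()] applied to every generation, or a
#'   list with one spec per generation (named `"0"`, `"1"`, ... or ordered).
#' @param seed Master integer seed; all per-generation and per-cell draws
#'   are derived from it deterministically.
#' @param dt Seconds per raw frame (default 0.1).
#' @param latent_stride Raw frames per latent step (default 5, matching the
#'   standard analysis stride).
#' @return An object of class `series_bundle`: a list with `lineage`,
#'   `series` (named list of raw-KE [cell_series()]), `truth` (named vector
#'   of ground-truth regime labels), `specs`, `seed`, `dt`, `latent_stride`.
#' @export
#' @examples
#' lin <- simulate_lineage(2, 1500, seed = 1)
#' bun <- simulate_community(lin, regime_spec("independent"), seed = 1)
#' bun
simulate_community <- function(lineage, specs, seed = 1L, dt = 0.1,
                               latent_stride = 5L) {
  validate_lineage(lineage)
  gens <- sort(unique(lineage$generation))
  if (inherits(specs, "regime_spec")) {
    specs <- setNames(rep(list(specs), length(gens)), as.character(gens))
  }
  if (is.null(names(specs)) || any(names(specs) == "")) {
    names(specs) <- as.character(gens[seq_along(specs)])
  }
  missing <- setdiff(as.character(gens), names(specs))
  if (length(missing)) {
    abort(paste0("no regime spec for generation(s): ",
                 paste(missing, collapse = ", ")))
  }
  lapply(specs, validate_regime_spec)

  n_cells <- nrow(lineage)
  latents_final <- setNames(numeric(n_cells), as.character(lineage$cell_id))
  locs <- setNames(numeric(n_cells), as.character(lineage$cell_id))
  series <- setNames(vector("list", n_cells), as.character(lineage$cell_id))
  truth <- setNames(character(n_cells), as.character(lineage$cell_id))

  for (g in gens) {
    spec <- specs[[as.character(g)]]
    cohort <- lineage[lineage$generation == g, ]
    cohort <- cohort[order(cohort$cell_id), ]
    nc <- nrow(cohort)
    start <- min(cohort$birth_frame)
    stop_ <- max(cohort$end_frame)
    n_steps <- ceiling((stop_ - start) / latent_stride) + 1L

    set.seed(derive_seed(seed, "cohort", g))
    innov <- matrix(rnorm(n_steps * nc), n_steps, nc)
    shared <- numeric(n_steps)
    ar <- spec$shared_drive_ar
    w <- rnorm(n_steps)
    shared[1L] <- w[1L]
    if (n_steps > 1L) {
      sc <- sqrt(1 - ar^2)
      for (t in 2:n_steps) shared[t] <- ar * shared[t - 1L] + sc * w[t]
    }
    div_draw <- rnorm(nc)

    # initial latent state and heritable location
    x <- numeric(nc)
    for (i in seq_len(nc)) {
      id <- as.character(cohort$cell_id[i])
      if (is.na(cohort$parent_id[i])) {
        sd0 <- spec$private_noise_sd / sqrt(1 - spec$self_coefficient^2)
        x[i] <- innov[1L, i] * sd0
        locs[id] <- 0
      } else {
        pid <- as.character(cohort$parent_id[i])
        x[i] <- latents_final[pid]
        locs[id] <- locs[pid] + spec$divergence_sd * div_draw[i]
      }
    }

    lat <- matrix(NA_real_, n_steps, nc)
    lat[1L, ] <- x
    if (n_steps > 1L) {
      for (t in 2:n_steps) {
        ctx <- if (nc > 1L) (sum(x) - x) / (nc - 1L) else rep(0, nc)
        x <- regime_kernel_step(x, ctx, shared[t - 1L], spec, innov[t, ])
        lat[t, ] <- x
      }
    }
    node_frames <- start + (seq_len(n_steps) - 1L) * latent_stride

    for (i in seq_len(nc)) {
      id <- as.character(cohort$cell_id[i])
      latents_final[id] <- lat[n_steps, i]
      truth[id] <- spec$regime_label
      frames <- seq(cohort$birth_frame[i], cohort$end_frame[i] - 1L)
      lat_raw <- approx(node_frames, lat[, i], xout = frames)$y
      ke <- latent_to_ke(lat_raw, spec, loc = locs[id])
      ke <- ke * envelope_profile(length(ke), spec$envelope)
      series[[id]] <- cell_series(cohort$cell_id[i], frames, ke, dt = dt)
    }
  }

  structure(list(lineage = lineage, series = series, truth = truth,
                 specs = specs, seed = as.integer(seed), dt = dt,
                 latent_stride = as.integer(latent_stride)),
            class = "series_bundle")
}

#' @export
print.series_bundle <- function(x, ...) {
  regs <- vapply(x$specs, function(s) s$regime_label, character(1))
  cat(sprintf("<series_bundle> %d cells, %d generations, seed %d\n",
              length(x$series), length(unique(x$lineage$generation)),
              x$seed))
  cat("  regimes by generation: ", paste(regs, collapse = " / "), "\n")
  invisible(x)
}

#' Synthetic 2-D tracks consistent with a bundle's kinetic energies
#'
#' Builds random-heading trajectories whose frame-to-frame displacements
#' reproduce each cell's kinetic-energy series exactly (speed
#' `v = sqrt(2 KE)`, heading a persistent random walk).  Useful for
#' exercising the trajectory-ingestion path against known KE.
#'
#' @param bundle A [simulate_community()] result.
#' @param heading_persistence Standard deviation (radians) of the per-frame
#'   heading increment.
#' @return A tibble with columns `cell_id`, `frame`, `x`, `y`.
#' @export
bundle_tracks <- function(bundle, heading_persistence = 0.4) {
  stopifnot(inherits(bundle, "series_bundle"))
  out <- lapply(bundle$series, function(s) {
    set.seed(derive_seed(bundle$seed, "track", s$cell_id))
    n <- length(s$values)
    speed <- sqrt(2 * s$values) * s$dt
    theta <- cumsum(rnorm(n + 1L, 0, heading_persistence))
    x <- cumsum(c(0, speed * cos(theta[-1L])))
    y <- cumsum(c(0, speed * sin(theta[-1L])))
    tibble::tibble(cell_id = s$cell_id,
                   frame = c(s$frames, s$frames[n] + s$stride),
                   x = x, y = y)
  })
  dplyr::bind_rows(out)
}

#' Log-transform and resample every series of a bundle
#'
#' @param bundle A [simulate_community()] result (raw KE).
#' @param stride Analysis stride (default 5).
#' @return A named list of transformed [cell_series()].
#' @export
bundle_log_series <- function(bundle, stride = 5L) {
  stopifnot(inherits(bundle, "series_bundle"))
  lapply(bundle$series, log_resample, stride = stride)
}
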