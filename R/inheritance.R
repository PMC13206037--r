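#' Shared log-KE histogram bins for a comparison set
#'
#' Divergences are only well defined on a common support, so histogram bins
#' are shared across all cells of a comparison set: `n_bins` equal-width
#' bins spanning the pooled 0.5th-99.5th percentile range of the
#' (log-scale) values.
#'
#' @param series_list List of transformed [cell_series()] (or plain numeric
#'   vectors) whose pooled values define the range.
#' @param n_bins Number of bins (default 50).
#' @return A numeric vector of `n_bins + 1` bin edges.
#' @export
shared_log_ke_bins <- function(series_list, n_bins = 50L) {
  pooled <- unlist(lapply(series_list, function(s) {
    if (inherits(s, "cell_series")) s$values else as.numeric(s)
  }), use.names = FALSE)
  rng <- quantile(pooled, c(0.005, 0.995), names = FALSE)
  if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
  seq(rng[1L], rng[2L], length.out = n_bins + 1L)
}

#' Histogram estimate of a cell's log-KE distribution
#'
#' Estimates the kinetic-energy distribution of one cell from its central
#' window, as a normalized histogram on a shared log-KE grid.  Values
#' outside the shared range are clamped into the edge bins so every
#' distribution integrates to 1 on the common support.
#'
#' @param series A transformed [cell_series()].
#' @param bin_edges Shared bin edges from [shared_log_ke_bins()].
#' @param window Optional index range `c(first, last)` into the series
#'   (e.g. the `central_window` of [segment_phases()]); default whole
#'   series.
#' @param min_samples Below this sample count the estimate is flagged as
#'   unreliable (default 50) with a warning.
#' @return An object of class `ke_distribution`: `cell_id`, `bin_edges`,
#'   `probabilities` (non-negative, summing to 1), `n_samples`, `flagged`.
#' @export
ke_distribution <- function(series, bin_edges, window = NULL,
                            min_samples = 50L) {
  stopifnot(inherits(series, "cell_series"))
  v <- series$values
  if (!is.null(window)) v <- v[seq(window[1L], window[2L])]
  flagged <- length(v) < min_samples
  if (flagged) {
    warn(sprintf("only %d samples for cell %d: distribution flagged.",
                 length(v), series$cell_id))
  }
  idx <- findInterval(v, bin_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = length(bin_edges) - 1L)
  structure(list(cell_id = series$cell_id, bin_edges = bin_edges,
                 probabilities = counts / sum(counts),
                 n_samples = length(v), flagged = flagged),
            class = "ke_distribution")
}

#' Jensen-Shannon divergence between two distributions
#'
#' `JSD(p, q) = 0.5 KL(p || m) + 0.5 KL(q || m)` with `m = (p + q) / 2`,
#' logarithms base 2, so the divergence is symmetric and bounded in
#' `[0, 1]`; zero-probability bins contribute nothing.  Lower values mean
#' higher parent-daughter inheritance fidelity.
#'
#' @param p,q [ke_distribution()] objects on identical bins, or bare
#'   probability vectors of equal length.
#' @return The divergence in `[0, 1]`.
#' @export
#' @examples
#' jsd(c(1, 0), c(0.5, 0.5))  # 0.5*log2(4/3) + 0.25*log2(2/3) + 0.25 = 0.3113
jsd <- function(p, q) {
  if (inherits(p, "ke_distribution") && inherits(q, "ke_distribution")) {
    if (length(p$bin_edges) != length(q$bin_edges) ||
        any(p$bin_edges != q$bin_edges)) {
      abort("distributions must share identical bin edges.")
    }
    p <- p$probabilities
    q <- q$probabilities
  }
  if (length(p) != length(q)) abort("probability vectors differ in length.")
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Pairwise divergence matrix and phenotype clusters
#'
#' Computes the full symmetric Jensen-Shannon divergence matrix over a set
#' of cell distributions, clusters it by average-linkage hierarchical
#' clustering, and cuts the dendrogram at a fixed height to obtain flat
#' phenotype groups.
#'
#' @param distributions List of [ke_distribution()] on shared bins.
#' @param cut_height Dendrogram cut (default 0.3 on the JSD scale).
#' @return A list with `matrix` (JSD matrix with cell ids as dimnames),
#'   `hclust` (the dendrogram) and `clusters` (named integer labels).
#' @export
pairwise_jsd_cluster <- function(distributions, cut_height = 0.3) {
  n <- length(distributions)
  if (n < 2L) abort("need at least 2 distributions.")
  ids <- vapply(distributions, function(d) as.character(d$cell_id),
                character(1))
  if (anyDuplicated(ids)) ids <- paste0(ids, "#", seq_len(n))
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (jx in (i + 1L):n) {
      d <- jsd(distributions[[i]], distributions[[jx]])
      M[i, jx] <- d
      M[jx, i] <- d
    }
  }
  hc <- hclust(as.dist(M), method = "average")
  list(matrix = M, hclust = hc, clusters = cutree(hc, h = cut_height))
}

#' Middle-phase distributions for every cell of a bundle
#'
#' Convenience wrapper: log-resample each series, take the central window
#' of the middle phase, and histogram on bins shared across the whole
#' community.
#'
#' @param bundle A [simulate_community()] result.
#' @param stride Analysis stride (default 5).
#' @param n_bins Shared bins (default 50).
#' @param window_samples Central window size in resampled samples
#'   (default 3000).
#' @return A named list of [ke_distribution()].
#' @export
bundle_distributions <- function(bundle, stride = 5L, n_bins = 50L,
                                 window_samples = 3000L) {
  log_series <- lapply(bundle$series, log_resample, stride = stride)
  windows <- lapply(log_series, function(s) {
    seg <- withCallingHandlers(
      segment_phases(s, window_samples = window_samples),
      warning = function(w) invokeRestart("muffleWarning"))
    phase_slice(s, seg, "central_window")
  })
  edges <- shared_log_ke_bins(windows, n_bins = n_bins)
  lapply(windows, ke_distribution, bin_edges = edges)
}

#' Parent-daughter divergence table for a lineage
#'
#' @param lineage A lineage tibble.
#' @param distributions Named list of [ke_distribution()] (names = cell
#'   ids), e.g. from [bundle_distributions()].
#' @return A tibble with `parent_id`, `daughter_id`, `transition`
#'   (`"gen0->1"`, ...) and `jsd`; pairs with a missing distribution are
#'   skipped with a message.
#' @export
fidelity_pairs <- function(lineage, distributions) {
  kids <- lineage[!is.na(lineage$parent_id), ]
  rows <- list()
  for (i in seq_len(nrow(kids))) {
    did <- as.character(kids$cell_id[i])
    pid <- as.character(kids$parent_id[i])
    if (is.null(distributions[[did]]) || is.null(distributions[[pid]])) {
      inform(sprintf("skipping pair %s -> %s: missing distribution.",
                     pid, did))
      next
    }
    g <- kids$generation[i]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      parent_id = kids$parent_id[i],
      daughter_id = kids$cell_id[i],
      transition = sprintf("gen%d->%d", g - 1L, g),
      jsd = jsd(distributions[[pid]], distributions[[did]])
    )
  }
  dplyr::bind_rows(rows)
}

#' Inheritance fidelity grouped by informational regime
#'
#' Tests whether the daughter's informational regime predicts how far its
#' kinetic-energy distribution diverges from the parent's.  Only the three
#' interpretable regimes enter (`coupled`, `information_closure`,
#' `independent`); `synergistic` and `anomalous` cells are excluded, as are
#' groups with fewer than 2 observations (with a warning).  A
#' Kruskal-Wallis test runs across the remaining groups, followed by
#' two-sided Mann-Whitney tests for each pair with Bonferroni correction
#' (`p_corr = min(1, 3 p_raw)`) and the rank-biserial effect size
#' `r = 1 - 2U / (n1 n2)`, oriented so that `r >= 0` when the second group
#' of the pair has the larger divergences.
#'
#' @param pairs A tibble with columns `jsd` and `category` (the daughter's
#'   regime), e.g. [fidelity_pairs()] joined to [classify_bundle()] output.
#' @return An object of class `fidelity_stats`: `groups` (per-regime n,
#'   mean, sd), `kruskal_h`, `kruskal_p`, and `pairwise` (tibble of U,
#'   p_raw, p_corr, effect_r per category pair).
#' @export
fidelity_by_regime <- function(pairs) {
  keep <- c("coupled", "information_closure", "independent")
  d <- pairs[pairs$category %in% keep, c("jsd", "category")]
  tab <- table(d$category)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warn(paste0("excluding regime group(s) with n < 2: ",
                paste(small, collapse = ", ")))
    d <- d[!d$category %in% small, ]
  }
  cats <- intersect(keep, unique(d$category))
  if (length(cats) < 2L) {
    abort("need at least 2 non-empty regime groups among coupled / information_closure / independent.")
  }
  groups <- d |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n = dplyr::n(), mean_jsd = mean(.data$jsd),
                     sd_jsd = sd(.data$jsd), .groups = "drop")
  kw <- kruskal.test(jsd ~ factor(category), data = d)

  combs <- utils::combn(cats, 2L, simplify = FALSE)
  pw <- lapply(combs, function(pr) {
    a <- d$jsd[d$category == pr[1L]]
    b <- d$jsd[d$category == pr[2L]]
    mw <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
    # wilcox.test reports U of the first group; orient the pair so the
    # first group has the smaller median, making r >= 0 when the second
    # group's divergences are larger
    if (median(a) > median(b)) {
      pr <- rev(pr)
      tmp <- a; a <- b; b <- tmp
      mw <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
    }
    u <- unname(mw$statistic)
    tibble::tibble(group1 = pr[1L], group2 = pr[2L],
                   n1 = length(a), n2 = length(b), u = u,
                   p_raw = mw$p.value,
                   p_corr = min(1, 3 * mw$p.value),
                   effect_r = rank_biserial(u, length(a), length(b)))
  })
  structure(list(groups = groups,
                 kruskal_h = unname(kw$statistic),
                 kruskal_p = kw$p.value,
                 pairwise = dplyr::bind_rows(pw)),
            class = "fidelity_stats")
}

#' Rank-biserial effect size from a Mann-Whitney U
#'
#' `r = 1 - 2U / (n1 n2)`: the difference between the probability that a
#' draw from group 2 exceeds one from group 1 and the reverse.
#'
#' @param u The Mann-Whitney U statistic of group 1.
#' @param n1,n2 Group sizes.
#' @return The effect size in `[-1, 1]`.
#' @export
#' @examples
#' rank_biserial(304, 37, 26)  # 0.368, printed as 0.37
rank_biserial <- function(u, n1, n2) {
  1 - 2 * u / (n1 * n2)
}

#' @export
print.fidelity_stats <- function(x, ...) {
  cat("<fidelity_stats>\n")
  print(x$groups)
  cat(sprintf("Kruskal-Wallis H = %.3f, p = %.4g\n", x$kruskal_h,
              x$kruskal_p))
  print(x$pairwise)
  invisible(x)
}

#' Inheritance fidelity across generation transitions
#'
#' Summarizes parent-daughter divergence per generation transition (pooled
#' and per series) and correlates, across series, the final-generation
#' information-closure fraction with the series' mean divergence -- the
#' community-level association between categorical differentiation and
#' phenotypic divergence.
#'
#' @param pair_tables Named list (by series label) of [fidelity_pairs()]
#'   tibbles.
#' @param ic_fractions Optional named numeric vector: fraction of
#'   information-closed cells in the final generation of each series (same
#'   names as `pair_tables`).
#' @return A list with `by_transition` (pooled mean, sd -- `NA` when a
#'   transition has a single pair -- and n), `by_series` (per-series per
#'   transition means and the series mean), and, when `ic_fractions` is
#'   given, `ic_correlation` (Pearson r, p, n).
#' @export
generation_fidelity <- function(pair_tables, ic_fractions = NULL) {
  stacked <- dplyr::bind_rows(pair_tables, .id = "series")
  by_transition <- stacked |>
    dplyr::group_by(.data$transition) |>
    dplyr::summarise(n = dplyr::n(), mean_jsd = mean(.data$jsd),
                     sd_jsd = ifelse(dplyr::n() > 1L, sd(.data$jsd),
                                     NA_real_),
                     .groups = "drop")
  by_series <- stacked |>
    dplyr::group_by(.data$series, .data$transition) |>
    dplyr::summarise(n = dplyr::n(), mean_jsd = mean(.data$jsd),
                     .groups = "drop")
  series_mean <- stacked |>
    dplyr::group_by(.data$series) |>
    dplyr::summarise(mean_jsd = mean(.data$jsd), .groups = "drop")
  out <- list(by_transition = by_transition, by_series = by_series,
              series_mean = series_mean)
  if (!is.null(ic_fractions)) {
    m <- series_mean[match(names(ic_fractions), series_mean$series), ]
    ok <- complete.cases(m$mean_jsd, ic_fractions)
    if (sum(ok) >= 3L) {
      ct <- cor.test(ic_fractions[ok], m$mean_jsd[ok], method = "pearson")
      out$ic_correlation <- list(r = unname(ct$estimate), p = ct$p.value,
                                 n = sum(ok))
    } else {
      out$ic_correlation <- list(r = NA_real_, p = NA_real_, n = sum(ok))
    }
  }
  out
}
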