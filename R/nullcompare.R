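#' Generate Brownian-motion null trait datasets
#'
#' Simulates `n_rep` replicate datasets on the empirical tree using the
#' fitted root states and rates (the empirical ML fits; nothing is
#' re-estimated per replicate). Each replicate and axis draws from its own
#' deterministic seed stream derived from `(master_seed, replicate, axis)`,
#' so the ensemble is reproducible bit-for-bit.
#'
#' @param phy a `phylo` tree.
#' @param fit a [fit_bm()] result for the empirical score axes.
#' @param n_rep number of replicates (default 10).
#' @param master_seed integer master seed.
#' @return list of replicates; each has `tips` (tip score matrix),
#'   `states` (the full simulated `node_states`) and `seeds` (per axis).
#' @export
generate_null <- function(phy, fit, n_rep = 10L, master_seed = 1L) {
  k <- length(fit$sigma2)
  lapply(seq_len(n_rep), function(r) {
    seeds <- vapply(seq_len(k), function(j) derive_seed(master_seed, r, j), 0L)
    states <- matrix(NA_real_, ape::Ntip(phy) + phy$Nnode, k)
    for (j in seq_len(k)) {
      sj <- simulate_bm(phy, fit$root_state[j], fit$sigma2[j], seed = seeds[j])
      states[, j] <- sj[, 1L]
    }
    rownames(states) <- rownames(sj)
    colnames(states) <- paste0("axis_", seq_len(k))
    states <- structure(states, node_age = attr(sj, "node_age"),
                        class = c("node_states", "matrix"))
    list(replicate = r, seeds = seeds,
         tips = tip_states(states, phy), states = states)
  })
}

#' Run the gap-detection pipeline on one dataset
#'
#' Fits Brownian motion to the tip scores, reconstructs ancestral states,
#' slices lineages at regular intervals, computes a Vietoris-Rips
#' persistence diagram per slice, characterises all gaps, filters notable
#' ones and links them into gap series. The same function serves the
#' empirical data and every null replicate, so both runs share one
#' configuration.
#'
#' @param phy a `phylo` tree.
#' @param tip_scores tips-by-axes score matrix.
#' @param config a [gap_config()] list.
#' @return list with `fit`, `states`, `slices`, `diagrams`, `gaps` (all
#'   gaps), `notable`, `series` and `config`.
#' @export
run_gap_pipeline <- function(phy, tip_scores, config = gap_config()) {
  fit <- fit_bm(phy, tip_scores)
  states <- reconstruct_ancestral_states(phy, tip_scores, fit)
  slices <- slice_lineages(phy, states, interval = config$slice_interval,
                           max_age = config$max_age)
  diagrams <- list()
  gaps <- list()
  for (s in slices) {
    n <- nrow(s$coords)
    if (n < 4L) next
    if (n > config$max_points && !isTRUE(config$force)) {
      stop("slice at ", s$slice_age, " My has ", n, " points (> max_points = ",
           config$max_points, "); triangle count grows cubically - set ",
           "force = TRUE to proceed")
    }
    cap <- if (identical(config$cap, "enclosing")) NULL else config$cap
    dg <- rips_diagram(dist(s$coords), max_scale = cap)
    diagrams[[format(s$slice_age)]] <- dg
    gaps <- c(gaps, gaps_from_diagram(dg, s$coords, s$slice_age))
  }
  notable <- notable_gaps(gaps, threshold = config$notable_threshold)
  series <- link_gap_series(notable, link_radius = config$link_radius,
                            interval = config$slice_interval)
  list(fit = fit, states = states, slices = slices, diagrams = diagrams,
       gaps = gaps, notable = notable, series = series, config = config)
}

#' Null quantile of a focal gap with highest-density-region contours
#'
#' Places a focal gap's (persistence, sparsity) pair inside the null gap
#' distribution using a two-dimensional product-Gaussian kernel density
#' with Scott's bandwidth. The focal quantile is the fraction of null
#' probability mass lying at density greater than or equal to the density
#' at the focal point (estimated by evaluating the KDE at the null sample
#' itself), so ~1 means the focal gap sits far outside the null cloud.
#' Highest-density-region contour polygons are returned at the requested
#' coverage levels.
#'
#' With fewer than `min_points` null gaps the KDE is unreliable; the
#' function then falls back to per-axis empirical-rank quantiles and flags
#' the output.
#'
#' @param focal numeric length-2 vector: (persistence, sparsity) of the
#'   focal gap.
#' @param null_points two-column matrix/data frame of null gap
#'   (persistence, sparsity) pairs.
#' @param levels HDR coverage levels for the contours.
#' @param grid_n grid resolution per axis for contour extraction.
#' @param min_points minimum null sample size for the KDE route.
#' @return list with `quantile`, `method` ("kde" or "rank"), `flagged`,
#'   `bandwidth`, `contours` (per level, lists of polygon coordinate
#'   lists) and, for the rank fallback, `axis_quantiles`.
#' @export
null_quantile <- function(focal, null_points,
                          levels = c(0.90, 0.95, 0.99),
                          grid_n = 101L, min_points = 30L) {
  pts <- as.matrix(null_points)
  if (ncol(pts) != 2L) stop("null_points must have two columns")
  if (any(levels <= 0 | levels >= 1)) stop("levels must be inside (0,1)")
  focal <- as.numeric(focal)
  n <- nrow(pts)
  if (n < min_points) {
    aq <- vapply(1:2, function(j) mean(pts[, j] <= focal[j]), 0)
    return(list(quantile = max(aq), method = "rank", flagged = TRUE,
                axis_quantiles = aq, contours = NULL, bandwidth = NULL))
  }
  h <- apply(pts, 2L, sd) * n^(-1 / 6) # Scott's rule, d = 2
  h[h <= 0] <- 1e-9
  kde <- function(qx, qy) {
    vapply(seq_along(qx), function(i) {
      mean(stats::dnorm((qx[i] - pts[, 1L]) / h[1L]) *
             stats::dnorm((qy[i] - pts[, 2L]) / h[2L])) / (h[1L] * h[2L])
    }, 0)
  }
  # leave-one-out density at the null points themselves, so that the
  # focal point (which contributes no kernel of its own) is exchangeable
  # with the null points and the quantile is calibrated
  self_k <- stats::dnorm(0)^2 / (h[1L] * h[2L])
  f_null <- (kde(pts[, 1L], pts[, 2L]) * n - self_k) / (n - 1L)
  f_focal <- kde(focal[1L], focal[2L])
  q <- mean(f_null >= f_focal)
  gx <- seq(min(pts[, 1L]) - 3 * h[1L], max(pts[, 1L]) + 3 * h[1L],
            length.out = grid_n)
  gy <- seq(min(pts[, 2L]) - 3 * h[2L], max(pts[, 2L]) + 3 * h[2L],
            length.out = grid_n)
  z <- outer(gx, gy, function(a, b) kde(a, b))
  contours <- lapply(levels, function(lv) {
    thr <- as.numeric(quantile(f_null, probs = 1 - lv, type = 7))
    contourLines(gx, gy, z, levels = thr)
  })
  names(contours) <- paste0("hdr_", levels)
  list(quantile = q, method = "kde", flagged = FALSE, bandwidth = h,
       contours = contours)
}

#' Count null gap series exceeding a lifespan threshold
#'
#' @param series data frame of series (as in [link_gap_series()]`$series`),
#'   optionally with a `replicate` column.
#' @param threshold_my lifespan threshold in My; the count uses a strict
#'   `>` comparison.
#' @return list with `count`, `rate` (fraction of all series) and
#'   `per_replicate` counts when a replicate column is present.
#' @export
lifespan_exceedance <- function(series, threshold_my = 4) {
  exceed <- series$lifespan_my > threshold_my
  per_rep <- if ("replicate" %in% names(series)) {
    vapply(split(exceed, series$replicate), sum, 0L)
  } else NULL
  list(count = sum(exceed),
       rate = if (nrow(series) == 0L) NA_real_ else mean(exceed),
       per_replicate = per_rep)
}

#' Compare an empirical gap analysis against a Brownian-motion null
#'
#' Generates the null ensemble with [generate_null()], runs the identical
#' pipeline configuration on every replicate, and situates the focal gap
#' (by default the top-persistence notable gap of the modern slice)
#' against the null gaps' (persistence, sparsity) distribution at the same
#' slice age, plus lifespan exceedance tallies over all null series.
#'
#' @param empirical result of [run_gap_pipeline()] on the empirical data.
#' @param phy the tree used throughout.
#' @param config the shared [gap_config()]; replicate count and master
#'   seed are taken from it.
#' @param focal_slice_age slice age at which the focal gap is taken
#'   (default 0 = present).
#' @param lifespan_threshold_my threshold for the exceedance tally.
#' @return list with `focal` (the focal gap), `null_points`, `quantile`
#'   (see [null_quantile()]), `exceedance`, `null_series`, `null_gaps`
#'   and the `config_hash`.
#' @export
compare_to_null <- function(empirical, phy, config = empirical$config,
                            focal_slice_age = 0,
                            lifespan_threshold_my = 4) {
  stopifnot(identical(config_hash(config), config_hash(empirical$config)))
  nulls <- generate_null(phy, empirical$fit, n_rep = config$n_null,
                         master_seed = config$master_seed)
  null_runs <- lapply(nulls, function(nr) {
    run_gap_pipeline(phy, nr$tips, config)
  })
  null_gaps <- do.call(rbind, lapply(seq_along(null_runs), function(r) {
    tb <- gap_table(null_runs[[r]]$gaps)
    if (nrow(tb) > 0L) tb$replicate <- r
    tb
  }))
  null_series <- do.call(rbind, lapply(seq_along(null_runs), function(r) {
    s <- null_runs[[r]]$series$series
    if (nrow(s) > 0L) s$replicate <- r
    s
  }))
  cand <- Filter(function(g) isTRUE(all.equal(g$slice_age, focal_slice_age)),
                 empirical$notable)
  focal <- if (length(cand) > 0L) cand[[1L]] else NULL
  qt <- NULL
  if (!is.null(focal) && !is.null(null_gaps) && nrow(null_gaps) > 0L) {
    at_age <- null_gaps[abs(null_gaps$slice_age - focal_slice_age) < 1e-9, ]
    qt <- null_quantile(c(focal$persistence, focal$sparsity),
                        at_age[, c("persistence", "sparsity")])
  }
  exceed <- if (!is.null(null_series) && nrow(null_series) > 0L) {
    lifespan_exceedance(null_series, lifespan_threshold_my)
  } else list(count = 0L, rate = NA_real_, per_replicate = NULL)
  list(focal = focal, null_gaps = null_gaps, null_series = null_series,
       quantile = qt, exceedance = exceed,
       config_hash = config_hash(config))
}
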