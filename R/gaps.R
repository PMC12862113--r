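#' Characterise an H1 bar as a morphological gap
#'
#' A gap is one finite H1 feature at one time slice. Its topological
#' persistence is `death - birth` (robustness across distance scales); its
#' centroid is the mean location of the loop vertices; its size is the
#' mean distance from the centroid to those vertices; and its sparsity is
#' the mean distance from the centroid to the nearest 5% of cloud points
#' (`k = ceiling(0.05 * n)` neighbours, so `k = 69` at `n = 1378`), a
#' distance-based measure of how densely occupied the surrounding
#' morphospace is. All metrics are in PC distance units.
#'
#' @param bar list or one-row data frame with `birth` and `death`.
#' @param cycle_vertices integer ids of the loop vertices (rows of `cloud`).
#' @param cloud the full point cloud of the slice (points x axes).
#' @param slice_age slice age in My (default `NA`).
#' @return an object of class `gap`.
#' @export
characterize_gap <- function(bar, cycle_vertices, cloud, slice_age = NA_real_) {
  cloud <- as.matrix(cloud)
  n <- nrow(cloud)
  k <- ceiling(0.05 * n)
  if (k < 1L) stop("cloud too small for the 5% sparsity rule")
  birth <- bar$birth
  death <- bar$death
  if (!is.finite(death) || death < birth) stop("bar must be finite with death >= birth")
  verts <- sort(unique(as.integer(cycle_vertices)))
  if (any(verts < 1L | verts > n)) stop("cycle vertices outside the cloud")
  vc <- cloud[verts, , drop = FALSE]
  centroid <- colMeans(vc)
  size <- mean(sqrt(rowSums(sweep(vc, 2L, centroid)^2)))
  d_all <- sqrt(rowSums(sweep(cloud, 2L, centroid)^2))
  sparsity <- mean(sort(d_all)[seq_len(k)])
  structure(
    list(slice_age = slice_age, birth = birth, death = death,
         persistence = death - birth, vertices = verts,
         centroid = centroid, size = size, sparsity = sparsity,
         n_points = n, k_sparsity = as.integer(k)),
    class = "gap"
  )
}

#' @export
print.gap <- function(x, ...) {
  cat(sprintf(
    "gap @ %s My: persistence %.3f (birth %.3f, death %.3f), size %.3f, sparsity %.3f, %d vertices\n",
    format(x$slice_age), x$persistence, x$birth, x$death, x$size,
    x$sparsity, length(x$vertices)))
  invisible(x)
}

#' All gaps of one time slice
#'
#' Characterises every finite H1 bar of a diagram whose representative
#' cycle has at least three distinct vertices. Gaps are ordered by
#' descending persistence (ties by birth, then vertex tuple) so that gap
#' identity within a slice is deterministic.
#'
#' @param diagram a `persistence_diagram` of the slice cloud.
#' @param cloud the slice point cloud the diagram was computed from.
#' @param slice_age slice age in My.
#' @return list of `gap` objects.
#' @export
gaps_from_diagram <- function(diagram, cloud, slice_age = NA_real_) {
  bars <- diagram$bars
  idx <- which(bars$dim == 1L & is.finite(bars$death))
  gaps <- list()
  for (i in idx) {
    verts <- unique(as.vector(diagram$cycles[[bars$cycle_id[i]]]))
    if (length(verts) < 3L) next
    gaps[[length(gaps) + 1L]] <-
      characterize_gap(bars[i, ], verts, cloud, slice_age)
  }
  if (length(gaps) > 1L) {
    key <- order(-vapply(gaps, `[[`, 0, "persistence"),
                 vapply(gaps, `[[`, 0, "birth"),
                 vapply(gaps, function(g) g$vertices[1L], 0L))
    gaps <- gaps[key]
  }
  gaps
}

#' Gap list to data frame
#' @param gaps list of `gap` objects.
#' @return data frame, one row per gap, centroid components as
#'   `centroid_1..k`, vertex ids semicolon-joined.
#' @export
gap_table <- function(gaps) {
  if (length(gaps) == 0L) {
    return(data.frame(slice_age = numeric(0), birth = numeric(0),
                      death = numeric(0), persistence = numeric(0),
                      size = numeric(0), sparsity = numeric(0)))
  }
  cent <- do.call(rbind, lapply(gaps, `[[`, "centroid"))
  colnames(cent) <- paste0("centroid_", seq_len(ncol(cent)))
  out <- data.frame(
    slice_age = vapply(gaps, `[[`, 0, "slice_age"),
    birth = vapply(gaps, `[[`, 0, "birth"),
    death = vapply(gaps, `[[`, 0, "death"),
    persistence = vapply(gaps, `[[`, 0, "persistence"),
    size = vapply(gaps, `[[`, 0, "size"),
    sparsity = vapply(gaps, `[[`, 0, "sparsity"),
    cent,
    vertices = vapply(gaps, function(g) paste(g$vertices, collapse = ";"), ""),
    row.names = NULL
  )
  out
}

#' Filter notable gaps
#'
#' Keeps gaps with topological persistence strictly greater than the
#' threshold (default 0.4 PC units). The fraction retained is attached as
#' an attribute.
#'
#' @param gaps list of `gap` objects.
#' @param threshold positive persistence threshold.
#' @return the filtered list, with attribute `fraction_retained`.
#' @export
notable_gaps <- function(gaps, threshold = 0.4) {
  if (threshold <= 0) stop("threshold must be positive")
  keep <- vapply(gaps, function(g) g$persistence > threshold, TRUE)
  out <- gaps[keep]
  attr(out, "fraction_retained") <-
    if (length(gaps) == 0L) NA_real_ else mean(keep)
  out
}

#' Link gaps across time slices into gap series
#'
#' Gaps at consecutive slice ages are linked when their centroids are
#' within `link_radius` (full retained-PC-space Euclidean distance,
#' default 1 PC unit). Matching between two consecutive slices is greedy
#' one-to-one by ascending centroid distance. Chains of links form gap
#' series; a series' evolutionary lifespan is the span from its youngest
#' to its oldest slice age (a singleton has lifespan 0).
#'
#' @param gaps list of `gap` objects (typically the notable gaps of all
#'   slices).
#' @param link_radius maximum centroid distance for a link (PC units).
#' @param interval the slice spacing (My); only ages exactly `interval`
#'   apart are "consecutive".
#' @return list with `series` (data frame: `series_id`, `lifespan_my`,
#'   `n_gaps`, `age_min`, `age_max`, `mean_size`, `mean_sparsity`,
#'   `mean_persistence`) and `gaps` (the [gap_table()] with a `series_id`
#'   column).
#' @export
link_gap_series <- function(gaps, link_radius = 1, interval = 1) {
  tab <- gap_table(gaps)
  ng <- nrow(tab)
  series_id <- seq_len(ng) # start as singletons
  if (ng > 0L) {
    cent <- do.call(rbind, lapply(gaps, `[[`, "centroid"))
    ages <- tab$slice_age
    for (a in sort(unique(ages))) {
      i_young <- which(ages == a)
      i_old <- which(abs(ages - (a + interval)) < 1e-9)
      if (length(i_young) == 0L || length(i_old) == 0L) next
      pairs <- expand.grid(y = i_young, o = i_old)
      pairs$d <- sqrt(rowSums((cent[pairs$y, , drop = FALSE] -
                                 cent[pairs$o, , drop = FALSE])^2))
      pairs <- pairs[pairs$d <= link_radius, , drop = FALSE]
      pairs <- pairs[order(pairs$d, pairs$y, pairs$o), , drop = FALSE]
      used_y <- used_o <- integer(0)
      for (r in seq_len(nrow(pairs))) {
        y <- pairs$y[r]; o <- pairs$o[r]
        if (y %in% used_y || o %in% used_o) next
        used_y <- c(used_y, y); used_o <- c(used_o, o)
        series_id[series_id == series_id[o]] <- series_id[y]
      }
    }
    series_id <- match(series_id, unique(series_id))
  }
  tab$series_id <- series_id
  series <- do.call(rbind, lapply(split(tab, tab$series_id), function(s) {
    data.frame(series_id = s$series_id[1L],
               lifespan_my = max(s$slice_age) - min(s$slice_age),
               n_gaps = nrow(s),
               age_min = min(s$slice_age), age_max = max(s$slice_age),
               mean_size = mean(s$size), mean_sparsity = mean(s$sparsity),
               mean_persistence = mean(s$persistence))
  }))
  if (is.null(series)) {
    series <- data.frame(series_id = integer(0), lifespan_my = numeric(0),
                         n_gaps = integer(0), age_min = numeric(0),
                         age_max = numeric(0), mean_size = numeric(0),
                         mean_sparsity = numeric(0),
                         mean_persistence = numeric(0))
  }
  rownames(series) <- NULL
  list(series = series, gaps = tab)
}

#' Classify species relative to a gap
#'
#' Scaled distance from the gap centroid: a species is `within` the gap
#' when its distance is at most half the gap size, `near` when between
#' half and the full gap size (boundaries inclusive), otherwise `outside`.
#'
#' @param gap a `gap` object.
#' @param scores score matrix (species x axes) in the same PC space.
#' @return factor with levels `within`, `near`, `outside`, named by the
#'   rownames of `scores`.
#' @export
classify_species <- function(gap, scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != length(gap$centroid)) {
    stop("scores have ", ncol(scores), " axes but the gap centroid has ",
         length(gap$centroid))
  }
  d <- sqrt(rowSums(sweep(scores, 2L, gap$centroid)^2))
  lab <- ifelse(d <= 0.5 * gap$size, "within",
                ifelse(d <= gap$size, "near", "outside"))
  factor(setNames(lab, rownames(scores)),
         levels = c("within", "near", "outside"))
}
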