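#' Time-sliced point clouds from lineage values
#'
#' For each slice age `a` on the grid `0, interval, ..., max_age`, every
#' branch whose parent is older than `a` and whose child is at age `<= a`
#' contributes one point, obtained by linear interpolation between the
#' child and parent values. The slice at age 0 reproduces the tip values
#' exactly.
#'
#' @param phy a `phylo` tree.
#' @param states a `node_states` matrix covering every node (from
#'   [reconstruct_ancestral_states()] or [simulate_bm()]).
#' @param interval slice spacing in My (default 1).
#' @param max_age oldest slice age in My (default 10). If this reaches the
#'   root age the grid is truncated, with a warning, to the oldest slice
#'   holding at least 3 points.
#' @return a list of `sliced_cloud` objects: each has `slice_age`,
#'   `lineage_id` (the child node of the branch crossed) and `coords`.
#' @export
slice_lineages <- function(phy, states, interval = 1, max_age = 10) {
  validate_dated_tree(phy)
  if (interval <= 0) stop("interval must be positive")
  v <- unclass(states)
  n_node <- ape::Ntip(phy) + phy$Nnode
  if (nrow(v) != n_node) stop("states must cover all ", n_node, " nodes")
  ages <- node_ages(phy)
  root_age <- max(ages)
  grid <- seq(0, max_age, by = interval)

  parent <- phy$edge[, 1L]
  child <- phy$edge[, 2L]
  pa <- ages[parent]
  ca <- ages[child]
  eps <- 1e-9 * max(root_age, 1) # absorb float noise in derived ages

  make_slice <- function(a) {
    on <- which(pa > a + eps & ca <= a + eps)
    if (length(on) == 0L) return(NULL)
    w <- pmin(pmax((a - ca[on]) / (pa[on] - ca[on]), 0), 1)
    coords <- v[child[on], , drop = FALSE] * (1 - w) +
      v[parent[on], , drop = FALSE] * w
    rownames(coords) <- NULL
    structure(list(slice_age = a, lineage_id = child[on], coords = coords),
              class = "sliced_cloud")
  }

  slices <- lapply(grid, make_slice)
  counts <- vapply(slices, function(s) if (is.null(s)) 0L else nrow(s$coords),
                   integer(1))
  if (max_age >= root_age - eps) {
    keep_up_to <- max(c(0L, which(counts >= 3L)))
    if (keep_up_to < length(grid)) {
      warning("slice grid reaches the root age (", format(root_age),
              " My); truncated at age ", grid[max(keep_up_to, 1L)],
              " My, the oldest slice with at least 3 lineages")
    }
    slices <- slices[seq_len(keep_up_to)]
  }
  slices <- Filter(Negate(is.null), slices)
  names(slices) <- vapply(slices, function(s) format(s$slice_age), "")
  slices
}

#' @export
print.sliced_cloud <- function(x, ...) {
  cat("sliced_cloud: age", x$slice_age, "My,", nrow(x$coords), "lineages,",
      ncol(x$coords), "axes\n")
  invisible(x)
}

#' Export sliced clouds as a single data frame
#' @param slices list returned by [slice_lineages()].
#' @return data frame with `slice_age`, `lineage_id` and one column per axis.
#' @export
sliced_clouds_df <- function(slices) {
  do.call(rbind, lapply(slices, function(s) {
    data.frame(slice_age = s$slice_age, lineage_id = s$lineage_id,
               s$coords, row.names = NULL)
  }))
}
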