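as_distance_matrix <- function(x) {
  if (inherits(x, "dist")) x <- as.matrix(x)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("distances must be numeric")
  if (nrow(x) != ncol(x)) {
    # points-by-axes input: compute Euclidean distances
    return(as.matrix(dist(x)))
  }
  # square input must be a valid distance matrix
  if (!isSymmetric(unname(x), tol = 1e-12)) {
    stop("square input must be a symmetric distance matrix ",
         "(pass dist(points) for a square points matrix)")
  }
  if (any(x < 0)) stop("distance matrix has negative entries")
  if (any(abs(diag(x)) > 1e-12)) stop("distance matrix diagonal must be zero")
  unname(x)
}

#' Enclosing radius of a point cloud
#'
#' The minimum over points of the maximum distance to any other point. At
#' this filtration scale the complex becomes a cone over that point, so
#' every H1 feature has died; it is the default Vietoris-Rips cap because
#' it guarantees finite H1 bars while pruning the cubic triangle count.
#'
#' @param d distance matrix (or points matrix / `dist`).
#' @return a scalar distance.
#' @export
enclosing_radius <- function(d) {
  d <- as_distance_matrix(d)
  if (nrow(d) == 1L) return(0)
  min(apply(d, 1L, max))
}

#' Build a Vietoris-Rips filtration
#'
#' All vertices (value 0), all edges with length at most `max_scale`, and
#' all triangles whose longest edge is at most `max_scale`, each simplex
#' valued at its largest pairwise distance, in the global order
#' (value, dimension, lexicographic vertex tuple). Faces always precede
#' cofaces.
#'
#' @param d symmetric distance matrix with zero diagonal (or a points
#'   matrix, in which case Euclidean distances are used).
#' @param max_scale filtration cap; defaults to the enclosing radius.
#' @return data frame with `order`, `value`, `dim` and vertex ids
#'   `v1..v3` (1-based; `NA` for unused slots).
#' @export
build_filtration <- function(d, max_scale = NULL) {
  d <- as_distance_matrix(d)
  if (is.null(max_scale)) max_scale <- enclosing_radius(d)
  if (max_scale <= 0) stop("max_scale must be positive")
  cpp_build_filtration(d, max_scale)
}

#' Vietoris-Rips persistence diagram (H0 and H1)
#'
#' Computes persistent homology in dimensions 0 and 1 over GF(2) by
#' boundary-matrix column reduction of the Vietoris-Rips filtration, with
#' a representative cycle (the reduced column of the killing triangle) for
#' every finite H1 bar. Zero-persistence bars are dropped from the
#' reported diagram but counted internally.
#'
#' @param x points matrix (rows = points), `dist`, or a symmetric distance
#'   matrix with zero diagonal.
#' @param max_scale filtration cap; defaults to the enclosing radius, at
#'   which every H1 bar is guaranteed finite.
#' @return an object of class `persistence_diagram`: list with `bars` (a
#'   data frame: `dim`, `birth`, `death`, `persistence`, birth/death
#'   simplex vertices), `cycles` (edge matrices for finite H1 bars, indexed
#'   by `bars$cycle_id`), `n_points`, `max_scale` and zero-persistence
#'   counts.
#' @export
rips_diagram <- function(x, max_scale = NULL) {
  d <- as_distance_matrix(x)
  if (is.null(max_scale)) max_scale <- enclosing_radius(d)
  if (max_scale <= 0) stop("max_scale must be positive")
  res <- cpp_rips_persistence(d, max_scale)
  bars <- res$bars
  bars$persistence <- bars$death - bars$birth
  o <- order(bars$dim, bars$birth, bars$death, bars$b1, bars$b2)
  bars <- bars[o, , drop = FALSE]
  rownames(bars) <- NULL
  structure(
    list(bars = bars, cycles = res$cycles, n_points = res$n_points,
         max_scale = res$max_scale,
         n_zero_persistence = c(h0 = res$n_h0_zero, h1 = res$n_h1_zero),
         n_simplices = res$n_simplices),
    class = "persistence_diagram"
  )
}

#' @export
print.persistence_diagram <- function(x, ...) {
  nb <- table(factor(x$bars$dim, levels = 0:1))
  cat("Vietoris-Rips persistence diagram:", x$n_points, "points, cap",
      format(x$max_scale, digits = 4), "\n")
  cat("  H0 bars:", nb[["0"]], " H1 bars:", nb[["1"]],
      " (zero-persistence dropped:", sum(x$n_zero_persistence), ")\n")
  invisible(x)
}

#' Export a persistence diagram as a data frame
#' @param x a `persistence_diagram`.
#' @param ... unused.
#' @return the `bars` data frame plus semicolon-joined cycle vertex ids.
#' @export
as.data.frame.persistence_diagram <- function(x, ...) {
  bars <- x$bars
  bars$cycle_vertices <- vapply(bars$cycle_id, function(ci) {
    if (is.na(ci)) return(NA_character_)
    paste(sort(unique(as.vector(x$cycles[[ci]]))), collapse = ";")
  }, "")
  bars
}

#' Representative cycle of a finite H1 bar
#'
#' The reduced column of the triangle that kills the class: a GF(2)
#' 1-cycle whose largest edge equals the bar's birth. Returns the edge
#' list, the vertex set, and an ordered vertex loop obtained by walking
#' the cycle; the cycle is verified to have zero GF(2) boundary (every
#' vertex has even degree).
#'
#' @param diagram a `persistence_diagram`.
#' @param bar row index into `diagram$bars`.
#' @return list with `edges` (two-column matrix of vertex ids),
#'   `vertices` (sorted unique ids) and `loop` (ordered vertex walk).
#' @export
representative_cycle <- function(diagram, bar) {
  b <- diagram$bars[bar, , drop = FALSE]
  if (nrow(b) != 1L) stop("bar must index a single row of diagram$bars")
  if (b$dim != 1L || !is.finite(b$death)) {
    stop("representative cycles exist only for finite H1 bars")
  }
  edges <- diagram$cycles[[b$cycle_id]]
  deg <- table(as.vector(edges))
  if (any(deg %% 2L != 0L)) stop("internal error: cycle has nonzero boundary")
  loop <- walk_cycle(edges)
  list(edges = edges, vertices = sort(unique(as.vector(edges))), loop = loop)
}

# order the edges of a GF(2) 1-cycle into a vertex walk (the component
# containing the first edge; vertices of degree > 2 are passed through on
# whichever unused edge comes first)
walk_cycle <- function(edges) {
  used <- rep(FALSE, nrow(edges))
  cur <- edges[1L, 1L]
  loop <- cur
  repeat {
    nxt <- which(!used & (edges[, 1L] == cur | edges[, 2L] == cur))
    if (length(nxt) == 0L) break
    e <- nxt[1L]
    used[e] <- TRUE
    cur <- if (edges[e, 1L] == cur) edges[e, 2L] else edges[e, 1L]
    if (cur == loop[1L]) break
    loop <- c(loop, cur)
  }
  loop
}

#' Finite H0 deaths via the minimum spanning tree
#'
#' The finite H0 bar deaths of a Vietoris-Rips filtration are exactly the
#' minimum-spanning-tree edge weights of the point cloud (single-linkage
#' merge heights). Used as a fast independent cross-check of the matrix
#' reduction.
#'
#' @param d distance input as in [rips_diagram()].
#' @return sorted numeric vector of MST edge weights.
#' @export
h0_mst_deaths <- function(d) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  if (n < 2L) return(numeric(0))
  # Prim's algorithm, O(n^2)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- d[1L, ]
  weights <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    weights[i] <- best[j]
    in_tree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  sort(weights)
}
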