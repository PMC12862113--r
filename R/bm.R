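#' Brownian-motion covariance of a phylogeny
#'
#' Under Brownian motion the covariance between two tips is proportional
#' to the path length shared from the root to their most recent common
#' ancestor; the diagonal holds root-to-tip distances. This matrix `C`
#' underlies the generalised-least-squares fit and the ancestral-state
#' conditional means.
#'
#' @param phy a `phylo` tree with branch lengths in My.
#' @return a symmetric positive-semidefinite tips-by-tips matrix (My),
#'   with tip labels as dimnames.
#' @export
phylo_covariance <- function(phy) {
  validate_dated_tree(phy)
  ape::vcv(phy)
}

# Cholesky with a tiny diagonal ridge only when the plain factorisation
# fails (e.g. zero-length cherries making C singular).
chol_or_regularise <- function(C, root_age) {
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  ridge <- 1e-10 * root_age
  ch <- tryCatch(chol(C + diag(ridge, nrow(C))), error = function(e) NULL)
  if (is.null(ch)) {
    stop("phylogenetic covariance is singular even after regularisation; ",
         "consider enforcing a minimum branch length")
  }
  ch
}

align_tip_values <- function(phy, tip_values) {
  n <- ape::Ntip(phy)
  x <- as.matrix(tip_values)
  if (!is.null(rownames(x)) && all(phy$tip.label %in% rownames(x))) {
    x <- x[phy$tip.label, , drop = FALSE]
  } else if (nrow(x) != n) {
    stop("tip values must be named by tip label or given in tip order")
  }
  if (anyNA(x) || any(!is.finite(x))) stop("tip values must be finite")
  x
}

#' Fit Brownian motion to tip values by generalised least squares
#'
#' Each axis (column) is fitted independently. The root state is the GLS
#' mean \eqn{\hat a = (1'C^{-1}1)^{-1} 1'C^{-1} x} and the rate is the
#' maximum-likelihood estimate
#' \eqn{\hat\sigma^2 = (x - \hat a 1)' C^{-1} (x - \hat a 1) / n}.
#'
#' @param phy a `phylo` tree.
#' @param tip_values numeric vector or matrix (tips x axes), named by tip
#'   label or in tip order.
#' @return an object of class `bm_fit`: list with `root_state`, `sigma2`
#'   (per-axis, in axis units squared per My) and `log_likelihood`.
#' @export
fit_bm <- function(phy, tip_values) {
  x <- align_tip_values(phy, tip_values)
  n <- nrow(x)
  if (n < 2L) stop("at least two tips are required")
  C <- phylo_covariance(phy)
  root_age <- max(node_ages(phy))
  ch <- chol_or_regularise(C, root_age)
  ones <- rep(1, n)
  Cinv_x <- backsolve(ch, forwardsolve(t(ch), x))
  Cinv_1 <- backsolve(ch, forwardsolve(t(ch), ones))
  denom <- sum(Cinv_1)
  a <- drop(crossprod(Cinv_1, x)) / denom
  resid <- sweep(x, 2L, a)
  Cinv_r <- backsolve(ch, forwardsolve(t(ch), resid))
  s2 <- colSums(resid * Cinv_r) / n
  logdetC <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * (n * log(2 * pi * s2) + logdetC + n)
  structure(
    list(root_state = a, sigma2 = s2, log_likelihood = ll,
         n_tips = n, tip_labels = rownames(C)),
    class = "bm_fit"
  )
}

#' @export
print.bm_fit <- function(x, ...) {
  cat("Brownian-motion GLS fit:", length(x$sigma2), "axis/axes,",
      x$n_tips, "tips\n")
  print(data.frame(root_state = x$root_state, sigma2 = x$sigma2,
                   log_likelihood = x$log_likelihood))
  invisible(x)
}

#' Ancestral state reconstruction under Brownian motion
#'
#' Internal-node values are the conditional expectations of the node
#' states given the tip values,
#' \eqn{\mu = \hat a + C_{node,tips} C_{tips}^{-1} (x - \hat a 1)},
#' where covariances are shared path lengths from the root. This equals
#' the GLS root estimate of the tree re-rooted at each node. Tips pass
#' through unchanged.
#'
#' @param phy a `phylo` tree.
#' @param tip_values tip values as in [fit_bm()].
#' @param fit optional [fit_bm()] result for the same data; refitted when
#'   missing.
#' @return a `node_states` matrix with one row per node (`ape` node ids
#'   `1..2n-1`) and one column per axis; attribute `node_age` holds ages.
#' @export
reconstruct_ancestral_states <- function(phy, tip_values, fit = NULL) {
  x <- align_tip_values(phy, tip_values)
  if (is.null(fit)) fit <- fit_bm(phy, x)
  n <- ape::Ntip(phy)
  n_node <- n + phy$Nnode
  depth <- ape::node.depth.edgelength(phy)
  ages <- node_ages(phy)
  C <- phylo_covariance(phy)
  ch <- chol_or_regularise(C, max(ages))
  resid <- sweep(x, 2L, fit$root_state)
  Cinv_r <- backsolve(ch, forwardsolve(t(ch), resid))

  # shared path length between each internal node and each tip = depth of
  # their most recent common ancestor
  mr <- ape::mrca(phy, full = TRUE)
  internal <- (n + 1L):n_node
  C_nt <- matrix(depth[mr[internal, seq_len(n), drop = FALSE]],
                 nrow = length(internal))
  anc <- sweep(C_nt %*% Cinv_r, 2L, fit$root_state, `+`)

  out <- matrix(NA_real_, n_node, ncol(x))
  out[seq_len(n), ] <- x
  out[internal, ] <- anc
  rownames(out) <- c(phy$tip.label, paste0("node_", internal))
  colnames(out) <- colnames(x)
  structure(out, node_age = ages, class = c("node_states", "matrix"))
}

#' Simulate Brownian motion on a tree
#'
#' Recursive simulation from the root to the tips: the increment along a
#' branch of length `t` is Normal(0, `sigma2 * t`). Axes are simulated
#' independently, each from its own deterministic seed stream derived from
#' `seed`.
#'
#' @param phy a `phylo` tree.
#' @param root_state numeric vector, one value per axis.
#' @param sigma2 numeric vector of rates (axis units squared per My),
#'   recycled against `root_state`.
#' @param seed integer master seed; axis `j` uses a stream derived from
#'   `(seed, 0, j)`.
#' @return a `node_states` matrix covering every node (tips included).
#' @export
simulate_bm <- function(phy, root_state, sigma2, seed = 1L) {
  validate_dated_tree(phy)
  k <- max(length(root_state), length(sigma2))
  root_state <- rep_len(root_state, k)
  sigma2 <- rep_len(sigma2, k)
  if (any(sigma2 < 0)) stop("sigma2 must be nonnegative")
  n <- ape::Ntip(phy)
  n_node <- n + phy$Nnode
  phy_cw <- reorder(phy, "cladewise") # parents precede children
  root <- n + 1L
  out <- matrix(NA_real_, n_node, k)
  for (j in seq_len(k)) {
    set.seed(derive_seed(seed, 0L, j))
    eps <- rnorm(nrow(phy_cw$edge), 0, sqrt(sigma2[j] * phy_cw$edge.length))
    v <- rep(NA_real_, n_node)
    v[root] <- root_state[j]
    for (e in seq_len(nrow(phy_cw$edge))) {
      v[phy_cw$edge[e, 2L]] <- v[phy_cw$edge[e, 1L]] + eps[e]
    }
    out[, j] <- v
  }
  rownames(out) <- c(phy$tip.label, paste0("node_", (n + 1L):n_node))
  colnames(out) <- paste0("axis_", seq_len(k))
  structure(out, node_age = node_ages(phy), class = c("node_states", "matrix"))
}

#' Tip rows of a node-states matrix
#' @param states a `node_states` matrix.
#' @param phy the tree it was computed on.
#' @return the tips-by-axes submatrix, rownames = tip labels.
#' @export
tip_states <- function(states, phy) {
  unclass(states)[seq_len(ape::Ntip(phy)), , drop = FALSE]
}

#' Export node states as a data frame
#' @param x a `node_states` matrix.
#' @param ... unused.
#' @return data frame with `node_id`, one column per axis, and `node_age`.
#' @export
as.data.frame.node_states <- function(x, ...) {
  m <- unclass(x)
  attr(m, "node_age") <- NULL
  df <- data.frame(node_id = seq_len(nrow(m)), m, row.names = NULL)
  df$node_age <- attr(x, "node_age")
  df
}
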