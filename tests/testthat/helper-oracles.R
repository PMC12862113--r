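# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: Betti numbers by exhaustive GF(2) linear
# algebra, covariances by naive root walks, likelihoods by direct
# multivariate-normal evaluation.

# rank of a 0/1 matrix over GF(2) by Gaussian elimination
gf2_rank <- function(M) {
  if (length(M) == 0L) return(0L)
  M <- M %% 2L
  r <- 0L
  nr <- nrow(M); nc <- ncol(M)
  for (j in seq_len(nc)) {
    piv <- which(M[, j] == 1L & seq_len(nr) > r)
    if (length(piv) == 0L) next
    r <- r + 1L
    if (piv[1L] != r) M[c(r, piv[1L]), ] <- M[c(piv[1L], r), ]
    hit <- which(M[, j] == 1L & seq_len(nr) != r)
    if (length(hit) > 0L) M[hit, ] <- (M[hit, , drop = FALSE] + rep(M[r, ], each = length(hit))) %% 2L
    if (r == nr) break
  }
  r
}

# Betti numbers (beta0, beta1) of the Vietoris-Rips complex at scale r,
# from ranks of the boundary maps
betti_at_scale <- function(d, r) {
  n <- nrow(d)
  edges <- which(upper.tri(d) & d <= r, arr.ind = TRUE)
  ne <- nrow(edges)
  tris <- if (n >= 3L) t(combn(n, 3)) else matrix(0L, 0L, 3L)
  if (nrow(tris) > 0L) {
    tv <- apply(tris, 1L, function(t_) max(d[t_[1], t_[2]], d[t_[1], t_[3]],
                                           d[t_[2], t_[3]]))
    tris <- tris[tv <= r, , drop = FALSE]
  }
  nt <- nrow(tris)
  b1 <- matrix(0L, n, ne)
  if (ne > 0L) {
    for (e in seq_len(ne)) b1[edges[e, ], e] <- 1L
  }
  ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  eidx <- setNames(seq_len(ne), ekey(edges[, 1L], edges[, 2L]))
  b2 <- matrix(0L, ne, nt)
  if (nt > 0L) {
    for (t_ in seq_len(nt)) {
      v <- tris[t_, ]
      b2[eidx[c(ekey(v[1], v[2]), ekey(v[1], v[3]), ekey(v[2], v[3]))], t_] <- 1L
    }
  }
  r1 <- gf2_rank(b1)
  r2 <- gf2_rank(b2)
  c(beta0 = n - r1, beta1 = (ne - r1) - r2)
}

# bars alive at scale r (born at or before r, dead strictly after)
bars_alive_at <- function(bars, r, dimension) {
  sum(bars$dim == dimension & bars$birth <= r & bars$death > r)
}

# tip-tip shared path length by naive root walks
naive_phylo_covariance <- function(phy) {
  n <- ape::Ntip(phy)
  root <- n + 1L
  path_edges <- function(tip) {
    e <- integer(0)
    v <- tip
    while (v != root) {
      row <- which(phy$edge[, 2L] == v)
      e <- c(e, row)
      v <- phy$edge[row, 1L]
    }
    e
  }
  paths <- lapply(seq_len(n), path_edges)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C[i, j] <- sum(phy$edge.length[intersect(paths[[i]], paths[[j]])])
    }
  }
  dimnames(C) <- list(phy$tip.label, phy$tip.label)
  C
}

# direct multivariate-normal log likelihood of tip values under BM
bm_loglik_direct <- function(phy, x, root, sigma2) {
  C <- naive_phylo_covariance(phy)
  V <- sigma2 * C
  n <- length(x)
  r <- x - root
  -0.5 * (n * log(2 * pi) + determinant(V, logarithm = TRUE)$modulus +
            drop(t(r) %*% solve(V, r)))
}

# brute-force ML fit by numerical optimisation over (root, log sigma2)
bm_fit_bruteforce <- function(phy, x) {
  nll <- function(p) -bm_loglik_direct(phy, x, p[1L], exp(p[2L]))
  o <- optim(c(mean(x), 0), nll, method = "Nelder-Mead",
             control = list(reltol = 1e-14, maxit = 5000))
  list(root = o$par[1L], sigma2 = exp(o$par[2L]), loglik = -o$value)
}

# random non-ultrametric test tree with reproducible shape
random_tree <- function(n, seed) {
  set.seed(seed)
  phy <- ape::rtree(n)
  phy$edge.length <- phy$edge.length + 0.1
  phy
}
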