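#' Noisy circle point cloud
#'
#' Points at uniformly spaced angles on a circle, with Gaussian radial
#' noise, optionally zero-padded into a higher-dimensional ambient space
#' (an isometric embedding, so the persistence diagram is unchanged).
#' A clean circle carries exactly one H1 class.
#'
#' @param n number of points (>= 4).
#' @param radius circle radius.
#' @param noise_sd SD of the radial Gaussian noise.
#' @param seed integer seed.
#' @param dim ambient dimension (>= 2); extra coordinates are 0.
#' @return an `n` x `dim` matrix.
#' @export
make_circle_cloud <- function(n, radius = 1, noise_sd = 0, seed = 1L,
                              dim = 2L) {
  if (n < 4L) stop("n must be at least 4")
  set.seed(derive_seed(seed))
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  r <- radius + rnorm(n, 0, noise_sd)
  out <- matrix(0, n, dim)
  out[, 1L] <- r * cos(theta)
  out[, 2L] <- r * sin(theta)
  out
}

#' Random pure-birth (Yule) tree of fixed depth
#'
#' A Yule tree conditioned on the tip count, rescaled so the root age is
#' exactly `depth_my`. Ultrametric by construction.
#'
#' @param n_tips number of tips (>= 2).
#' @param depth_my total tree depth in My.
#' @param seed integer seed.
#' @return a `phylo` tree.
#' @export
make_pure_birth_tree <- function(n_tips, depth_my = 10, seed = 1L) {
  if (n_tips < 2L) stop("n_tips must be at least 2")
  set.seed(derive_seed(seed))
  phy <- ape::rphylo(n_tips, birth = 1, death = 0)
  root_age <- max(node_ages(phy))
  phy$edge.length <- phy$edge.length * depth_my / root_age
  phy
}

#' Brownian-motion dataset with a planted morphospace hole
#'
#' Simulates multivariate Brownian motion on a Yule tree and then enforces
#' a "forbidden" hypersphere in score space that extant tips avoid — a
#' planted gap with known centre and radius for testing the detector. Only
#' tip values are modified: ancestral reconstructions then smooth over the
#' hole naturally, mimicking the empirical situation where ancestors are
#' inferred rather than observed. The untouched simulation is returned as
#' a paired control.
#'
#' Enforcement modes: `"push"` (default) moves offending tips radially out
#' to the hole boundary, evoking displacement of species at the edge of a
#' forbidden trait region; `"reject"` re-draws the terminal-branch BM
#' increment of each offending tip until it lands outside the hole
#' (bounded retries). Rejection suits holes that are small relative to the
#' terminal-branch variance; for larger holes a tip whose parent sits deep
#' inside the hole at the end of a short branch may be unable to escape,
#' in which case the generator stops with an error rather than silently
#' changing the sampling scheme.
#'
#' @param centre hole centre (length-k numeric, PC units).
#' @param radius hole radius (PC units); should be small relative to the
#'   cloud spread (at most ~1 SD of the tip scores).
#' @param mode `"reject"` or `"push"`.
#' @param n_tips,depth_my,seed tree/simulation parameters.
#' @param sigma2 per-axis BM rate (recycled to `length(centre)`).
#' @param root_state per-axis root value (defaults to the hole centre, so
#'   the hole sits in the densest part of the cloud).
#' @param max_retries per-tip rejection budget in `"reject"` mode.
#' @return list with `tree`, `tips` (hole-enforced tip scores),
#'   `control_tips` (the untouched BM draw), `states` (untouched full
#'   simulation) and `spec` (the generator settings, echoed for
#'   provenance).
#' @export
make_planted_gap_dataset <- function(centre = c(0, 0), radius = 1.5,
                                     mode = c("push", "reject"),
                                     n_tips = 150L, depth_my = 10,
                                     sigma2 = 1, seed = 1L,
                                     root_state = centre,
                                     max_retries = 500L) {
  mode <- match.arg(mode)
  if (radius < 0) stop("radius must be nonnegative")
  k <- length(centre)
  sigma2 <- rep_len(sigma2, k)
  root_state <- rep_len(root_state, k)
  tree <- make_pure_birth_tree(n_tips, depth_my, seed = derive_seed(seed, 1L))
  states <- simulate_bm(tree, root_state, sigma2, seed = derive_seed(seed, 2L))
  tips <- tip_states(states, tree)
  control <- tips
  tip_sd <- mean(apply(tips, 2L, sd))
  if (radius > tip_sd) {
    warning("hole radius (", radius, ") exceeds ~1 SD of tip scores (",
            format(tip_sd, digits = 3), "); detection may be trivial")
  }
  d <- sqrt(rowSums(sweep(tips, 2L, centre)^2))
  inside <- which(d < radius)
  if (length(inside) > 0L && radius > 0) {
    ages <- node_ages(tree)
    parent_of <- tree$edge[match(seq_len(n_tips), tree$edge[, 2L]), 1L]
    set.seed(derive_seed(seed, 3L))
    if (mode == "push") {
      for (i in inside) {
        v <- tips[i, ] - centre
        nv <- sqrt(sum(v^2))
        if (nv == 0) v <- c(1, rep(0, k - 1L)) else v <- v / nv
        tips[i, ] <- centre + v * radius
      }
    } else {
      for (i in inside) {
        plen <- ages[parent_of[i]] - ages[i]
        pval <- unclass(states)[parent_of[i], ]
        ok <- FALSE
        for (try in seq_len(max_retries)) {
          cand <- pval + rnorm(k, 0, sqrt(sigma2 * plen))
          if (sqrt(sum((cand - centre)^2)) >= radius) {
            tips[i, ] <- cand
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop("rejection sampling failed for tip ", i, " after ",
               max_retries, " retries; use a smaller hole radius")
        }
      }
    }
  }
  list(tree = tree, tips = tips, control_tips = control, states = states,
       spec = list(centre = centre, radius = radius, mode = mode,
                   n_tips = n_tips, depth_my = depth_my, sigma2 = sigma2,
                   root_state = root_state, seed = seed))
}
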