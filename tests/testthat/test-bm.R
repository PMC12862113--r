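test_that("phylogenetic covariance equals shared path lengths", {
  phy <- read_newick("((A:1,B:1):1,C:2);")
  C <- phylo_covariance(phy)
  expect_equal(unname(C[c("A", "B", "C"), c("A", "B", "C")]),
               rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))

  star <- ape::stree(5, "star")
  star$edge.length <- rep(3, 5)
  expect_equal(unname(phylo_covariance(star)), diag(3, 5))

  rt <- random_tree(8, seed = 11)
  expect_equal(phylo_covariance(rt), naive_phylo_covariance(rt),
               tolerance = 1e-12)
  ev <- eigen(phylo_covariance(rt), symmetric = TRUE, only.values = TRUE)
  expect_true(all(ev$values > -1e-10))
  expect_equal(unname(diag(phylo_covariance(rt))),
               unname(ape::node.depth.edgelength(rt)[1:8]))
})

test_that("GLS Brownian fit matches closed forms and brute-force ML", {
  t2 <- read_newick("(A:1,B:1);")
  f <- fit_bm(t2, setNames(c(0, 2), c("A", "B")))
  expect_equal(unname(f$root_state), 1)
  expect_equal(unname(f$sigma2), 1)

  t3 <- read_newick("(A:1,B:3);")
  f3 <- fit_bm(t3, setNames(c(0, 4), c("A", "B")))
  expect_equal(unname(f3$root_state), (0 / 1 + 4 / 3) / (1 / 1 + 1 / 3))

  for (seed in c(3, 7, 21)) {
    phy <- random_tree(6, seed)
    set.seed(seed + 100)
    x <- setNames(rnorm(6, sd = 2), phy$tip.label)
    mine <- fit_bm(phy, x)
    bf <- bm_fit_bruteforce(phy, x)
    expect_equal(unname(mine$root_state), bf$root, tolerance = 1e-4)
    expect_equal(unname(mine$sigma2), bf$sigma2, tolerance = 1e-4)
    expect_equal(unname(mine$log_likelihood), bf$loglik, tolerance = 1e-6)
  }
})

test_that("ancestral states are BM conditional means", {
  t2 <- read_newick("(A:1,B:1);")
  st <- reconstruct_ancestral_states(t2, setNames(c(0, 2), c("A", "B")))
  expect_equal(unname(unclass(st)[3L, 1L]), 1)

  star <- ape::stree(6, "star")
  star$edge.length <- rep(2, 6)
  x <- setNames(c(1, 4, -2, 0.5, 3, -1), star$tip.label)
  st2 <- reconstruct_ancestral_states(star, x)
  expect_equal(unname(unclass(st2)[7L, 1L]), mean(x))

  # independent route: re-root at each internal node; the GLS root of the
  # re-rooted tree is the node's conditional expectation
  phy <- random_tree(6, seed = 42)
  set.seed(1); x <- setNames(rnorm(6), phy$tip.label)
  mine <- reconstruct_ancestral_states(phy, x)
  expect_equal(unname(unclass(mine)[7L, 1L]),
               unname(fit_bm(phy, x)$root_state), tolerance = 1e-10)
  for (node in (8:11)) {
    rr <- ape::root(phy, node = node, resolve.root = FALSE)
    expect_equal(unname(unclass(mine)[node, 1L]),
                 unname(fit_bm(rr, x)$root_state),
                 tolerance = 1e-8)
  }
  skip_if_not_installed("phytools")
  fa <- phytools::fastAnc(phy, x)
  expect_equal(unname(unclass(mine)[7:11, 1L]), unname(as.numeric(fa)),
               tolerance = 1e-8)
})

test_that("reconstruction is linear and shift-equivariant in tip values", {
  phy <- random_tree(7, seed = 9)
  set.seed(2)
  x <- setNames(rnorm(7), phy$tip.label)
  y <- setNames(rnorm(7), phy$tip.label)
  sx <- unclass(reconstruct_ancestral_states(phy, x))
  sy <- unclass(reconstruct_ancestral_states(phy, y))
  sxy <- unclass(reconstruct_ancestral_states(phy, 0.3 * x + 0.7 * y))
  expect_equal(sxy, 0.3 * sx + 0.7 * sy, tolerance = 1e-10)
  sshift <- unclass(reconstruct_ancestral_states(phy, x + 5))
  expect_equal(sshift, sx + 5, tolerance = 1e-10)
})

test_that("BM simulation reproduces the model's moments", {
  # zero-length branch: child equals parent
  phy <- read_newick("((A:0,B:1):1,C:2);")
  sim <- simulate_bm(phy, 0, 1, seed = 4)
  parentA <- phy$edge[phy$edge[, 2L] == 1L, 1L]
  expect_identical(unclass(sim)[1L, 1L], unclass(sim)[parentA, 1L])

  # star tree: Var(tips) ~ sigma2 * depth
  star <- ape::stree(2000, "star")
  depth <- 3
  star$edge.length <- rep(depth, 2000)
  sim2 <- simulate_bm(star, 0, 1, seed = 5)
  v <- var(unclass(sim2)[1:2000, 1L])
  expect_gt(v, 0.9 * depth)
  expect_lt(v, 1.1 * depth)

  # sister pair sharing path s: Cov ~ sigma2 * s
  cherry <- read_newick("((A:1,B:1):2,C:3);")
  reps <- vapply(1:3000, function(r) {
    s <- simulate_bm(cherry, 0, 1, seed = r)
    unclass(s)[1:2, 1L]
  }, numeric(2))
  cv <- cov(reps[1L, ], reps[2L, ])
  expect_gt(cv, 2 - 0.25)
  expect_lt(cv, 2 + 0.25)

  # determinism under fixed seed
  expect_identical(simulate_bm(cherry, c(0, 1), c(1, 2), seed = 99),
                   simulate_bm(cherry, c(0, 1), c(1, 2), seed = 99))
})
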