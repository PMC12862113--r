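square_loop_cloud <- function(n_extra = 30, seed = 1) {
  set.seed(seed)
  corners <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  rbind(corners, matrix(runif(2 * n_extra, 2, 6), ncol = 2))
}

test_that("gap metrics follow their definitions", {
  cloud <- square_loop_cloud(30)
  g <- characterize_gap(list(birth = 0.5, death = 1.0), 1:4, cloud,
                        slice_age = 0)
  expect_equal(g$persistence, 0.5)
  expect_equal(unname(g$centroid), c(0, 0))
  expect_equal(g$size, sqrt(2))
  # sparsity: mean distance from the centroid to the k nearest points
  k <- ceiling(0.05 * nrow(cloud))
  d <- sort(sqrt(rowSums(sweep(cloud, 2, c(0, 0))^2)))
  expect_equal(g$sparsity, mean(d[seq_len(k)]))

  # the 5% rule gives 69 neighbours for 1378 points
  set.seed(2)
  big <- matrix(rnorm(1378 * 2), 1378)
  gb <- characterize_gap(list(birth = 0.5, death = 1.0), 1:4, big)
  expect_identical(gb$k_sparsity, 69L)
})

test_that("gap metrics are rigid-motion invariant and scale linearly", {
  cloud <- square_loop_cloud(40, seed = 3)
  bar <- list(birth = 0.6, death = 1.4)
  g0 <- characterize_gap(bar, 1:4, cloud)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  g1 <- characterize_gap(bar, 1:4, sweep(cloud %*% R, 2, c(5, -2), `+`))
  expect_equal(g1$persistence, g0$persistence)
  expect_equal(g1$size, g0$size, tolerance = 1e-12)
  expect_equal(g1$sparsity, g0$sparsity, tolerance = 1e-12)

  c_ <- 2.5
  g2 <- characterize_gap(list(birth = c_ * 0.6, death = c_ * 1.4), 1:4,
                         c_ * cloud)
  expect_equal(g2$persistence, c_ * g0$persistence)
  expect_equal(g2$size, c_ * g0$size, tolerance = 1e-12)
  expect_equal(g2$sparsity, c_ * g0$sparsity, tolerance = 1e-12)
})

test_that("a planted annulus hole is located accurately", {
  hits <- vapply(1:20, function(seed) {
    cloud <- make_circle_cloud(60, radius = 1, noise_sd = 0.08, seed = seed)
    dg <- rips_diagram(cloud)
    gaps <- gaps_from_diagram(dg, cloud, slice_age = 0)
    top <- gaps[[1L]] # ordered by descending persistence
    sqrt(sum(top$centroid^2)) <= 0.2 * (1 - 2 * 0.08)
  }, TRUE)
  expect_true(all(hits))
})

test_that("notable gaps use a strict persistence threshold", {
  mk <- function(p) structure(list(persistence = p), class = "gap")
  gaps <- lapply(c(0.39, 0.40, 0.41), mk)
  kept <- notable_gaps(gaps, threshold = 0.4)
  expect_equal(length(kept), 1L)
  expect_equal(kept[[1L]]$persistence, 0.41)
  expect_equal(attr(kept, "fraction_retained"), 1 / 3)
  expect_equal(length(notable_gaps(list())), 0L)

  # thresholding at the 99.5th percentile of simulated persistences keeps ~0.5%
  set.seed(4)
  ps <- rexp(200, rate = 10)
  thr <- quantile(ps, 0.995)
  kept2 <- notable_gaps(lapply(ps, mk), threshold = thr)
  expect_equal(length(kept2), sum(ps > thr))
  expect_lte(length(kept2), 2L)
})

test_that("series linking follows the centroid-distance rule", {
  mk <- function(age, cx, p = 1) {
    structure(list(slice_age = age, birth = 1, death = 1 + p,
                   persistence = p, vertices = 1:3,
                   centroid = c(cx, 0, 0, 0), size = 1, sparsity = 1),
              class = "gap")
  }
  # within 1 unit: linked, lifespan 1 My
  res <- link_gap_series(list(mk(0, 0), mk(1, 0.5)))
  expect_equal(nrow(res$series), 1L)
  expect_equal(res$series$lifespan_my, 1)

  # 1.2 apart: two singleton series of lifespan 0
  res2 <- link_gap_series(list(mk(0, 0), mk(1, 1.2)))
  expect_equal(nrow(res2$series), 2L)
  expect_equal(res2$series$lifespan_my, c(0, 0))

  # greedy nearest-first matching equals exhaustive minimum matching here:
  # slice 0 gaps at x = 0, 0.8; slice 1 gaps at x = 0.3, 0.9
  res3 <- link_gap_series(list(mk(0, 0), mk(0, 0.8), mk(1, 0.3), mk(1, 0.9)))
  tab <- res3$gaps
  sid <- function(x, a) tab$series_id[tab$centroid_1 == x & tab$slice_age == a]
  expect_equal(sid(0, 0), sid(0.3, 1))   # pair distance 0.3 chosen first
  expect_equal(sid(0.8, 0), sid(0.9, 1)) # then 0.1... greedy order: 0.1 first
  # exhaustive check over both possible one-to-one assignments: greedy picks
  # {0-0.3, 0.8-0.9} (total 0.4) over {0-0.9, 0.8-0.3} (total 1.4)
  expect_equal(nrow(res3$series), 2L)

  # multi-slice chain: 0 -> 1 -> 2 gives lifespan 2
  res4 <- link_gap_series(list(mk(0, 0), mk(1, 0.4), mk(2, 0.8)))
  expect_equal(res4$series$lifespan_my, 2)
  expect_equal(res4$series$n_gaps, 3L)
})

test_that("series lifespans never grow when the link radius shrinks", {
  set.seed(6)
  mk <- function(age, c2) {
    structure(list(slice_age = age, birth = 1, death = 2, persistence = 1,
                   vertices = 1:3, centroid = c2, size = 1, sparsity = 1),
              class = "gap")
  }
  gaps <- unlist(lapply(0:5, function(a) {
    lapply(seq_len(3), function(i) mk(a, rnorm(2, sd = 0.8)))
  }), recursive = FALSE)
  radii <- c(1.5, 1.0, 0.5, 0.25)
  max_life <- vapply(radii, function(r) {
    max(link_gap_series(gaps, link_radius = r)$series$lifespan_my)
  }, 0)
  expect_true(all(diff(max_life) <= 0))
})

test_that("species are classified by scaled centroid distance", {
  g <- structure(list(centroid = c(0, 0), size = 2), class = "gap")
  scores <- rbind(at_centroid = c(0, 0),
                  band = c(1.5, 0),   # d = 0.75 * size
                  boundary = c(2, 0), # d = size exactly
                  far = c(5, 5))
  lab <- classify_species(g, scores)
  expect_equal(as.character(lab),
               c("within", "near", "near", "outside"))
  expect_error(classify_species(g, matrix(0, 2, 3)), "axes")
})
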