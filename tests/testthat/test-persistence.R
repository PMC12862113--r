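test_that("filtration contains the right simplices in the right order", {
  # 3 points pairwise distance 1
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  f <- build_filtration(d3, max_scale = 2)
  expect_equal(sum(f$dim == 0L), 3L)
  expect_equal(sum(f$dim == 1L), 3L)
  expect_equal(sum(f$dim == 2L), 1L)
  expect_equal(f$value[f$dim == 2L], 1)

  # unit square, cap 1.2: diagonals sqrt(2) excluded, no triangles
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  f2 <- build_filtration(sq, max_scale = 1.2)
  expect_equal(sum(f2$dim == 1L), 4L)
  expect_equal(sum(f2$dim == 2L), 0L)

  # cap = diameter: complete counts n, C(n,2), C(n,3)
  set.seed(21)
  pts <- matrix(rnorm(24), 12)
  f3 <- build_filtration(pts, max_scale = max(dist(pts)))
  expect_equal(as.integer(table(f3$dim)), c(12L, 66L, 220L))

  # faces precede cofaces; global order sorted by (value, dim, vertices)
  expect_true(all(diff(f3$order) == 1L))
  expect_true(all(f3$value == cummax(f3$value)))
  for (i in which(f3$dim == 2L)) {
    for (pair in list(c("v1", "v2"), c("v1", "v3"), c("v2", "v3"))) {
      j <- which(f3$dim == 1L & f3$v1 == f3[[pair[1]]][i] &
                   f3$v2 == f3[[pair[2]]][i])
      expect_lt(j, i)
    }
  }

  expect_error(build_filtration(matrix(c(0, 1, 2, 0), 2), 1), "symmetric|negative|diag")
})

test_that("reduction reproduces closed-form diagrams", {
  # unit square: one H1 bar (1, sqrt(2)); H0 deaths all 1
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  dg <- rips_diagram(sq, max_scale = 2)
  h1 <- dg$bars[dg$bars$dim == 1L, ]
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$birth, 1)
  expect_equal(h1$death, sqrt(2))
  h0 <- dg$bars[dg$bars$dim == 0L & is.finite(dg$bars$death), ]
  expect_equal(h0$death, rep(1, 3))

  # two points at distance d: H0 bars (0, d) and (0, Inf)
  two <- matrix(c(0, 3), ncol = 1)
  d2 <- rips_diagram(two, max_scale = 5)
  expect_equal(d2$bars$dim, c(0L, 0L))
  expect_equal(d2$bars$death, c(3, Inf))

  # 20 points on a circle: exactly one positive-persistence H1 bar
  circ <- make_circle_cloud(20)
  dc <- rips_diagram(circ)
  expect_equal(sum(dc$bars$dim == 1L), 1L)
  expect_gt(dc$bars$persistence[dc$bars$dim == 1L], 0)
})

test_that("bars alive at any scale match exhaustive GF(2) Betti numbers", {
  # includes the square checked at scales 0.9 / 1.1 / 1.5
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  dsq <- as.matrix(dist(sq))
  dg <- rips_diagram(sq, max_scale = 2)
  for (r in c(0.9, 1.1, 1.5)) {
    b <- betti_at_scale(dsq, r)
    expect_equal(bars_alive_at(dg$bars, r, 0L), unname(b["beta0"]))
    expect_equal(bars_alive_at(dg$bars, r, 1L), unname(b["beta1"]))
  }
  for (seed in c(1, 2)) {
    set.seed(seed)
    pts <- matrix(runif(2 * 12), 12)
    d <- as.matrix(dist(pts))
    cap <- max(d)
    dg <- rips_diagram(d, max_scale = cap)
    for (r in unique(sort(d[upper.tri(d)]))) {
      b <- betti_at_scale(d, r)
      expect_equal(bars_alive_at(dg$bars, r, 0L), unname(b["beta0"]))
      expect_equal(bars_alive_at(dg$bars, r, 1L), unname(b["beta1"]))
    }
  }
})

test_that("representative cycles are true cycles born at the bar's birth", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  dg <- rips_diagram(sq, max_scale = 2)
  rc <- representative_cycle(dg, which(dg$bars$dim == 1L))
  expect_setequal(rc$vertices, 1:4)
  expect_equal(nrow(rc$edges), 4L)
  expect_equal(length(rc$loop), 4L)

  # equilateral triangle is contractible: no finite H1 bar to query
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  dt <- rips_diagram(d3, max_scale = 2)
  expect_equal(sum(dt$bars$dim == 1L), 0L)
  expect_error(representative_cycle(dt, 1L), "H1")

  # rim of a circle with an early-connected centre point: the cycle still
  # runs through rim points only
  rim <- make_circle_cloud(12)
  cloud <- rbind(rim, c(0, 0))
  dgc <- rips_diagram(cloud)
  h1 <- which(dgc$bars$dim == 1L & dgc$bars$persistence > 0.2)
  expect_equal(length(h1), 1L)
  rcc <- representative_cycle(dgc, h1)
  # max edge length of the cycle equals the birth
  dmat <- as.matrix(dist(cloud))
  elens <- apply(rcc$edges, 1L, function(e) dmat[e[1L], e[2L]])
  expect_equal(max(elens), dgc$bars$birth[h1])
  # zero GF(2) boundary: every vertex has even degree
  expect_true(all(table(as.vector(rcc$edges)) %% 2 == 0))
})

test_that("finite H0 deaths equal minimum-spanning-tree edge weights", {
  # collinear points 0, 1, 3: merge heights 1 and 2
  x <- matrix(c(0, 1, 3), ncol = 1)
  expect_equal(h0_mst_deaths(as.matrix(dist(x))), c(1, 2))
  expect_equal(h0_mst_deaths(matrix(0, 1, 1)), numeric(0))

  set.seed(31)
  pts <- matrix(rnorm(80), 40)
  dg <- rips_diagram(pts)
  h0 <- sort(dg$bars$death[dg$bars$dim == 0L & is.finite(dg$bars$death)])
  expect_equal(h0, h0_mst_deaths(pts), tolerance = 1e-12)
  skip_if_not_installed("vegan")
  expect_equal(h0, sort(vegan::spantree(dist(pts))$dist), tolerance = 1e-12)
})

test_that("the enclosing-radius cap leaves no infinite H1 bar", {
  for (seed in 1:5) {
    set.seed(seed)
    pts <- matrix(rnorm(60), 30)
    dg <- rips_diagram(pts) # default cap = enclosing radius
    h1 <- dg$bars[dg$bars$dim == 1L, ]
    expect_true(all(is.finite(h1$death)))
  }
})

test_that("small perturbations move endpoints by at most twice their size", {
  set.seed(41)
  pts <- matrix(rnorm(50), 25)
  eps <- 0.005
  pert <- pts + matrix(runif(50, -eps / sqrt(2), eps / sqrt(2)), 25)
  cap <- max(dist(pts)) + 1
  b1 <- rips_diagram(pts, max_scale = cap)$bars
  b2 <- rips_diagram(pert, max_scale = cap)$bars
  h1a <- b1[b1$dim == 1L & b1$persistence > 4 * eps, ]
  h1b <- b2[b2$dim == 1L & b2$persistence > 4 * eps, ]
  expect_equal(nrow(h1a), nrow(h1b))
  o1 <- order(-h1a$persistence); o2 <- order(-h1b$persistence)
  expect_true(all(abs(h1a$birth[o1] - h1b$birth[o2]) <= 2 * eps + 1e-12))
  expect_true(all(abs(h1a$death[o1] - h1b$death[o2]) <= 2 * eps + 1e-12))
})

test_that("zero-padding into higher dimensions leaves the diagram unchanged", {
  c2 <- make_circle_cloud(16, seed = 7, noise_sd = 0.05)
  c4 <- cbind(c2, 0, 0)
  cap <- max(dist(c2))
  expect_equal(rips_diagram(c2, cap)$bars, rips_diagram(c4, cap)$bars,
               tolerance = 1e-12)
})
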