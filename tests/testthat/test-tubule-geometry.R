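test_that("windowed-COM axis has the expected point count and anchored tail", {
  bc <- straightChain(1000)
  ax <- computeAxis(bc, window = 150, step = 10)
  expect_equal(nrow(axisPoints(ax)), 86L)        # floor(850/10) + 1
  # collinear input stays collinear
  expect_equal(axisPoints(ax)[, 2], rep(0, 86))
  expect_equal(contourLength(ax), 850 * 0.38, tolerance = 1e-9)

  # window == chain length: single point at the centroid
  bc150 <- straightChain(150)
  ax150 <- computeAxis(bc150, window = 150)
  expect_equal(nrow(axisPoints(ax150)), 1L)
  expect_equal(axisPoints(ax150)[1, ], colMeans(beadCoords(bc150)))
  expect_equal(contourLength(ax150), 0)

  # anchored final window when (n - window) is not a multiple of step
  ax2 <- computeAxis(straightChain(1005), window = 150, step = 10)
  expect_equal(nrow(axisPoints(ax2)), 87L)
  expect_equal(axisPoints(ax2)[87, 1],
               mean(seq(856, 1005) * 0.38), tolerance = 1e-9)

  expect_error(computeAxis(straightChain(100), window = 150), "window")
})

test_that("axis of an ideal helix collapses onto the helix axis", {
  # 25 beads per turn; a 150-residue window spans 6 full turns, whose
  # centre of mass lies on the helix axis by symmetry
  n <- 500; perTurn <- 25; r <- 1
  th <- 2 * pi * (seq_len(n) - 1) / perTurn
  helix <- BeadChain(cbind(r * cos(th), r * sin(th), 0.1 * seq_len(n)))
  ax <- computeAxis(helix, window = 150, step = 10)
  p <- axisPoints(ax)
  expect_lt(max(abs(p[, 1])), 1e-10)
  expect_lt(max(abs(p[, 2])), 1e-10)
  expect_true(!is.unsorted(p[, 3]))
})

test_that("maximum Euclidean extent is exact", {
  expect_equal(maxEuclidean(rbind(c(0, 0, 0), c(5, 0, 0))), 5)
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(maxEuclidean(tri), 1, tolerance = 1e-12)
  expect_error(maxEuclidean(matrix(0, 1, 3)), "2 beads")

  # blocked large-n path against the plain dist() computation
  set.seed(21)
  big <- matrix(rnorm(2600 * 3), ncol = 3)
  expect_equal(maxEuclidean(big), max(dist(big)), tolerance = 1e-9)
  # double-loop oracle on small random sets
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rnorm(40 * 3), ncol = 3)
    expect_equal(maxEuclidean(x), bruteMaxDist(x), tolerance = 1e-12)
  }
})

test_that("tube radius is the chosen percentile of bead-to-polyline distance", {
  # beads on a cylinder surface around a straight axis: constant
  # distance, so every percentile equals the cylinder radius
  set.seed(17)
  n <- 400; r <- 1.7
  th <- runif(n, 0, 2 * pi)
  cyl <- BeadChain(cbind(r * cos(th), r * sin(th), seq(0, 20, length.out = n)))
  trueAx <- new("TubuleAxis", points = rbind(c(0, 0, -1), c(0, 0, 21)),
                window = 150L, step = 10L)
  expect_equal(tubeRadius(cyl, trueAx), r, tolerance = 1e-9)
  # the windowed-COM axis wobbles by ~r/sqrt(window) around the true
  # axis and stops half a window short of the chain ends, so use the
  # (robust) median and a loose band
  ax <- computeAxis(cyl, window = 150, step = 10)
  expect_equal(tubeRadius(cyl, ax, percentile = 50), r, tolerance = 0.1)

  # single-point axis: percentile of distances to that point
  one <- new("TubuleAxis", points = matrix(0, 1, 3),
             window = 10L, step = 1L)
  pts <- BeadChain(cbind(c(1, 2, 3, 4), 0, 0))
  expect_equal(tubeRadius(pts, one, percentile = 90),
               unname(quantile(1:4, 0.9, type = 7)))

  # point-to-segment, not vertex-only: a bead over the middle of a
  # long segment must use the perpendicular distance
  seg <- new("TubuleAxis", points = rbind(c(0, 0, 0), c(10, 0, 0)),
             window = 10L, step = 1L)
  mid <- BeadChain(matrix(c(5, 2, 0), 1))
  expect_equal(tubeRadius(mid, seg, percentile = 50), 2)
})

test_that("radius of gyration and Kirkwood Rh satisfy their closed forms", {
  two <- BeadChain(rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(radiusOfGyration(two), 1.5)
  expect_equal(kirkwoodRh(two), 6)      # 2 d

  ball <- makeBall(3000, radius = 8, seed = 5)$chain
  expect_equal(radiusOfGyration(ball), sqrt(3 / 5) * 8, tolerance = 0.02)
  expect_equal(kirkwoodRh(ball), 5 * 8 / 6, tolerance = 0.02)

  # rigid-motion invariance and linear scaling
  x <- beadCoords(makeCoil(200, seed = 2)$chain)
  R <- randomRotation(5)
  moved <- t(R %*% t(x)) + matrix(c(3, -1, 7), 200, 3, byrow = TRUE)
  expect_equal(radiusOfGyration(moved), radiusOfGyration(x))
  expect_equal(kirkwoodRh(moved), kirkwoodRh(x))
  expect_equal(radiusOfGyration(2.5 * x), 2.5 * radiusOfGyration(x))
  expect_equal(kirkwoodRh(2.5 * x), 2.5 * kirkwoodRh(x))

  dup <- BeadChain(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0)))
  expect_error(kirkwoodRh(dup), "1 and 3")
})

test_that("shape classification matches the reference scale it is given", {
  # literature-scale defaults
  expect_equal(classifyShape(0.77), "spherical")
  expect_equal(classifyShape(1.0), "coil")
  expect_equal(classifyShape(1.7), "rod")
  expect_error(classifyShape(0), "positive")

  # self-consistent calibration labels synthetic references correctly
  cal <- calibrateShapeClasses(nBeads = 1500, seed = 1)
  for (seed in 1:10) {
    sphere <- makeBall(1000, 5, seed = seed)$chain
    coil <- makeCoil(1000, seed = seed)$chain
    rod <- makeRod(1000, length = 50, diameter = 1, seed = seed)$chain
    sf <- function(ch) radiusOfGyration(ch) / kirkwoodRh(ch)
    expect_equal(classifyShape(sf(sphere), cal), "spherical")
    expect_equal(classifyShape(sf(coil), cal), "coil")
    expect_equal(classifyShape(sf(rod), cal), "rod")
  }
})

test_that("shapeMetrics assembles consistent hierarchical metrics", {
  ball <- makeBall(10000, radius = 6, seed = 3)$chain
  m <- shapeMetrics(ball, window = 150, step = 10)
  expect_equal(m$rg_over_maxe, sqrt(3 / 5) / 2, tolerance = 0.05)
  expect_gte(m$maxe, m$rg)
  expect_lte(m$rt, m$maxe)

  # all metrics rigid-motion invariant
  x <- beadCoords(makeTube(600, axisLength = 20, tubeRadius = 1.5,
                           seed = 9)$chain)
  R <- randomRotation(3)
  a <- shapeMetrics(BeadChain(x))
  b <- shapeMetrics(BeadChain(t(R %*% t(x)) +
                              matrix(c(1, 2, 3), 600, 3, byrow = TRUE)))
  for (f in c("acl", "maxe", "rt", "rg", "rh", "shape_factor"))
    expect_equal(a[[f]], b[[f]], tolerance = 1e-9)

  # chains shorter than the window: axis metrics absent, rest present
  short <- shapeMetrics(makeBall(80, 3, seed = 1)$chain, window = 150)
  expect_true(is.na(short$acl) && is.na(short$rt))
  expect_false(is.na(short$rg))

  # a straight synthetic rod is classified as rod under calibration
  cal <- calibrateShapeClasses(nBeads = 1500, seed = 1)
  rodm <- shapeMetrics(makeRod(1200, length = 60, diameter = 1,
                               seed = 2)$chain, calibration = cal)
  expect_equal(rodm$shape_class, "rod")
})
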