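test_that("Debye intensities satisfy their closed forms", {
  q <- c(0, 0.5, 1, 2)
  one <- BeadChain(matrix(0, 1, 3))
  expect_equal(intensities(debyeCurve(one, q)), rep(1, 4))

  two <- BeadChain(rbind(c(0, 0, 0), c(1.5, 0, 0)))
  got <- intensities(debyeCurve(two, q))
  expected <- c(4, 2 + 2 * sin(0.5 * 1.5) / (0.5 * 1.5),
                2 + 2 * sin(1.5) / 1.5, 2 + 2 * sin(3) / 3)
  expect_equal(got, expected, tolerance = 1e-12)

  n <- 250
  ch <- makeBall(n, 5, seed = 2)$chain
  expect_equal(intensities(debyeCurve(ch, 0))[1], n^2)
  expect_error(debyeCurve(ch, c(-0.1, 0.2)), "negative q")
})

test_that("histogram-accelerated Debye agrees with the exact double sum", {
  q <- seq(0.05, 3, length.out = 30)
  worst <- 0
  for (s in 1:50) {
    ch <- makeBall(120, radius = runif(1, 2, 8), seed = s)$chain
    ex <- intensities(debyeCurve(ch, q, method = "exact"))
    hi <- intensities(debyeCurve(ch, q, method = "histogram"))
    worst <- max(worst, max(abs(hi - ex) / ex))
  }
  expect_lt(worst, 0.005)
})

test_that("Guinier analysis inverts synthetic and Debye curves", {
  q <- seq(0.01, 0.5, by = 0.005)
  gauss <- ScatteringCurve(q, exp(-q^2 * 13.8^2 / 3))
  gf <- guinierFit(gauss)
  expect_equal(gf$rg, 13.8, tolerance = 1e-6)
  expect_equal(gf$i0, 1, tolerance = 1e-6)
  expect_true(max(gf$q_window) * gf$rg <= 1.3 + 1e-9)

  # Debye curve of a uniform ball: Guinier Rg within 2% of sqrt(3/5) R
  R <- 6
  ball <- makeBall(1500, R, seed = 4)$chain
  qc <- seq(0.01, 0.8, by = 0.01)
  gf2 <- guinierFit(debyeCurve(ball, qc))
  expect_equal(gf2$rg, sqrt(3 / 5) * R, tolerance = 0.02)

  flat <- ScatteringCurve(q, rep(2, length(q)))
  expect_error(guinierFit(flat), "Guinier regime")
  expect_error(guinierFit(ScatteringCurve(c(0.1, 0.2), c(2, 1))),
               "3 points")
})

test_that("Guinier Rg of a mixture lies between the component extremes", {
  q <- seq(0.005, 0.2, by = 0.005)
  small <- debyeCurve(makeBall(800, 4, seed = 1)$chain, q)
  large <- debyeCurve(makeBall(800, 9, seed = 2)$chain, q)
  rgS <- guinierFit(small)$rg
  rgL <- guinierFit(large)$rg
  mix <- makeMixtureCurve(list(small, large), c(0.5, 0.5))
  rgM <- guinierFit(mix)$rg
  expect_gt(rgM, rgS)
  expect_lt(rgM, rgL)
})

test_that("the Kratky transform is the q^2-weighted intensity", {
  q <- seq(0.1, 2, by = 0.1)
  flat <- ScatteringCurve(q, rep(1, length(q)))
  expect_equal(kratkyTransform(flat)$q2I, q^2)

  # linearity in I
  c1 <- ScatteringCurve(q, exp(-q))
  c2 <- ScatteringCurve(q, 1 / (1 + q))
  lhs <- kratkyTransform(ScatteringCurve(q, intensities(c1) +
                                            intensities(c2)))$q2I
  expect_equal(lhs, kratkyTransform(c1)$q2I + kratkyTransform(c2)$q2I)

  # Gaussian-chain Debye function plateaus at high q
  rg <- 3
  x <- (q * rg)^2
  deb <- ScatteringCurve(q, 2 * (exp(-x) - 1 + x) / x^2)
  k <- kratkyTransform(deb)$q2I
  expect_true(all(diff(k) > 0))
  expect_lt((k[length(k)] - k[length(k) - 1]) / k[length(k)], 0.02)
})

test_that("chi-squared uses the analytically optimal scale", {
  q <- seq(0.1, 1, by = 0.1)
  I <- exp(-q)
  ex <- ScatteringCurve(q, I, sigma = rep(1, 10))
  self <- chiSquare(ex, ScatteringCurve(q, I))
  expect_equal(self$chi2, 0)
  expect_equal(self$scale, 1)

  halved <- chiSquare(ex, ScatteringCurve(q, 2 * I))
  expect_equal(halved$chi2, 0, tolerance = 1e-12)
  expect_equal(halved$scale, 0.5)

  # closed form against a brute grid search over the scale factor
  ex2 <- ScatteringCurve(c(0.1, 0.2), c(1, 2), sigma = c(1, 1))
  got <- chiSquare(ex2, ScatteringCurve(c(0.1, 0.2), c(2, 1)))
  grid <- seq(0.01, 2, by = 1e-4)
  gridChi <- vapply(grid, function(cc)
    sum((c(1, 2) - cc * c(2, 1))^2), numeric(1))
  expect_equal(got$scale, grid[which.min(gridChi)], tolerance = 1e-3)
  expect_equal(got$chi2, min(gridChi) / 1, tolerance = 1e-6)

  expect_error(chiSquare(ScatteringCurve(0.1, 1, 1),
                         ScatteringCurve(0.1, 1)), "at least 2")
})

test_that("GA ensemble selection recovers known mixtures", {
  q <- seq(0.05, 3, length.out = 80)
  ball <- debyeCurve(makeBall(300, 5, seed = 1)$chain, q, id = "ball")
  rod <- debyeCurve(makeRod(300, 30, 3, seed = 2)$chain, q, id = "rod")

  # the experimental curve itself in the pool: selected with weight 1
  ex <- ScatteringCurve(q, intensities(ball), sigma = 0.01 * intensities(ball))
  fit1 <- gaEnsembleFit(list(ball, rod), ex,
                        gaParams(population = 30, generations = 60, seed = 1))
  w <- ensembleWeights(fit1)
  expect_equal(unname(w["ball"]), 1)
  expect_lt(fitChi2(fit1), 1e-10)

  # noiseless 50:50 mixture: weights recovered within 0.1, chi2 within
  # 5% of the exhaustive multiset oracle
  mix <- makeMixtureCurve(list(ball, rod), c(0.5, 0.5))
  fit2 <- gaEnsembleFit(list(ball, rod), mix,
                        gaParams(ensembleSizeMax = 10, population = 30,
                                 generations = 80, seed = 3))
  w2 <- ensembleWeights(fit2)
  expect_equal(unname(w2["ball"]), 0.5, tolerance = 0.1)
  M <- cbind(intensities(ball), intensities(rod))
  oracle <- enumerateBestChi2(M, intensities(mix), sigmas(mix), 10)
  expect_lte(fitChi2(fit2), oracle$chi2 * 1.05 + 1e-12)

  # single-curve pool
  fit3 <- gaEnsembleFit(list(ball), ex,
                        gaParams(population = 10, generations = 5, seed = 1))
  expect_equal(unname(ensembleWeights(fit3)), 1)

  # reproducibility and the elitism guarantee
  fit2b <- gaEnsembleFit(list(ball, rod), mix,
                         gaParams(ensembleSizeMax = 10, population = 30,
                                  generations = 80, seed = 3))
  expect_identical(ensembleWeights(fit2), ensembleWeights(fit2b))
  expect_identical(fitChi2(fit2), fitChi2(fit2b))
  expect_true(all(diff(fit2@trace) <= 0))

  expect_error(gaEnsembleFit(list(), ex), "empty pool")
  offgrid <- ScatteringCurve(q + 0.001, intensities(rod))
  expect_error(gaEnsembleFit(list(ball, offgrid), ex), "q grid")
})

test_that("GA matches the exhaustive oracle on a 3-curve pool", {
  q <- seq(0.05, 2.5, length.out = 60)
  pool <- list(
    debyeCurve(makeBall(200, 4, seed = 1)$chain, q, id = "a"),
    debyeCurve(makeRod(200, 25, 2, seed = 2)$chain, q, id = "b"),
    debyeCurve(makeCoil(200, 0.38, seed = 3)$chain, q, id = "c"))
  target <- makeMixtureCurve(pool, c(0.2, 0.5, 0.3))
  fit <- gaEnsembleFit(pool, target,
                       gaParams(ensembleSizeMax = 10, population = 40,
                                generations = 120, seed = 2))
  M <- vapply(pool, intensities, numeric(length(q)))
  oracle <- enumerateBestChi2(M, intensities(target), sigmas(target), 10)
  expect_lte(fitChi2(fit), oracle$chi2 * 1.05 + 1e-12)
})

test_that("pool assembly tags and parses conformer descriptors", {
  dir <- tempfile(); dir.create(dir)
  writeBeadPDB(makeBall(50, 3, seed = 1)$chain, file.path(dir, "M2_0010.pdb"))
  writeBeadPDB(makeBall(50, 3, seed = 2)$chain, file.path(dir, "M3_0100.pdb"))
  writeBeadPDB(makeBall(50, 3, seed = 3)$chain,
               file.path(dir, "M2M3_0130_0160.pdb"))
  q <- seq(0.1, 2, length.out = 20)
  pool <- assemblePool(dir, q)
  expect_length(pool, 3L)
  expect_setequal(vapply(pool, curveId, character(1)),
                  c("M2_0010", "M3_0100", "M2M3_0130_0160"))

  # unreadable member skipped with a warning, not fatal
  writeLines("garbage", file.path(dir, "broken.pdb"))
  expect_warning(pool2 <- assemblePool(dir, q), "skipping")
  expect_length(pool2, 3L)

  empty <- tempfile(); dir.create(empty)
  expect_error(assemblePool(empty, q), "empty pool")

  p1 <- parseConformerId("M2_0140")
  expect_equal(p1$model, "M2")
  expect_equal(p1$time_ns, 140L)
  p2 <- parseConformerId("M2M3_0130_0160")
  expect_equal(p2$model, c("M2", "M3"))
  expect_equal(p2$time_ns, c(130L, 160L))
  p3 <- parseConformerId("M2-M3_0010_1000")
  expect_equal(p3$time_ns, c(10L, 1000L))
  expect_error(parseConformerId("X9_!!"), "unparseable")
})
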