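test_that("predicted velocity is the plateau-and-ramp profile", {
  p <- leakyTubeParams(u0 = 22.6, zoneStart = 350)
  prof <- predictVelocity(p, c(0, 175, 350, 500))
  expect_equal(velocities(prof), c(0, 11.3, 22.6, 22.6))
  # impermeable limit: constant velocity everywhere
  p0 <- leakyTubeParams(u0 = 22.6, zoneStart = 350, zoneLength = 0)
  expect_equal(velocities(predictVelocity(p0, c(0, 100, 600))), rep(22.6, 3))
})

test_that("the fitted model conserves mass along the tube", {
  # axial flow drop A (u0 - u(x)) equals the cumulative lateral efflux
  # from x to the plateau; for the uniform leak law the efflux per unit
  # length is A u0 / zoneLength inside the zone.
  p <- leakyTubeParams(u0 = 22.6, zoneStart = 350)
  A <- pi / 4 * 3.6^2 # um^2
  x <- seq(0, 350, by = 10)
  u <- velocities(predictVelocity(p, x))
  drop <- A * (p@u0 - u)
  efflux <- A * p@u0 / p@zoneLength * (p@zoneStart - x)
  expect_equal(drop, efflux)
  # total lateral efflux equals the volumetric flow delivered by the tube
  expect_equal(
    A * p@u0 * 1e-18, # um^2 x um/s -> m^3/s
    volumetricFlow(tubeGeometry(diameter = 3.6, velocity = 22.6))
  )
})

test_that("noise-free profiles are recovered essentially exactly", {
  for (truth in list(c(22.6, 350), c(15, 200), c(30, 420))) {
    p <- leakyTubeParams(u0 = truth[1], zoneStart = truth[2])
    prof <- predictVelocity(p, seq(20, 600, by = 20))
    fit <- fitUnloadingZone(prof, nboot = 0)
    expect_false(fit@degenerate)
    expect_lt(abs(fit@params@u0 - truth[1]) / truth[1], 1e-6)
    expect_lt(abs(fit@params@zoneStart - truth[2]) / truth[2], 1e-6)
  }
})

test_that("plateau velocity is unbiased on noise-free grids", {
  grids <- list(seq(50, 500, length.out = 10), seq(10, 700, length.out = 25))
  for (g in grids) {
    fit <- fitUnloadingZone(
      predictVelocity(leakyTubeParams(22.6, 350), g),
      nboot = 0
    )
    expect_lt(abs(fit@params@u0 - 22.6) / 22.6, 0.02)
  }
})

test_that("constant profiles are flagged degenerate", {
  prof <- velocityProfile(seq(10, 100, by = 10), rep(20, 10))
  fit <- fitUnloadingZone(prof, nboot = 0)
  expect_true(fit@degenerate)
  expect_equal(fit@params@zoneLength, 0)
})

test_that("too few points are rejected", {
  prof <- velocityProfile(c(10, 20, 30, 40), c(1, 2, 3, 4))
  expect_error(fitUnloadingZone(prof), "at least 5 points")
})

test_that("noisy profiles recover the breakpoint with small median error", {
  x <- seq(20, 600, length.out = 30)
  truth <- leakyTubeParams(u0 = 22.6, zoneStart = 350)
  est <- vapply(1:40, function(s) {
    prof <- synthVelocityProfile(truth, x, noiseSd = 2, seed = s)
    fitUnloadingZone(prof, nboot = 0)@params@zoneStart
  }, numeric(1))
  expect_lt(abs(median(est) - 350) / 350, 0.1)
})

test_that("bootstrap intervals bracket the point estimate", {
  prof <- synthVelocityProfile(
    leakyTubeParams(22.6, 350), seq(20, 600, length.out = 30),
    noiseSd = 2, seed = 7
  )
  fit <- fitUnloadingZone(prof, nboot = 99, seed = 11)
  expect_equal(dim(fit@ci), c(2L, 2L))
  expect_true(all(fit@ci[, "lower"] <= fit@ci[, "upper"]))
  expect_gte(fit@params@u0, fit@ci["u0", "lower"] - 3)
  expect_lte(fit@params@u0, fit@ci["u0", "upper"] + 3)
})

test_that("exponential leak law predicts and refits consistently", {
  p <- leakyTubeParams(u0 = 22.6, zoneStart = 350)
  prof <- predictVelocity(p, seq(20, 600, by = 20), law = "exponential")
  expect_true(all(diff(velocities(prof)) >= 0))
  fit <- fitUnloadingZone(prof, law = "exponential", nboot = 0)
  expect_lt(abs(fit@params@zoneStart - 350) / 350, 0.01)
})

test_that("velocity profiles round-trip through CSV", {
  prof <- synthVelocityProfile(
    leakyTubeParams(), seq(25, 600, by = 25),
    noiseSd = 2, seed = 3
  )
  path <- tempfile(fileext = ".csv")
  writeVelocityCsv(prof, path)
  back <- readVelocityCsv(path)
  expect_equal(positions(back), positions(prof))
  expect_equal(velocities(back), velocities(prof))
})
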