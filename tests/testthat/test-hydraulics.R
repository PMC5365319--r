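test_that("annular resistance matches an independent finite-difference solution", {
  sap <- base_sap()
  cases <- list(
    c(a = 7.5e-9, b = 10.3e-9, L = 500e-9),
    c(a = 7.5e-9, b = 15e-9, L = 500e-9),
    c(a = 20e-9, b = 22e-9, L = 1e-6)
  )
  for (cs in cases) {
    geom <- simplePD(
      desmotubule = 2 * cs[["a"]], sleeve = cs[["b"]] - cs[["a"]],
      wall = cs[["L"]], units = "m"
    )
    R_pkg <- annularResistance(geom, sap)
    R_fd <- fd_annulus_resistance(cs[["a"]], cs[["b"]], cs[["L"]], viscosity(sap))
    expect_lt(abs(R_pkg - R_fd) / R_fd, 0.01)
  }
})

test_that("annular resistance is exactly linear in length and viscosity", {
  sap <- base_sap()
  sap2 <- sapProperties(viscosity = 2 * viscosity(sap))
  R1 <- annularResistance(simplePD(), sap)
  expect_equal(annularResistance(simplePD(wall = 1000), sap), 2 * R1)
  expect_equal(annularResistance(simplePD(), sap2), 2 * R1)
})

test_that("thin-slit approximation agrees with the annulus for narrow sleeves", {
  sap <- base_sap()
  # sleeve much smaller than the desmotubule radius
  for (sl in c(0.3, 0.5, 1)) {
    geom <- simplePD(desmotubule = 30, sleeve = sl)
    Ra <- annularResistance(geom, sap, model = "annulus")
    Rs <- annularResistance(geom, sap, model = "slit")
    expect_lt(abs(Ra - Rs) / Ra, 0.15)
  }
  # even the base geometry (sleeve ~ 0.4x radius) stays within 15%
  g0 <- simplePD()
  expect_lt(
    abs(annularResistance(g0, sap) - annularResistance(g0, sap, model = "slit")) /
      annularResistance(g0, sap),
    0.15
  )
})

test_that("funnel integrator reproduces the closed-form tapered-tube resistance", {
  sap <- base_sap()
  mu <- viscosity(sap)
  for (cs in list(
    c(r1 = 75e-9, r2 = 10.3e-9, L = 500e-9),
    c(r1 = 150e-9, r2 = 10e-9, L = 1e-6),
    c(r1 = 20e-9, r2 = 20e-9, L = 500e-9) # degenerate cylinder
  )) {
    R_num <- openConeResistance(cs[["r1"]], cs[["r2"]], cs[["L"]], sap)
    R_cf <- cone_resistance_closed_form(cs[["r1"]], cs[["r2"]], cs[["L"]], mu)
    expect_lt(abs(R_num - R_cf) / R_cf, 1e-6)
  }
})

test_that("a degenerate funnel has the resistance of the matching simple PD", {
  sap <- base_sap()
  deg <- funnelPD(mouth = 20.6, mode = "full_span")
  expect_lt(
    abs(funnelResistance(deg, sap) - annularResistance(simplePD(), sap)) /
      annularResistance(simplePD(), sap),
    1e-6
  )
})

test_that("wider mouths and less desmotubule never increase resistance", {
  sap <- base_sap()
  R_simple <- annularResistance(simplePD(), sap)
  mouths <- c(30, 60, 150, 300)
  for (mode in c("full_span", "neck_only")) {
    R <- vapply(
      mouths,
      function(m) funnelResistance(funnelPD(mouth = m, mode = mode), sap),
      numeric(1)
    )
    expect_true(all(diff(R) < 0)) # monotone decreasing in mouth diameter
    expect_true(all(R < R_simple)) # funnels always beat the simple PD
  }
  # more obstruction never lowers resistance
  expect_gte(
    funnelResistance(funnelPD(mode = "full_span"), sap),
    funnelResistance(funnelPD(mode = "neck_only"), sap)
  )
  # neck_only resistance grows with the obstructed fraction
  fr <- c(0.005, 0.05, 0.5, 1)
  Rn <- vapply(
    fr,
    function(f) funnelResistance(funnelPD(mode = "neck_only", neckFraction = f), sap),
    numeric(1)
  )
  expect_true(all(diff(Rn) > 0))
  expect_equal(Rn[4], funnelResistance(funnelPD(mode = "full_span"), sap),
    tolerance = 1e-8
  )
})

test_that("population pressure is linear in flow and viscosity", {
  sap <- base_sap()
  pop <- list(
    list(geom = simplePD(), count = 24),
    list(geom = funnelPD(), count = 216)
  )
  p1 <- populationPressure(1e-16, pop, sap)
  for (s in c(0.5, 2, 10)) {
    expect_equal(populationPressure(s * 1e-16, pop, sap), s * p1, tolerance = 1e-12)
    sap_s <- sapProperties(viscosity = s * viscosity(sap))
    expect_equal(populationPressure(1e-16, pop, sap_s), s * p1, tolerance = 1e-10)
  }
  expect_equal(populationPressure(0, pop, sap), 0)
  expect_error(populationPressure(1e-16, list(), sap), "at least one PD")
})

test_that("the all-simple population requires ~8.14 MPa for the unloading flow", {
  Q <- volumetricFlow(base_tube())
  dP <- populationPressure(Q, simplePD(), base_sap(), count = 240)
  expect_equal(dP / 1e6, 8.14, tolerance = 0.002)
})

test_that("dimensional consistency: nm, um and m inputs give identical results", {
  sap <- base_sap()
  g_nm <- simplePD(15, 2.8, 500, units = "nm")
  g_um <- simplePD(0.015, 0.0028, 0.5, units = "um")
  g_m <- simplePD(15e-9, 2.8e-9, 500e-9, units = "m")
  expect_equal(annularResistance(g_nm, sap), annularResistance(g_um, sap))
  expect_equal(annularResistance(g_nm, sap), annularResistance(g_m, sap))
  f_nm <- funnelPD(150, 15, 2.8, 500, units = "nm")
  f_um <- funnelPD(0.15, 0.015, 0.0028, 0.5, units = "um")
  expect_equal(funnelResistance(f_nm, sap), funnelResistance(f_um, sap),
    tolerance = 1e-10
  )
})
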