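test_that("volumetric flow follows (pi/4) d^2 u", {
  tube <- base_tube()
  expect_equal(volumetricFlow(tube), pi / 4 * (3.6e-6)^2 * 22.6e-6)
  expect_equal(volumetricFlow(tubeGeometry(velocity = 0)), 0)
  expect_equal(
    volumetricFlow(tubeGeometry(diameter = 7.2)),
    4 * volumetricFlow(tube)
  )
  expect_error(tubeGeometry(diameter = -1), "positive")
})

test_that("solute flux is the product of flow and concentration", {
  expect_equal(soluteFlux(230e-18, 500), 1.15e-13)
  # 100 fl/s at 100 mM: 1e-16 L/s... 1e-16 m^3/s x 100 mol/m^3
  expect_equal(soluteFlux(100e-18, 100), 1.0e-14)
  expect_equal(soluteFlux(230e-18, 0), 0)
  expect_error(soluteFlux(-1e-18, 500), "non-negative")
})

test_that("diffusive permeability reduces to D A / L for constant sections", {
  sap <- base_sap()
  g <- simplePD()
  A <- pi * (neckRadius(g)^2 - desmotubuleRadius(g)^2)
  expect_equal(
    diffusivePermeability(g, sap),
    hindrance(sap) * diffusivity(sap) * A / wallLength(g)
  )
  # linear in D and in H
  sap2 <- sapProperties(diffusivity = 2 * diffusivity(sap))
  expect_equal(diffusivePermeability(g, sap2), 2 * diffusivePermeability(g, sap))
  sapH <- sapProperties(hindrance = 0.5)
  expect_equal(diffusivePermeability(g, sapH), 0.5 * diffusivePermeability(g, sap))
})

test_that("funnel permeability exceeds the matching simple PD and grows with the mouth", {
  sap <- base_sap()
  P_simple <- diffusivePermeability(simplePD(), sap)
  P <- vapply(
    c(30, 60, 150, 300),
    function(m) diffusivePermeability(funnelPD(mouth = m), sap),
    numeric(1)
  )
  expect_true(all(diff(P) > 0))
  expect_true(all(P > P_simple))
  # degenerate funnel equals the simple PD
  expect_equal(diffusivePermeability(funnelPD(mouth = 20.6), sap), P_simple,
    tolerance = 1e-8
  )
})

test_that("required concentration difference is flux over permeability", {
  expect_equal(requiredConcentrationDifference(1e-15, 1e-18), 1000)
  expect_equal(requiredConcentrationDifference(0, 1e-18), 0)
  expect_error(requiredConcentrationDifference(1e-15, 0), "positive")
})

test_that("convective flux interpolates between diffusion and advection", {
  P <- 2e-18
  # Pe -> 0: pure diffusion
  expect_equal(convectiveFlux(0, P, 500, 100), P * 400)
  # tiny Pe remains continuous (no division blow-up)
  expect_equal(convectiveFlux(1e-30, P, 500, 100), P * 400, tolerance = 1e-6)
  # Pe -> infinity: pure advection of the upstream concentration
  expect_equal(convectiveFlux(1e-12, P, 500, 100), 1e-12 * 500, tolerance = 1e-9)
  # Pe = 1 with c_down = 0: Q c_up / (1 - e^-1)
  Q <- P
  expect_equal(convectiveFlux(Q, P, 1, 0), Q / (1 - exp(-1)))
  # uniform solution is advected exactly
  for (Q in c(1e-20, 1e-18, 1e-16)) {
    expect_equal(convectiveFlux(Q, P, 500, 500), Q * 500)
  }
})

test_that("convective flux is monotone in both concentrations", {
  P <- 2e-18
  Q <- 1e-18
  cups <- seq(0, 1000, by = 100)
  up <- vapply(cups, function(cu) convectiveFlux(Q, P, cu, 200), numeric(1))
  expect_true(all(diff(up) > 0))
  down <- vapply(cups, function(cd) convectiveFlux(Q, P, 500, cd), numeric(1))
  expect_true(all(diff(down) < 0))
})

test_that("membrane water removal pressures match the permeability bounds", {
  tube <- base_tube()
  Q <- volumetricFlow(tube)
  dp <- membraneWaterPressure(Q, tube)
  A <- pi * 3.6e-6 * 350e-6
  expect_equal(unname(dp["high_Lp"]), Q / (1e-12 * A))
  expect_equal(unname(dp["low_Lp"]), Q / (1e-14 * A))
  expect_equal(unname(membraneWaterPressure(0, tube)), c(0, 0))
  # inverse proportionality to Lp and to zone length
  for (s in c(2, 5, 10)) {
    expect_equal(
      membraneWaterPressure(Q, tube, Lp = s * 1e-13),
      membraneWaterPressure(Q, tube, Lp = 1e-13) / s
    )
    tube_s <- tubeGeometry(zone = s * 350)
    expect_equal(
      unname(membraneWaterPressure(Q, tube_s)), unname(dp) / s
    )
  }
})

test_that("van 't Hoff conversion and its inverse round-trip exactly", {
  expect_equal(vantHoff(1e6, T = 298), 1e6 / (8.31446 * 298))
  expect_equal(vantHoff(1e6, T = 298), 403.5, tolerance = 1e-3)
  expect_equal(vantHoff(0), 0)
  for (dp in c(0.05e6, 0.2e6, 1e6, 3.7e6)) {
    expect_equal(vantHoffPressure(vantHoff(dp)), dp, tolerance = 1e-12)
  }
})

test_that("the scenario report is internally consistent", {
  res <- scenarioReport()
  expect_identical(res@I, soluteFlux(volumetricFlow(res@tube), 500))
  expect_identical(res@Q, volumetricFlow(res@tube))
  expect_equal(res@osmoticEquivalent, vantHoff(res@dPFunnel, T = 298))
  expect_true(all(c(
    res@Q, res@I, res@dPSimple, res@dPFunnel, res@dcDiffusive,
    res@dpMembrane, res@peclet
  ) >= 0))
  # a stalled tube requires nothing of any mechanism
  res0 <- scenarioReport(tube = tubeGeometry(velocity = 0))
  expect_equal(res0@dPSimple, 0)
  expect_equal(unname(res0@dPFunnel), c(0, 0))
  expect_equal(res0@dcDiffusive, 0)
  expect_equal(unname(res0@dpMembrane), c(0, 0))
})

test_that("per-funnel Peclet numbers are order one at the operating point", {
  # convection and diffusion contribute comparably through funnel PD
  res <- scenarioReport()
  expect_true(all(res@peclet > 0.05 & res@peclet < 20))
})
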