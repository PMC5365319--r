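test_that("an all-defaults run writes the full report set", {
  out <- runScenario(outDir = tempfile("run"), quiet = TRUE)
  expect_true(all(file.exists(out$files)))
  tab <- read.csv(out$files[["scenario_csv"]])
  val <- function(pat) tab$value[grepl(pat, tab$quantity)][1]
  expect_equal(val("Total sap volume"), 230)
  expect_equal(val("simple PD"), 8.14)
  expect_equal(val("neck only"), 0.05)
  expect_equal(val("diffusion only"), 274)
  census <- read.csv(out$files[["census"]])
  expect_equal(census$reported, c(240, 215, 73))
})

test_that("the resolved-config echo re-runs byte-identically", {
  d1 <- tempfile("run")
  d2 <- tempfile("run")
  out1 <- runScenario(
    config = list(tube = list(velocity_um_s = 20)),
    outDir = d1, quiet = TRUE
  )
  out2 <- runScenario(
    config = out1$files[["config"]],
    outDir = d2, quiet = TRUE
  )
  for (k in c("scenario_csv", "scenario_txt", "census")) {
    expect_identical(readLines(out1$files[[k]]), readLines(out2$files[[k]]))
  }
  # the echoed config resolves to itself
  expect_identical(out2$config, out1$config)
})

test_that("schema violations are reported by field name", {
  expect_error(
    runScenario(config = list(tube = list(diameter_um = -3.6)), quiet = TRUE),
    "tube.diameter_um"
  )
  expect_error(
    runScenario(config = list(tube = list(diamter_um = 3.6)), quiet = TRUE),
    "diamter_um"
  )
  expect_error(
    runScenario(config = list(nonsense = 1), quiet = TRUE),
    "nonsense"
  )
  expect_error(
    readRunConfig(config = list(pd = list(neck_fraction = 2))),
    "pd.neck_fraction"
  )
  expect_error(readRunConfig(path = tempfile("missing")), "not found")
})

test_that("every assumed default is logged exactly once with an assumption tag", {
  out <- runScenario(outDir = tempfile("run"), quiet = TRUE)
  log <- readLines(out$files[["log"]])
  assumed <- c(
    "sap.viscosity_pa_s", "sap.diffusivity_m2_s", "sap.hindrance",
    "sap.temperature_k", "pd.neck_fraction", "pd.annulus_model",
    "flags.leak_law"
  )
  for (key in assumed) {
    hits <- grep(paste0("default: ", key, " \\[assumption\\]"), log)
    expect_length(hits, 1)
  }
  # measured base values are defaults but not assumptions
  expect_length(grep("tube.diameter_um \\[assumption\\]", log), 0)
})

test_that("explicit configuration values override defaults and flow through", {
  out <- runScenario(
    config = list(
      tube = list(velocity_um_s = 45.2), # doubled velocity
      flags = list(leak_law = "exponential")
    ),
    outDir = tempfile("run"), quiet = TRUE
  )
  base <- runScenario(outDir = tempfile("run"), quiet = TRUE)
  expect_equal(out$result@Q, 2 * base$result@Q)
  expect_equal(out$result@dPSimple, 2 * base$result@dPSimple)
  log <- readLines(out$files[["log"]])
  expect_length(grep("default: tube.velocity_um_s", log), 0)
})

test_that("the slit-model flag changes the simple-PD pressure only slightly", {
  slit <- runScenario(
    config = list(pd = list(annulus_model = "slit")),
    outDir = tempfile("run"), quiet = TRUE
  )$result
  exact <- scenarioReport()
  expect_lt(abs(slit@dPSimple - exact@dPSimple) / exact@dPSimple, 0.01)
})
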