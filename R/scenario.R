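#' @include AllClasses.R
NULL

#' Default plasmodesma populations at the PSE-PPP interface
#'
#' Two bulk-flow hypotheses for the ~240 plasmodesmata at the PSE-PPP
#' interface: all simple, or the observed mix of 24 simple (10%) and
#' 216 funnel plasmodesmata.
#'
#' @param census A [PDCensus-class]; the PSE-PPP reported count sets the
#'   all-simple population size.
#' @param simpleGeom,funnelGeom Geometries used for the two classes.
#' @return A list with elements `simple_only` and `mixed`, each a list
#'   of `list(geom =, count =)` entries.
#' @export
defaultPopulations <- function(census = pdCensus(),
                               simpleGeom = simplePD(),
                               funnelGeom = funnelPD()) {
  nTotal <- interfaceCounts(census)$reported[1]
  nSimple <- round(0.1 * nTotal)
  list(
    simple_only = list(list(geom = simpleGeom, count = nTotal)),
    mixed = list(
      list(geom = simpleGeom, count = nSimple),
      list(geom = funnelGeom, count = nTotal - nSimple)
    )
  )
}

.with_mode <- function(geom, mode) {
  if (methods::is(geom, "FunnelPD")) geom@mode <- mode
  geom
}

.set_population_mode <- function(population, mode) {
  lapply(population, function(e) {
    e$geom <- .with_mode(e$geom, mode)
    e
  })
}

#' Full unloading-scenario report
#'
#' Evaluates every candidate unloading mechanism for one protophloem
#' file at steady state: the volumetric flow `Q = (pi/4) d^2 u` and
#' solute flux `I = Q c` to be unloaded; the pressure differential for
#' bulk flow through an all-simple plasmodesma population and through
#' the observed simple+funnel mix (both desmotubule-placement
#' extremes); the concentration difference for purely diffusive
#' unloading through the mixed population (desmotubule spanning the
#' funnels); the membrane pressure to remove the solvent at the two
#' reported permeability bounds; per-funnel Peclet numbers at the
#' bulk-flow operating point; and the van 't Hoff concentration
#' equivalents of the funnel pressures.
#'
#' @param tube A [TubeGeometry-class].
#' @param sap A [SapProperties-class].
#' @param census A [PDCensus-class].
#' @param populations As returned by [defaultPopulations()].
#' @param annulusModel Simple-PD resistance model, `"annulus"` (exact,
#'   default) or `"slit"`; see [annularResistance()].
#' @return A [ScenarioResult-class].
#' @examples
#' res <- scenarioReport()
#' res
#' @export
scenarioReport <- function(tube = tubeGeometry(),
                           sap = sapProperties(),
                           census = pdCensus(),
                           populations = defaultPopulations(census),
                           annulusModel = c("annulus", "slit")) {
  if (!all(c("simple_only", "mixed") %in% names(populations))) {
    stop("populations must have elements 'simple_only' and 'mixed'", call. = FALSE)
  }
  annulusModel <- match.arg(annulusModel)
  Q <- volumetricFlow(tube)
  I <- soluteFlux(Q, sapConcentration(sap))

  dPSimple <- populationPressure(Q, populations$simple_only, sap, model = annulusModel)
  modes <- c("full_span", "neck_only")
  dPFunnel <- vapply(modes, function(m) {
    populationPressure(Q, .set_population_mode(populations$mixed, m), sap,
      model = annulusModel
    )
  }, numeric(1))

  # Pure diffusion: published requirement corresponds to the obstructed
  # (full-span) funnel extreme.
  Ptot <- populationPermeability(
    .set_population_mode(populations$mixed, "full_span"), sap
  )
  dcDiffusive <- requiredConcentrationDifference(I, Ptot)

  dpMembrane <- membraneWaterPressure(Q, tube)

  peclet <- vapply(modes, function(m) {
    fun <- Filter(function(e) methods::is(e$geom, "FunnelPD"), populations$mixed)
    if (!length(fun)) {
      return(NA_real_)
    }
    g <- .with_mode(fun[[1]]$geom, m)
    Qpd <- dPFunnel[[m]] / funnelResistance(g, sap)
    Qpd / diffusivePermeability(g, sap)
  }, numeric(1))

  methods::new("ScenarioResult",
    Q = Q, I = I, dPSimple = dPSimple, dPFunnel = dPFunnel,
    dcDiffusive = dcDiffusive, dpMembrane = dpMembrane, peclet = peclet,
    osmoticEquivalent = vantHoff(dPFunnel, temperature(sap)),
    tube = tube, sap = sap, populations = populations
  )
}

.sig3 <- function(x) signif(x, 3)

#' Scenario result as a parameter/value table
#'
#' @param result A [ScenarioResult-class].
#' @return A data frame with columns `quantity`, `value`, `unit`
#'   (values in reporting units: fl/s, mol/s, MPa, mM), to 3
#'   significant figures.
#' @export
scenarioTable <- function(result) {
  stopifnot(methods::is(result, "ScenarioResult"))
  counts <- vapply(result@populations$mixed, `[[`, numeric(1), "count")
  simple_n <- result@populations$simple_only[[1]]$count
  data.frame(
    quantity = c(
      "Length of unloading zone",
      "Desmotubule diameter",
      "Cytoplasmic sleeve width",
      "Cell wall thickness",
      "Phloem sap osmotic potential",
      "Funnel opening towards PSE",
      "# of PD available for unloading (simple scenario)",
      "# of PD available for unloading (mixed scenario)",
      "Total sap volume",
      "Solute flux",
      "Required pressure differential (simple PD)",
      "Required pressure differential (funnel PD, desmotubule full span)",
      "Required pressure differential (funnel PD, desmotubule neck only)",
      "Required concentration difference (diffusion only)",
      "Membrane pressure (Lp = 1e-12 m/s/Pa)",
      "Membrane pressure (Lp = 1e-14 m/s/Pa)",
      "Osmotic equivalent of funnel pressures",
      "Peclet number per funnel PD"
    ),
    value = c(
      .sig3(zoneLength(result@tube) * 1e6),
      .sig3(result@populations$simple_only[[1]]$geom@desmotubule * 1e9),
      .sig3(result@populations$simple_only[[1]]$geom@sleeve * 1e9),
      .sig3(wallLength(result@populations$simple_only[[1]]$geom) * 1e9),
      .sig3(sapConcentration(result@sap)),
      .sig3(mouthRadius(result@populations$mixed[[2]]$geom) * 2e9),
      simple_n,
      sum(counts),
      .sig3(result@Q * 1e18),
      .sig3(result@I),
      .sig3(result@dPSimple / 1e6),
      .sig3(result@dPFunnel[["full_span"]] / 1e6),
      .sig3(result@dPFunnel[["neck_only"]] / 1e6),
      .sig3(result@dcDiffusive),
      .sig3(min(result@dpMembrane) / 1e6),
      .sig3(max(result@dpMembrane) / 1e6),
      .sig3(max(result@osmoticEquivalent)),
      .sig3(result@peclet[["full_span"]])
    ),
    unit = c(
      "um", "nm", "nm", "nm", "mM", "nm", "PD", "PD", "fl/s", "mol/s",
      "MPa", "MPa", "MPa", "mM", "MPa", "MPa", "mM", "-"
    ),
    stringsAsFactors = FALSE
  )
}

#' Write the scenario report to CSV / aligned text
#'
#' @param result A [ScenarioResult-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeScenarioCsv <- function(result, path) {
  utils::write.csv(scenarioTable(result), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScenarioCsv
#' @export
writeScenarioText <- function(result, path) {
  tab <- scenarioTable(result)
  lines <- c(
    "Phloem unloading scenario (one protophloem file, steady state)",
    sprintf(
      "%-62s %12s %-6s", tab$quantity, format(tab$value, trim = TRUE),
      tab$unit
    )
  )
  writeLines(lines, path)
  invisible(path)
}

setMethod("show", "ScenarioResult", function(object) {
  cat("Convective phloem unloading scenario\n")
  cat(sprintf(
    "  Q  = %.3g fl/s        I = %.3g mol/s\n",
    object@Q * 1e18, object@I
  ))
  cat(sprintf("  Bulk flow, all-simple PD:   dP = %.3g MPa\n", object@dPSimple / 1e6))
  cat(sprintf(
    "  Bulk flow, simple+funnel:   dP = %.3g-%.3g MPa (desmotubule extremes)\n",
    min(object@dPFunnel) / 1e6, max(object@dPFunnel) / 1e6
  ))
  cat(sprintf(
    "  Osmotic equivalent:         %.3g-%.3g mM\n",
    min(object@osmoticEquivalent), max(object@osmoticEquivalent)
  ))
  cat(sprintf("  Pure diffusion:             dc = %.3g mM\n", object@dcDiffusive))
  cat(sprintf(
    "  Membrane water removal:     dp = %.3g-%.3g MPa (Lp bounds)\n",
    min(object@dpMembrane) / 1e6, max(object@dpMembrane) / 1e6
  ))
  cat(sprintf(
    "  Peclet per funnel PD:       %.3g (full span), %.3g (neck only)\n",
    object@peclet[["full_span"]], object@peclet[["neck_only"]]
  ))
  invisible(NULL)
})
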