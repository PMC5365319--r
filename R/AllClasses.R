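#' @include AllGenerics.R
NULL

# All length slots are stored in SI metres regardless of the units the
# constructor accepted; accessors return SI.

#' Plasmodesma geometry
#'
#' Virtual parent of [SimplePD-class] and [FunnelPD-class]. A
#' plasmodesma is modelled as a channel through the cell wall
#' (length = wall thickness) containing a central desmotubule; the open
#' conducting space is the cytoplasmic sleeve between desmotubule and
#' wall.
#'
#' @slot desmotubule Desmotubule diameter, m.
#' @slot sleeve Cytoplasmic sleeve width (radial gap at the neck), m.
#' @slot wall Axial channel length = cell wall thickness, m.
#' @aliases PDGeometry
#' @seealso [simplePD()], [funnelPD()]
#' @export
setClass("PDGeometry",
  representation("VIRTUAL",
    desmotubule = "numeric", sleeve = "numeric", wall = "numeric"
  )
)

setValidity("PDGeometry", function(object) {
  v <- c(
    desmotubule = object@desmotubule, sleeve = object@sleeve,
    wall = object@wall
  )
  if (any(!is.finite(v)) || any(v <= 0)) {
    return("desmotubule, sleeve and wall lengths must be finite and strictly positive")
  }
  TRUE
})

#' Simple (cylindrical) plasmodesma
#'
#' A channel of constant circular cross-section with a concentric
#' desmotubule: the conducting space is an annulus of inner radius
#' `desmotubule/2` and outer radius `desmotubule/2 + sleeve` over the
#' full wall thickness.
#'
#' @aliases SimplePD
#' @seealso [simplePD()]
#' @export
setClass("SimplePD", contains = "PDGeometry")

#' Funnel-shaped plasmodesma
#'
#' Wide aperture (`mouth`) at the sieve-element entrance tapering
#' linearly to a conventional neck (outer radius
#' `desmotubule/2 + sleeve`) at the pericycle side. The desmotubule
#' placement is uncertain, so two extremes are modelled:
#' `"full_span"` (desmotubule runs the whole length; every section is
#' annular) and `"neck_only"` (the desmotubule obstructs only the final
#' `neckFraction` of the length; the wide region is an open cone).
#'
#' @slot mouth Aperture diameter at the sieve-element entrance, m.
#' @slot mode Desmotubule placement, `"full_span"` or `"neck_only"`.
#' @slot neckFraction Fraction of the length obstructed by the
#'   desmotubule in `"neck_only"` mode, in (0, 1].
#' @aliases FunnelPD
#' @seealso [funnelPD()]
#' @export
setClass("FunnelPD",
  contains = "PDGeometry",
  representation(mouth = "numeric", mode = "character", neckFraction = "numeric")
)

setValidity("FunnelPD", function(object) {
  msgs <- character()
  neck <- object@desmotubule + 2 * object@sleeve
  if (!is.finite(object@mouth) || object@mouth <= 0) {
    msgs <- c(msgs, "mouth diameter must be finite and strictly positive")
  } else if (object@mouth < neck * (1 - 1e-12)) {
    msgs <- c(msgs, sprintf(
      "mouth diameter (%.3g m) must be >= neck outer diameter (%.3g m)",
      object@mouth, neck
    ))
  }
  if (!object@mode %in% c("full_span", "neck_only")) {
    msgs <- c(msgs, 'mode must be "full_span" or "neck_only"')
  }
  if (!is.finite(object@neckFraction) || object@neckFraction <= 0 ||
    object@neckFraction > 1) {
    msgs <- c(msgs, "neckFraction must lie in (0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Phloem sap properties
#'
#' @slot viscosity Dynamic viscosity, Pa s.
#' @slot diffusivity Free solute diffusivity, m^2/s.
#' @slot hindrance Dimensionless hindrance factor in (0, 1] applied to
#'   diffusivity inside pores (effective diffusivity = H * D).
#' @slot concentration Solute concentration, mol/m^3.
#' @slot temperature Temperature, K.
#' @aliases SapProperties
#' @seealso [sapProperties()]
#' @export
setClass("SapProperties",
  representation(
    viscosity = "numeric", diffusivity = "numeric", hindrance = "numeric",
    concentration = "numeric", temperature = "numeric"
  )
)

setValidity("SapProperties", function(object) {
  v <- c(
    viscosity = object@viscosity, diffusivity = object@diffusivity,
    concentration = object@concentration, temperature = object@temperature
  )
  if (any(!is.finite(v)) || any(v <= 0)) {
    return("viscosity, diffusivity, concentration and temperature must be finite and strictly positive")
  }
  if (!is.finite(object@hindrance) || object@hindrance <= 0 ||
    object@hindrance > 1) {
    return("hindrance must lie in (0, 1]")
  }
  TRUE
})

#' Sieve-tube geometry of the unloading zone
#'
#' @slot diameter Sieve-tube inner diameter, m.
#' @slot velocity Axial flow velocity in the translocation zone, m/s.
#' @slot zone Length of the unloading zone, m.
#' @slot lp Plasma-membrane hydraulic permeability bounds
#'   `c(low, high)`, m/s/Pa.
#' @aliases TubeGeometry
#' @seealso [tubeGeometry()]
#' @export
setClass("TubeGeometry",
  representation(
    diameter = "numeric", velocity = "numeric", zone = "numeric",
    lp = "numeric"
  )
)

setValidity("TubeGeometry", function(object) {
  v <- c(diameter = object@diameter, zone = object@zone)
  if (any(!is.finite(v)) || any(v <= 0)) {
    return("diameter and zone length must be finite and strictly positive")
  }
  # velocity 0 is allowed (stalled tube: every budget degenerates to 0)
  if (!is.finite(object@velocity) || object@velocity < 0) {
    return("velocity must be finite and non-negative")
  }
  if (length(object@lp) != 2L || any(!is.finite(object@lp)) ||
    any(object@lp <= 0) || object@lp[1] > object@lp[2]) {
    return("lp must be two positive permeabilities c(low, high) with low <= high")
  }
  TRUE
})

#' Plasmodesmal census of one unloading domain
#'
#' Total plasmodesmata per protophloem unloading domain (mean, SD over
#' `n` domains) and the fractional distribution across the three wall
#' interfaces of the protophloem sieve element: PSE-PPP (phloem-pole
#' pericycle), PSE-CC (companion cell), PSE-MSE (metaphloem sieve
#' element).
#'
#' @slot total Mean total per domain.
#' @slot sd Standard deviation of the total.
#' @slot n Number of domains measured.
#' @slot fractions Named fractions `c(PSE_PPP, PSE_CC, PSE_MSE)` summing
#'   to 1 (within 0.005).
#' @aliases PDCensus
#' @seealso [pdCensus()], [interfaceCounts()]
#' @export
setClass("PDCensus",
  representation(
    total = "numeric", sd = "numeric", n = "numeric", fractions = "numeric"
  )
)

setValidity("PDCensus", function(object) {
  if (!is.finite(object@total) || object@total <= 0) {
    return("total must be strictly positive")
  }
  if (!is.finite(object@sd) || object@sd < 0) return("sd must be non-negative")
  if (!is.finite(object@n) || object@n < 1) return("n must be >= 1")
  f <- object@fractions
  if (length(f) != 3L || any(!is.finite(f)) || any(f < 0)) {
    return("fractions must be three non-negative numbers")
  }
  if (abs(sum(f) - 1) > 0.005) {
    return(sprintf("fractions must sum to 1 within 0.005 (got %.4f)", sum(f)))
  }
  if (!identical(names(f), c("PSE_PPP", "PSE_CC", "PSE_MSE"))) {
    return("fractions must be named PSE_PPP, PSE_CC, PSE_MSE")
  }
  TRUE
})

#' Leaky-tube model parameters
#'
#' Piecewise-linear model of axial sieve-tube velocity: a plateau `u0`
#' basipetal of `zoneStart`, then a linear decline to zero over
#' `zoneLength` (uniform volumetric leak per unit length). Positions are
#' measured in micrometres basipetally from PSE zero (the terminal
#' sieve element), so the unloading zone ends at
#' `zoneStart - zoneLength >= 0`.
#'
#' @slot u0 Plateau velocity, um/s.
#' @slot zoneStart Position where deceleration begins, um.
#' @slot zoneLength Length of the decelerating zone, um.
#' @aliases LeakyTubeParams
#' @seealso [leakyTubeParams()], [predictVelocity()], [fitUnloadingZone()]
#' @export
setClass("LeakyTubeParams",
  representation(u0 = "numeric", zoneStart = "numeric", zoneLength = "numeric")
)

setValidity("LeakyTubeParams", function(object) {
  if (!is.finite(object@u0) || object@u0 <= 0) return("u0 must be strictly positive")
  if (!is.finite(object@zoneLength) || object@zoneLength < 0) {
    return("zoneLength must be non-negative")
  }
  if (!is.finite(object@zoneStart) || object@zoneStart < object@zoneLength) {
    return("zoneStart must be >= zoneLength (the zone ends at or before PSE zero)")
  }
  TRUE
})

#' Velocity-vs-position profile
#'
#' @slot position Positions, um basipetal from PSE zero, strictly
#'   increasing.
#' @slot velocity Velocities, um/s, non-negative.
#' @slot sd Optional per-point SD, um/s (length 0 if absent).
#' @aliases VelocityProfile
#' @seealso [velocityProfile()], [fitUnloadingZone()]
#' @export
setClass("VelocityProfile",
  representation(position = "numeric", velocity = "numeric", sd = "numeric")
)

setValidity("VelocityProfile", function(object) {
  p <- object@position
  v <- object@velocity
  if (length(p) != length(v)) return("position and velocity lengths differ")
  if (any(!is.finite(p)) || any(diff(p) <= 0)) {
    return("positions must be finite and strictly increasing")
  }
  if (any(!is.finite(v)) || any(v < 0)) return("velocities must be non-negative")
  if (length(object@sd) && (length(object@sd) != length(p) ||
    any(!is.finite(object@sd)) || any(object@sd < 0))) {
    return("sd must be empty or one non-negative value per point")
  }
  TRUE
})

#' Full unloading-scenario result
#'
#' All derived quantities of the steady-state unloading budget, in SI.
#' Two-element slots are named `c(full_span, neck_only)` for the
#' desmotubule-placement extremes, or `c(low, high)` for the membrane
#' permeability bounds.
#'
#' @slot Q Volumetric flow to be unloaded, m^3/s.
#' @slot I Solute flux, mol/s.
#' @slot dPSimple Pressure differential for bulk flow through the
#'   all-simple PD population, Pa.
#' @slot dPFunnel Pressure differentials for the mixed simple+funnel
#'   population under the two desmotubule extremes, Pa.
#' @slot dcDiffusive Concentration difference for purely diffusive
#'   unloading through the mixed population, mol/m^3.
#' @slot dpMembrane Pressure to remove the solvent across the lateral
#'   membrane at the two permeability bounds, Pa.
#' @slot peclet Peclet number (Q_pd / P_pd) of a single funnel PD under
#'   each desmotubule extreme at the operating point.
#' @slot osmoticEquivalent Van 't Hoff concentration equivalents of
#'   `dPFunnel`, mol/m^3.
#' @slot tube,sap Input echoes.
#' @slot populations List of `list(geom =, count =)` used.
#' @aliases ScenarioResult
#' @seealso [scenarioReport()]
#' @export
setClass("ScenarioResult",
  representation(
    Q = "numeric", I = "numeric", dPSimple = "numeric", dPFunnel = "numeric",
    dcDiffusive = "numeric", dpMembrane = "numeric", peclet = "numeric",
    osmoticEquivalent = "numeric", tube = "TubeGeometry",
    sap = "SapProperties", populations = "list"
  )
)

#' Fitted unloading-zone parameters
#'
#' @slot params Point estimates as a [LeakyTubeParams-class].
#' @slot ci Matrix of bootstrap percentile confidence intervals (rows
#'   `u0`, `zoneStart`; columns `lower`, `upper`).
#' @slot degenerate `TRUE` when the profile carries no deceleration
#'   signal (fit collapses to a constant; `zoneLength = 0`).
#' @slot rss Residual sum of squares at the optimum.
#' @slot boot Matrix of bootstrap replicate estimates.
#' @aliases UnloadingZoneFit
#' @seealso [fitUnloadingZone()]
#' @export
setClass("UnloadingZoneFit",
  representation(
    params = "LeakyTubeParams", ci = "matrix", degenerate = "logical",
    rss = "numeric", boot = "matrix"
  )
)

## ---- accessors ----

#' Accessors for phloemflow classes
#'
#' Small accessor generics returning slot values in SI units (metres,
#' seconds, Pa, mol/m^3), except the leaky-tube classes which work in
#' the micrometre units of the measurements.
#'
#' @param x An object of the matching class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("wallLength", "PDGeometry", function(x) x@wall)
#' @rdname accessors
#' @export
setMethod("desmotubuleRadius", "PDGeometry", function(x) x@desmotubule / 2)
#' @rdname accessors
#' @export
setMethod("neckRadius", "PDGeometry", function(x) x@desmotubule / 2 + x@sleeve)
#' @rdname accessors
#' @export
setMethod("mouthRadius", "SimplePD", function(x) neckRadius(x))
#' @rdname accessors
#' @export
setMethod("mouthRadius", "FunnelPD", function(x) x@mouth / 2)
#' @rdname accessors
#' @export
setMethod("desmotubuleMode", "FunnelPD", function(x) x@mode)
#' @rdname accessors
#' @export
setMethod("viscosity", "SapProperties", function(x) x@viscosity)
#' @rdname accessors
#' @export
setMethod("diffusivity", "SapProperties", function(x) x@diffusivity)
#' @rdname accessors
#' @export
setMethod("hindrance", "SapProperties", function(x) x@hindrance)
#' @rdname accessors
#' @export
setMethod("sapConcentration", "SapProperties", function(x) x@concentration)
#' @rdname accessors
#' @export
setMethod("temperature", "SapProperties", function(x) x@temperature)
#' @rdname accessors
#' @export
setMethod("tubeDiameter", "TubeGeometry", function(x) x@diameter)
#' @rdname accessors
#' @export
setMethod("flowVelocity", "TubeGeometry", function(x) x@velocity)
#' @rdname accessors
#' @export
setMethod("zoneLength", "TubeGeometry", function(x) x@zone)
#' @rdname accessors
#' @export
setMethod("lpRange", "TubeGeometry", function(x) x@lp)
#' @rdname accessors
#' @export
setMethod("censusTotal", "PDCensus", function(x) x@total)
#' @rdname accessors
#' @export
setMethod("censusFractions", "PDCensus", function(x) x@fractions)
#' @rdname accessors
#' @export
setMethod("positions", "VelocityProfile", function(x) x@position)
#' @rdname accessors
#' @export
setMethod("velocities", "VelocityProfile", function(x) x@velocity)

## ---- show methods ----

setMethod("show", "SimplePD", function(object) {
  cat(sprintf(
    "SimplePD: desmotubule %.3g nm, sleeve %.3g nm, length %.3g nm (outer radius %.3g nm)\n",
    object@desmotubule * 1e9, object@sleeve * 1e9, object@wall * 1e9,
    neckRadius(object) * 1e9
  ))
})

setMethod("show", "FunnelPD", function(object) {
  cat(sprintf(
    "FunnelPD: mouth %.3g nm -> neck %.3g nm over %.3g nm; desmotubule %.3g nm (%s%s)\n",
    object@mouth * 1e9, 2 * neckRadius(object) * 1e9, object@wall * 1e9,
    object@desmotubule * 1e9, object@mode,
    if (object@mode == "neck_only") {
      sprintf(", neck fraction %.3g", object@neckFraction)
    } else {
      ""
    }
  ))
})

setMethod("show", "SapProperties", function(object) {
  cat(sprintf(
    "SapProperties: viscosity %.3g mPa s, D %.3g m^2/s (H = %.3g), c %.3g mM, T %.1f K\n",
    object@viscosity * 1e3, object@diffusivity, object@hindrance,
    object@concentration, object@temperature
  ))
})

setMethod("show", "TubeGeometry", function(object) {
  cat(sprintf(
    "TubeGeometry: d %.3g um, u %.3g um/s, unloading zone %.3g um, Lp [%.1g, %.1g] m/s/Pa\n",
    object@diameter * 1e6, object@velocity * 1e6, object@zone * 1e6,
    object@lp[1], object@lp[2]
  ))
})

setMethod("show", "PDCensus", function(object) {
  cat(sprintf(
    "PDCensus: %.4g +/- %.3g PD per unloading domain (n = %d)\n",
    object@total, object@sd, as.integer(object@n)
  ))
  f <- object@fractions
  cat(sprintf(
    "  fractions: PSE-PPP %.1f%%, PSE-CC %.1f%%, PSE-MSE %.1f%%\n",
    100 * f[1], 100 * f[2], 100 * f[3]
  ))
})

setMethod("show", "LeakyTubeParams", function(object) {
  cat(sprintf(
    "LeakyTubeParams: u0 %.3g um/s, deceleration from %.3g um, zone length %.3g um\n",
    object@u0, object@zoneStart, object@zoneLength
  ))
})

setMethod("show", "VelocityProfile", function(object) {
  cat(sprintf(
    "VelocityProfile: %d points, %.3g-%.3g um, velocities %.3g-%.3g um/s\n",
    length(object@position), min(object@position), max(object@position),
    min(object@velocity), max(object@velocity)
  ))
})

setMethod("show", "UnloadingZoneFit", function(object) {
  show(object@params)
  if (object@degenerate) {
    cat("  [degenerate: no deceleration detected]\n")
  } else if (nrow(object@ci)) {
    cat(sprintf(
      "  95%% CI: u0 [%.3g, %.3g] um/s, zoneStart [%.3g, %.3g] um\n",
      object@ci["u0", 1], object@ci["u0", 2],
      object@ci["zoneStart", 1], object@ci["zoneStart", 2]
    ))
  }
  invisible(NULL)
})
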