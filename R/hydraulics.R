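#' @include AllClasses.R
NULL

#' Construct phloem sap properties
#'
#' Defaults describe sap of ~500 mM sucrose: viscosity 1.74 mPa s,
#' free sucrose diffusivity 5.2e-10 m^2/s with no additional pore
#' hindrance (H = 1), at 298 K. Viscosity and diffusivity are the
#' assumed (literature-range) values of the base scenario and are
#' flagged as assumptions in scenario logs.
#'
#' @param viscosity Dynamic viscosity, Pa s.
#' @param diffusivity Free solute diffusivity, m^2/s.
#' @param hindrance Hindrance factor in (0, 1] on diffusivity inside
#'   pores.
#' @param concentration Solute concentration, mol/m^3 (numerically equal
#'   to mM).
#' @param temperature Temperature, K.
#' @return A [SapProperties-class] object.
#' @examples
#' sapProperties()
#' @export
sapProperties <- function(viscosity = .DEFAULT_VISCOSITY,
                          diffusivity = .DEFAULT_DIFFUSIVITY,
                          hindrance = .DEFAULT_HINDRANCE,
                          concentration = .DEFAULT_CONCENTRATION,
                          temperature = .DEFAULT_TEMPERATURE) {
  methods::new("SapProperties",
    viscosity = viscosity, diffusivity = diffusivity, hindrance = hindrance,
    concentration = concentration, temperature = temperature
  )
}

# Poiseuille shape factor of a concentric annulus, outer radius r,
# inner radius a: Q = pi dP k / (8 mu L). Vectorised over r.
.annulus_k <- function(r, a) {
  r^4 - a^4 - (r^2 - a^2)^2 / log(r / a)
}

# Local resistance per unit length (Pa s / m^4) of a circular section
# of radius r, optionally with a concentric desmotubule of radius a.
.resistance_density <- function(r, a, mu, annular) {
  k <- if (annular) .annulus_k(r, a) else r^4
  8 * mu / (pi * k)
}

# Series (lubrication) integral of the local resistance over [x0, x1].
.integrate_resistance <- function(r_of, a, mu, x0, x1, annular) {
  if (x1 <= x0) {
    return(0)
  }
  stats::integrate(
    function(x) .resistance_density(r_of(x), a, mu, annular),
    x0, x1,
    rel.tol = 1e-8
  )$value
}

#' Hydraulic resistance of an open tapered tube
#'
#' Lubrication-theory resistance of a desmotubule-free cone of radius
#' `r1` at the entrance tapering linearly to `r2` over length `L`,
#' computed with the same adaptive integrator that handles funnel
#' plasmodesmata. The closed form
#' `(8 mu L / 3 pi) (r1^2 + r1 r2 + r2^2) / (r1^3 r2^3)` is its exact
#' value and serves as the integrator's regression oracle.
#'
#' @param r1,r2 Entrance / exit radii, m.
#' @param L Length, m.
#' @param sap A [SapProperties-class] object (only viscosity is used).
#' @return Resistance, Pa s/m^3.
#' @export
openConeResistance <- function(r1, r2, L, sap) {
  .assert_scalar(r1, "r1")
  .assert_scalar(r2, "r2")
  .assert_scalar(L, "L")
  r_of <- function(x) r1 + (r2 - r1) * x / L
  .integrate_resistance(r_of, a = 0, viscosity(sap), 0, L, annular = FALSE)
}

#' Hydraulic resistance of a simple (annular) plasmodesma
#'
#' Exact Poiseuille resistance of a concentric annulus (inner radius =
#' desmotubule radius, outer = desmotubule radius + sleeve) of the
#' channel length: `R = 8 mu L / (pi k)` with
#' `k = b^4 - a^4 - (b^2 - a^2)^2 / ln(b/a)`. `model = "slit"` instead
#' uses the planar thin-slit approximation `12 mu L / (w h^3)` with `w`
#' the mean circumference and `h` the sleeve width; for the default
#' geometry the two agree to better than 0.1%.
#'
#' @param geom A [SimplePD-class] object.
#' @param sap A [SapProperties-class] object.
#' @param model `"annulus"` (exact, default) or `"slit"`.
#' @return Resistance, Pa s/m^3.
#' @examples
#' annularResistance(simplePD(), sapProperties())
#' @export
annularResistance <- function(geom, sap, model = c("annulus", "slit")) {
  stopifnot(methods::is(geom, "SimplePD"))
  methods::validObject(geom)
  methods::validObject(sap)
  model <- match.arg(model)
  a <- desmotubuleRadius(geom)
  b <- neckRadius(geom)
  mu <- viscosity(sap)
  L <- wallLength(geom)
  if (model == "annulus") {
    8 * mu * L / (pi * .annulus_k(b, a))
  } else {
    w <- pi * (a + b) # mean circumference of the sleeve
    h <- geom@sleeve
    12 * mu * L / (w * h^3)
  }
}

#' Hydraulic resistance of a funnel plasmodesma
#'
#' Series (lubrication) integration of the local cross-section
#' resistance along the linear taper from mouth to neck:
#' `R = \int_0^L 8 mu / (pi k(x)) dx`, where `k(x)` is the annulus shape
#' factor where the desmotubule is present and `r(x)^4` (open circular
#' section) where it is not. Under `"full_span"` every section is
#' annular; under `"neck_only"` only the final `neckFraction` of the
#' length is. Adaptive quadrature at relative tolerance 1e-8; the
#' open-cone closed form is the regression oracle for the integrator.
#'
#' @param geom A [FunnelPD-class] object.
#' @param sap A [SapProperties-class] object.
#' @return Resistance, Pa s/m^3; always <= the matching simple-PD
#'   resistance, with equality when mouth = neck.
#' @examples
#' funnelResistance(funnelPD(), sapProperties())
#' funnelResistance(funnelPD(mode = "neck_only"), sapProperties())
#' @export
funnelResistance <- function(geom, sap) {
  stopifnot(methods::is(geom, "FunnelPD"))
  methods::validObject(geom)
  methods::validObject(sap)
  a <- desmotubuleRadius(geom)
  mu <- viscosity(sap)
  L <- wallLength(geom)
  r_of <- function(x) radiusProfile(geom, x)
  xb <- if (geom@mode == "full_span") 0 else (1 - geom@neckFraction) * L
  .integrate_resistance(r_of, a, mu, 0, xb, annular = FALSE) +
    .integrate_resistance(r_of, a, mu, xb, L, annular = TRUE)
}

#' @rdname hydraulicResistance
#' @export
setMethod("hydraulicResistance", "SimplePD", function(geom, sap, ...) {
  annularResistance(geom, sap, ...)
})

#' @rdname hydraulicResistance
#' @export
setMethod("hydraulicResistance", "FunnelPD", function(geom, sap, ...) {
  funnelResistance(geom, sap)
})

#' Pressure differential to drive a flow through a plasmodesma population
#'
#' The pores act as parallel hydraulic paths at a common pressure drop:
#' `dP = Q_total / sum(count_i / R_i)`. Flow partitions itself across
#' pore classes in proportion to conductance (pressure-equilibrated
#' parallel paths), not equally per pore.
#'
#' @param Q_total Total volumetric flow, m^3/s (>= 0).
#' @param population A list of `list(geom = <PDGeometry>, count = <n>)`
#'   entries, or a single [PDGeometry-class] (with `count`) for
#'   convenience.
#' @param sap A [SapProperties-class] object.
#' @param count Count used when `population` is a single geometry.
#' @param ... Passed to [hydraulicResistance()] (e.g. `model = "slit"`
#'   for simple PD).
#' @return Pressure differential, Pa.
#' @examples
#' sap <- sapProperties()
#' populationPressure(230e-18, simplePD(), sap, count = 240) # ~8.14 MPa
#' pop <- list(
#'   list(geom = simplePD(), count = 24),
#'   list(geom = funnelPD(), count = 216)
#' )
#' populationPressure(230e-18, pop, sap) # ~0.17 MPa
#' @export
populationPressure <- function(Q_total, population, sap, count = 1, ...) {
  .assert_scalar(Q_total, "Q_total", positive = FALSE, nonneg = TRUE)
  if (methods::is(population, "PDGeometry")) {
    population <- list(list(geom = population, count = count))
  }
  if (!length(population)) stop("population must contain at least one PD", call. = FALSE)
  conductance <- 0
  for (entry in population) {
    if (!methods::is(entry$geom, "PDGeometry") || is.null(entry$count)) {
      stop("each population entry must be list(geom = <PDGeometry>, count = <n>)",
        call. = FALSE
      )
    }
    .assert_scalar(entry$count, "count", positive = FALSE, nonneg = TRUE)
    if (entry$count == 0) next
    conductance <- conductance + entry$count / hydraulicResistance(entry$geom, sap, ...)
  }
  if (conductance == 0) stop("population has zero total conductance", call. = FALSE)
  Q_total / conductance
}
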