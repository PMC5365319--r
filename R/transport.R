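#' @include AllClasses.R
NULL

#' Construct the sieve-tube geometry of the unloading zone
#'
#' Defaults are the FRAP-derived measurements for the Arabidopsis root
#' protophloem: tube diameter 3.6 um, flow velocity 22.6 um/s in the
#' translocation zone, a 350 um unloading zone, and reported plasma-
#' membrane permeabilities spanning 1e-14 to 1e-12 m/s/Pa.
#'
#' @param diameter Sieve-tube diameter, um.
#' @param velocity Axial flow velocity, um/s.
#' @param zone Unloading-zone length, um.
#' @param lp Membrane hydraulic permeability bounds `c(low, high)`,
#'   m/s/Pa (a single value is used for both bounds).
#' @return A [TubeGeometry-class] object (lengths stored in metres).
#' @examples
#' tubeGeometry()
#' @export
tubeGeometry <- function(diameter = .DEFAULT_TUBE_DIAMETER_UM,
                         velocity = .DEFAULT_FLOW_VELOCITY_UM_S,
                         zone = .DEFAULT_ZONE_LENGTH_UM,
                         lp = .DEFAULT_LP_RANGE) {
  if (length(lp) == 1L) lp <- c(lp, lp)
  methods::new("TubeGeometry",
    diameter = diameter * 1e-6, velocity = velocity * 1e-6,
    zone = zone * 1e-6, lp = unname(sort(lp))
  )
}

#' Volumetric flow carried by one sieve-tube file
#'
#' `Q = (pi/4) d^2 u`: the volume arriving per unit time that must be
#' unloaded from a single protophloem file. With the default geometry
#' this is 230 fl/s (230 um^3/s).
#'
#' @param tube A [TubeGeometry-class] object.
#' @return Q, m^3/s.
#' @examples
#' volumetricFlow(tubeGeometry()) * 1e18 # fl/s
#' @export
volumetricFlow <- function(tube) {
  stopifnot(methods::is(tube, "TubeGeometry"))
  methods::validObject(tube)
  pi / 4 * tubeDiameter(tube)^2 * flowVelocity(tube)
}

#' Solute flux carried by a volumetric flow
#'
#' `I = Q c`: with the default 230 fl/s and 500 mM this is
#' ~1.2e-13 mol/s of sucrose to be unloaded.
#'
#' @param Q Volumetric flow, m^3/s (>= 0).
#' @param c Solute concentration, mol/m^3 (>= 0).
#' @return I, mol/s.
#' @examples
#' soluteFlux(230e-18, 500)
#' @export
soluteFlux <- function(Q, c) {
  .assert_scalar(Q, "Q", positive = FALSE, nonneg = TRUE)
  .assert_scalar(c, "c", positive = FALSE, nonneg = TRUE)
  Q * c
}

#' @rdname diffusivePermeability
#' @export
setMethod("diffusivePermeability", "SimplePD", function(geom, sap, ...) {
  methods::validObject(geom)
  methods::validObject(sap)
  a <- desmotubuleRadius(geom)
  b <- neckRadius(geom)
  Deff <- hindrance(sap) * diffusivity(sap)
  Deff * pi * (b^2 - a^2) / wallLength(geom)
})

#' @rdname diffusivePermeability
#' @export
setMethod("diffusivePermeability", "FunnelPD", function(geom, sap, ...) {
  methods::validObject(geom)
  methods::validObject(sap)
  a <- desmotubuleRadius(geom)
  Deff <- hindrance(sap) * diffusivity(sap)
  L <- wallLength(geom)
  xb <- if (geom@mode == "full_span") 0 else (1 - geom@neckFraction) * L
  open_area <- function(x, annular) {
    r <- radiusProfile(geom, x)
    if (annular) pi * (r^2 - a^2) else pi * r^2
  }
  acc <- 0
  if (xb > 0) {
    acc <- acc + stats::integrate(function(x) 1 / open_area(x, FALSE),
      0, xb,
      rel.tol = 1e-8
    )$value
  }
  if (xb < L) {
    acc <- acc + stats::integrate(function(x) 1 / open_area(x, TRUE),
      xb, L,
      rel.tol = 1e-8
    )$value
  }
  Deff / acc
})

#' Summed diffusive permeability of a plasmodesma population
#'
#' @inheritParams populationPressure
#' @return Total permeability, m^3/s.
#' @export
populationPermeability <- function(population, sap, count = 1) {
  if (methods::is(population, "PDGeometry")) {
    population <- list(list(geom = population, count = count))
  }
  if (!length(population)) stop("population must contain at least one PD", call. = FALSE)
  total <- 0
  for (entry in population) {
    total <- total + entry$count * diffusivePermeability(entry$geom, sap)
  }
  total
}

#' Concentration difference required for purely diffusive unloading
#'
#' `dc = I / P_total` for a solute flux `I` through a population of
#' total diffusive permeability `P_total`.
#'
#' @param I Solute flux, mol/s (>= 0).
#' @param P_total Total diffusive permeability, m^3/s (> 0).
#' @return dc, mol/m^3.
#' @examples
#' requiredConcentrationDifference(1e-15, 1e-18) # 1000 mol/m^3
#' @export
requiredConcentrationDifference <- function(I, P_total) {
  .assert_scalar(I, "I", positive = FALSE, nonneg = TRUE)
  .assert_scalar(P_total, "P_total")
  I / P_total
}

#' Steady convection-diffusion flux through a pore
#'
#' Patlak's solution for combined advection and diffusion through a
#' channel: `I = Q (c_up - c_down e^{-Pe}) / (1 - e^{-Pe})` with Peclet
#' number `Pe = Q / P`. Continuous at `Pe -> 0`, where it reduces to
#' pure diffusion `P (c_up - c_down)`; at large Pe it tends to pure
#' advection `Q c_up`. Computed via `expm1` so small Pe needs no special
#' casing beyond `Q = 0`.
#'
#' @param Q_pd Volumetric flow through the pore, m^3/s (>= 0).
#' @param P_pd Diffusive permeability of the pore, m^3/s (> 0).
#' @param c_up,c_down Upstream / downstream concentrations, mol/m^3.
#' @return Solute flux, mol/s.
#' @examples
#' convectiveFlux(0, 1e-18, 500, 100)    # diffusion limit
#' convectiveFlux(1e-18, 1e-18, 1, 0)    # Pe = 1: 1/(1 - exp(-1)) * Q
#' @export
convectiveFlux <- function(Q_pd, P_pd, c_up, c_down) {
  .assert_scalar(Q_pd, "Q_pd", positive = FALSE, nonneg = TRUE)
  .assert_scalar(P_pd, "P_pd")
  .assert_scalar(c_up, "c_up", positive = FALSE, nonneg = TRUE)
  .assert_scalar(c_down, "c_down", positive = FALSE, nonneg = TRUE)
  if (Q_pd == 0) {
    return(P_pd * (c_up - c_down))
  }
  Pe <- Q_pd / P_pd
  em <- -expm1(-Pe) # 1 - exp(-Pe), accurate for small Pe
  Q_pd * (c_up - c_down * exp(-Pe)) / em
}

#' Pressure to remove the solvent across the lateral membrane
#'
#' If solutes leave by diffusion, the water must exit across the plasma
#' membrane of the sieve elements: `dp = Q / (Lp A)` with `A = pi d l`
#' the lateral area of the tube over the unloading zone. At the
#' reported permeability bounds this spans ~0.059 MPa (Lp = 1e-12) to
#' ~5.9 MPa (Lp = 1e-14).
#'
#' @param Q Volumetric flow, m^3/s (>= 0).
#' @param tube A [TubeGeometry-class] object.
#' @param Lp Membrane permeability, m/s/Pa; defaults to both stored
#'   bounds, returning a named pair.
#' @return Pressure(s), Pa.
#' @examples
#' membraneWaterPressure(230e-18, tubeGeometry()) / 1e6 # MPa at both bounds
#' @export
membraneWaterPressure <- function(Q, tube, Lp = lpRange(tube)) {
  .assert_scalar(Q, "Q", positive = FALSE, nonneg = TRUE)
  stopifnot(methods::is(tube, "TubeGeometry"))
  methods::validObject(tube)
  if (any(!is.finite(Lp)) || any(Lp <= 0)) {
    stop("Lp must be strictly positive", call. = FALSE)
  }
  A <- pi * tubeDiameter(tube) * zoneLength(tube)
  if (A <= 0) stop("membrane area must be positive", call. = FALSE)
  out <- Q / (Lp * A)
  if (length(out) == 2L && is.null(names(Lp))) names(out) <- c("low_Lp", "high_Lp")
  out
}

#' Van 't Hoff osmotic equivalence
#'
#' `vantHoff` converts a pressure differential to the equivalent solute
#' concentration difference, `dc = dp / (R T)`; `vantHoffPressure` is
#' the exact inverse, `dp = R T dc`. A 0.05-0.2 MPa differential is
#' osmotically equivalent to ~20-80 mM at 298 K.
#'
#' @param dp Pressure differential, Pa.
#' @param dc Concentration difference, mol/m^3.
#' @param T Temperature, K.
#' @return Concentration difference (mol/m^3) or pressure (Pa).
#' @examples
#' vantHoff(0.2e6) # ~80 mol/m^3
#' vantHoffPressure(vantHoff(0.2e6)) # exact round trip
#' @export
vantHoff <- function(dp, T = .DEFAULT_TEMPERATURE) {
  .assert_scalar(T, "T")
  dp / (.R_GAS * T)
}

#' @rdname vantHoff
#' @export
vantHoffPressure <- function(dc, T = .DEFAULT_TEMPERATURE) {
  .assert_scalar(T, "T")
  dc * .R_GAS * T
}
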