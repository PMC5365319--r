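#' @include constants.R
NULL

#' Outer wall radius of a plasmodesma along its axis
#'
#' Returns the radius of the wall channel (not the desmotubule) at axial
#' position `x`, measured from the sieve-element-side wall face (`x = 0`)
#' towards the pericycle side (`x = wallLength`). Constant for simple
#' plasmodesmata; a linear taper from mouth to neck for funnel
#' plasmodesmata.
#'
#' @param geom A [PDGeometry-class] object.
#' @param x Axial position(s) in metres, in `[0, wallLength(geom)]`.
#' @return Numeric vector of outer radii in metres.
#' @examples
#' radiusProfile(simplePD(), 0)            # 10.3 nm
#' radiusProfile(funnelPD(), 0)            # 75 nm mouth
#' radiusProfile(funnelPD(), 500e-9)       # 10.3 nm neck
#' @export
setGeneric("radiusProfile", function(geom, x) standardGeneric("radiusProfile"))

#' Hydraulic resistance of a single plasmodesma
#'
#' Pressure drop per unit volumetric flow (Pa s/m^3) for low-Reynolds-number
#' pressure-driven flow through one pore. Simple plasmodesmata use the
#' exact concentric-annulus Poiseuille solution (or a thin-slit
#' approximation); funnels are integrated section-by-section along the
#' taper under the lubrication approximation.
#'
#' @param geom A [PDGeometry-class] object.
#' @param sap A [SapProperties-class] object.
#' @param ... Method-specific options; see [annularResistance()] and
#'   [funnelResistance()].
#' @return Hydraulic resistance in Pa s/m^3.
#' @seealso [populationPressure()]
#' @export
setGeneric("hydraulicResistance", function(geom, sap, ...) {
  standardGeneric("hydraulicResistance")
})

#' Diffusive permeability of a single plasmodesma
#'
#' Solute flux per unit concentration difference (m^3/s) for Fickian
#' diffusion through the open cross-section of one pore, using an
#' effective diffusivity `hindrance(sap) * diffusivity(sap)`. Constant
#' sections reduce to `D_eff A / L`; tapered pores use the series
#' (harmonic) combination `[\int dx / (D_eff A(x))]^{-1}`.
#'
#' @inheritParams hydraulicResistance
#' @return Diffusive permeability in m^3/s.
#' @export
setGeneric("diffusivePermeability", function(geom, sap, ...) {
  standardGeneric("diffusivePermeability")
})

#' @rdname accessors
#' @export
setGeneric("wallLength", function(x) standardGeneric("wallLength"))
#' @rdname accessors
#' @export
setGeneric("desmotubuleRadius", function(x) standardGeneric("desmotubuleRadius"))
#' @rdname accessors
#' @export
setGeneric("neckRadius", function(x) standardGeneric("neckRadius"))
#' @rdname accessors
#' @export
setGeneric("mouthRadius", function(x) standardGeneric("mouthRadius"))
#' @rdname accessors
#' @export
setGeneric("desmotubuleMode", function(x) standardGeneric("desmotubuleMode"))
#' @rdname accessors
#' @export
setGeneric("viscosity", function(x) standardGeneric("viscosity"))
#' @rdname accessors
#' @export
setGeneric("diffusivity", function(x) standardGeneric("diffusivity"))
#' @rdname accessors
#' @export
setGeneric("hindrance", function(x) standardGeneric("hindrance"))
#' @rdname accessors
#' @export
setGeneric("sapConcentration", function(x) standardGeneric("sapConcentration"))
#' @rdname accessors
#' @export
setGeneric("temperature", function(x) standardGeneric("temperature"))
#' @rdname accessors
#' @export
setGeneric("tubeDiameter", function(x) standardGeneric("tubeDiameter"))
#' @rdname accessors
#' @export
setGeneric("flowVelocity", function(x) standardGeneric("flowVelocity"))
#' @rdname accessors
#' @export
setGeneric("zoneLength", function(x) standardGeneric("zoneLength"))
#' @rdname accessors
#' @export
setGeneric("lpRange", function(x) standardGeneric("lpRange"))
#' @rdname accessors
#' @export
setGeneric("censusTotal", function(x) standardGeneric("censusTotal"))
#' @rdname accessors
#' @export
setGeneric("censusFractions", function(x) standardGeneric("censusFractions"))
#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("velocities", function(x) standardGeneric("velocities"))
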