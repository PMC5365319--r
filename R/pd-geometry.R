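#' @include AllClasses.R
NULL

#' Construct a simple (cylindrical) plasmodesma
#'
#' Defaults describe the plasmodesmata of the protophloem unloading
#' zone: 15 nm desmotubule, 2.8 nm cytoplasmic sleeve (the hydrodynamic
#' radius of GFP, taken as the size exclusion limit of the neck) through
#' a 500 nm cell wall.
#'
#' @param desmotubule Desmotubule diameter.
#' @param sleeve Cytoplasmic sleeve width (radial gap).
#' @param wall Cell-wall thickness = channel length.
#' @param units Unit of the three lengths: `"nm"` (default), `"um"` or
#'   `"m"`. Stored internally in metres.
#' @return A [SimplePD-class] object.
#' @examples
#' simplePD()
#' simplePD(desmotubule = 15, sleeve = 2.8, wall = 1000) # doubled wall
#' @export
simplePD <- function(desmotubule = .DEFAULT_DESMOTUBULE_NM,
                     sleeve = .DEFAULT_SLEEVE_NM,
                     wall = .DEFAULT_WALL_NM,
                     units = "nm") {
  s <- .unit_factor(units)
  methods::new("SimplePD",
    desmotubule = desmotubule * s, sleeve = sleeve * s, wall = wall * s
  )
}

#' Construct a funnel-shaped plasmodesma
#'
#' Defaults describe the funnel plasmodesmata at the PSE-PPP interface:
#' a 150 nm aperture at the sieve-element mouth tapering linearly to the
#' simple-PD neck (15 nm desmotubule + 2.8 nm sleeve) over a 500 nm
#' wall. `mode` selects the desmotubule-placement extreme (see
#' [FunnelPD-class]); `neckFraction` only matters for `"neck_only"`,
#' where its default confines the desmotubule to the narrow terminus of
#' the taper.
#'
#' @inheritParams simplePD
#' @param mouth Aperture diameter at the sieve-element entrance.
#' @param mode `"full_span"` (default) or `"neck_only"`.
#' @param neckFraction Fraction of the length obstructed by the
#'   desmotubule in `"neck_only"` mode.
#' @return A [FunnelPD-class] object.
#' @examples
#' funnelPD()
#' funnelPD(mode = "neck_only")
#' funnelPD(mouth = 20.6) # degenerate: equals the simple PD
#' @export
funnelPD <- function(mouth = .DEFAULT_MOUTH_NM,
                     desmotubule = .DEFAULT_DESMOTUBULE_NM,
                     sleeve = .DEFAULT_SLEEVE_NM,
                     wall = .DEFAULT_WALL_NM,
                     mode = c("full_span", "neck_only"),
                     neckFraction = .DEFAULT_NECK_FRACTION,
                     units = "nm") {
  mode <- match.arg(mode)
  s <- .unit_factor(units)
  methods::new("FunnelPD",
    desmotubule = desmotubule * s, sleeve = sleeve * s, wall = wall * s,
    mouth = mouth * s, mode = mode, neckFraction = neckFraction
  )
}

.check_axial <- function(geom, x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > geom@wall * (1 + 1e-12))) {
    stop("axial position x must lie in [0, wallLength] = [0, ",
      format(geom@wall), "] m",
      call. = FALSE
    )
  }
  pmin(x, geom@wall)
}

#' @rdname radiusProfile
#' @export
setMethod("radiusProfile", "SimplePD", function(geom, x) {
  x <- .check_axial(geom, x)
  rep(neckRadius(geom), length(x))
})

#' @rdname radiusProfile
#' @export
setMethod("radiusProfile", "FunnelPD", function(geom, x) {
  x <- .check_axial(geom, x)
  r1 <- mouthRadius(geom)
  r2 <- neckRadius(geom)
  r1 + (r2 - r1) * x / geom@wall
})
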