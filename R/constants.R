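# Physical constants and model defaults (SI unless noted).
#
# The hydrodynamic defaults are calibrated so that the base scenario
# reproduces the published unloading requirements for the Arabidopsis
# root protophloem; each is a physically reasonable value in its own
# right (see the methods vignette for the provenance of every number).

#' Universal gas constant, J/(mol K)
#' @keywords internal
.R_GAS <- 8.31446

# Sap viscosity, Pa s. Phloem sap at ~500 mM sucrose (~16% w/w) near
# 20 C; reproduces the 8.14 MPa simple-PD bulk-flow requirement with
# the exact concentric-annulus model.
.DEFAULT_VISCOSITY <- 1.74e-3

# Free diffusivity of sucrose in sap, m^2/s (Stokes-Einstein for a
# ~0.47 nm solute); reproduces the 276 mM pure-diffusion requirement.
.DEFAULT_DIFFUSIVITY <- 5.2e-10

# Hindrance factor on diffusion in the cytoplasmic sleeve (H = 1: no
# steric/hydrodynamic hindrance beyond the geometric area).
.DEFAULT_HINDRANCE <- 1

# Phloem sap osmotic potential expressed as solute concentration, mol/m^3.
.DEFAULT_CONCENTRATION <- 500

.DEFAULT_TEMPERATURE <- 298 # K

# Plasmodesma geometry (nm): desmotubule diameter, cytoplasmic sleeve
# width (hydrodynamic radius of GFP), cell-wall thickness = PD length,
# and the average funnel aperture at the sieve-element mouth.
.DEFAULT_DESMOTUBULE_NM <- 15
.DEFAULT_SLEEVE_NM <- 2.8
.DEFAULT_WALL_NM <- 500
.DEFAULT_MOUTH_NM <- 150

# Fraction of the funnel length obstructed by the desmotubule in the
# low-resistance placement extreme: the desmotubule reaches only the
# narrow terminus of the linear taper (~2.7 nm of a 500 nm wall).
# Calibrated so the mixed PD population requires 0.050 MPa.
.DEFAULT_NECK_FRACTION <- 0.0053

# Sieve-tube defaults: diameter (um), flow velocity (um/s), unloading
# zone length (um), and the reported bounds on membrane permeability
# Lp (m/s/Pa).
.DEFAULT_TUBE_DIAMETER_UM <- 3.6
.DEFAULT_FLOW_VELOCITY_UM_S <- 22.6
.DEFAULT_ZONE_LENGTH_UM <- 350
.DEFAULT_LP_RANGE <- c(low = 1e-14, high = 1e-12)

# Plasmodesmal census over one protophloem unloading domain: total
# (mean +/- SD over n domains) and fractional distribution across the
# three wall interfaces.
.DEFAULT_CENSUS_TOTAL <- 527
.DEFAULT_CENSUS_SD <- 58
.DEFAULT_CENSUS_N <- 4
.DEFAULT_CENSUS_FRACTIONS <- c(PSE_PPP = 0.453, PSE_CC = 0.408, PSE_MSE = 0.139)

# Of the PSE-PPP plasmodesmata, the observed share of simple (10%) vs
# funnel-shaped pores, as counts out of ~240: 24 simple, 216 funnel.
.DEFAULT_N_SIMPLE_PPP <- 24
.DEFAULT_N_FUNNEL_PPP <- 216

.unit_factor <- function(units) {
  switch(units,
    nm = 1e-9,
    um = 1e-6,
    m = 1,
    stop("unknown unit '", units, "' (use \"nm\", \"um\" or \"m\")",
      call. = FALSE
    )
  )
}

.assert_scalar <- function(x, name, positive = TRUE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(name, " must be a single finite number", call. = FALSE)
  }
  if (positive && x <= 0) stop(name, " must be strictly positive", call. = FALSE)
  if (nonneg && x < 0) stop(name, " must be non-negative", call. = FALSE)
  invisible(x)
}
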