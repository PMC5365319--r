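#' @include AllClasses.R
NULL

# Schema: every recognised key with its default and whether the default
# is a measured base-scenario value or a modelling assumption (the
# latter are tagged "[assumption]" in the run log).
.config_schema <- function() {
  list(
    tube = list(
      diameter_um = list(default = .DEFAULT_TUBE_DIAMETER_UM, assumption = FALSE),
      velocity_um_s = list(default = .DEFAULT_FLOW_VELOCITY_UM_S, assumption = FALSE),
      zone_length_um = list(default = .DEFAULT_ZONE_LENGTH_UM, assumption = FALSE),
      lp_low = list(default = .DEFAULT_LP_RANGE[["low"]], assumption = FALSE),
      lp_high = list(default = .DEFAULT_LP_RANGE[["high"]], assumption = FALSE)
    ),
    sap = list(
      viscosity_pa_s = list(default = .DEFAULT_VISCOSITY, assumption = TRUE),
      diffusivity_m2_s = list(default = .DEFAULT_DIFFUSIVITY, assumption = TRUE),
      hindrance = list(default = .DEFAULT_HINDRANCE, assumption = TRUE),
      concentration_mm = list(default = .DEFAULT_CONCENTRATION, assumption = FALSE),
      temperature_k = list(default = .DEFAULT_TEMPERATURE, assumption = TRUE)
    ),
    pd = list(
      desmotubule_nm = list(default = .DEFAULT_DESMOTUBULE_NM, assumption = FALSE),
      sleeve_nm = list(default = .DEFAULT_SLEEVE_NM, assumption = FALSE),
      wall_nm = list(default = .DEFAULT_WALL_NM, assumption = FALSE),
      mouth_nm = list(default = .DEFAULT_MOUTH_NM, assumption = FALSE),
      neck_fraction = list(default = .DEFAULT_NECK_FRACTION, assumption = TRUE),
      annulus_model = list(default = "annulus", assumption = TRUE)
    ),
    census = list(
      total = list(default = .DEFAULT_CENSUS_TOTAL, assumption = FALSE),
      sd = list(default = .DEFAULT_CENSUS_SD, assumption = FALSE),
      n = list(default = .DEFAULT_CENSUS_N, assumption = FALSE),
      fraction_pse_ppp = list(default = .DEFAULT_CENSUS_FRACTIONS[["PSE_PPP"]], assumption = FALSE),
      fraction_pse_cc = list(default = .DEFAULT_CENSUS_FRACTIONS[["PSE_CC"]], assumption = FALSE),
      fraction_pse_mse = list(default = .DEFAULT_CENSUS_FRACTIONS[["PSE_MSE"]], assumption = FALSE)
    ),
    populations = list(
      n_simple_only = list(default = 240, assumption = FALSE),
      n_simple_mixed = list(default = .DEFAULT_N_SIMPLE_PPP, assumption = FALSE),
      n_funnel_mixed = list(default = .DEFAULT_N_FUNNEL_PPP, assumption = FALSE)
    ),
    flags = list(
      leak_law = list(default = "linear", assumption = TRUE)
    ),
    seed = list(default = 1, assumption = FALSE)
  )
}

#' Fully resolved default configuration
#'
#' The nested list of every configuration key with its base-scenario
#' value; the same structure is accepted back by [runScenario()] and is
#' what a YAML configuration file must follow (any subset of keys;
#' unknown keys are errors).
#'
#' @return A nested named list.
#' @examples
#' str(defaultConfig())
#' @export
defaultConfig <- function() {
  schema <- .config_schema()
  resolve <- function(node) {
    if (!is.null(node$default) && !is.list(node$default)) {
      return(node$default)
    }
    lapply(node, resolve)
  }
  out <- lapply(schema, function(sec) {
    if (!is.null(sec$default)) sec$default else lapply(sec, `[[`, "default")
  })
  out
}

.validate_section <- function(user, schema, path) {
  if (is.null(user)) {
    return(invisible(NULL))
  }
  if (!is.list(user)) {
    stop("configuration section '", path, "' must be a mapping", call. = FALSE)
  }
  unknown <- setdiff(names(user), names(schema))
  if (length(unknown)) {
    stop("unknown configuration key(s) under '", path, "': ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(NULL)
}

#' Read and resolve a run configuration
#'
#' Reads a YAML configuration, validates it against the schema (unknown
#' keys are errors, not warnings; malformed values are reported by
#' field name), and fills every missing key from the base-scenario
#' defaults. The returned object records which keys were defaulted and
#' which of those are modelling assumptions.
#'
#' @param path Path to a YAML file, or `NULL` for an all-defaults run.
#' @param config A nested list used instead of reading `path`.
#' @return A list with elements `config` (fully resolved), `defaulted`
#'   (character keys filled from defaults) and `assumptions` (the
#'   subset that are modelling assumptions).
#' @export
readRunConfig <- function(path = NULL, config = NULL) {
  if (is.null(config)) {
    if (is.null(path)) {
      config <- list()
    } else {
      if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
      config <- yaml::read_yaml(path)
      if (is.null(config)) config <- list()
    }
  }
  schema <- .config_schema()
  if (!is.list(config)) stop("configuration must be a mapping", call. = FALSE)
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) {
    stop("unknown top-level configuration key(s): ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  resolved <- list()
  defaulted <- character()
  assumptions <- character()
  for (section in names(schema)) {
    spec <- schema[[section]]
    if (!is.null(spec$default)) { # scalar top-level key (seed)
      if (!is.null(config[[section]])) {
        resolved[[section]] <- config[[section]]
      } else {
        resolved[[section]] <- spec$default
        defaulted <- c(defaulted, section)
        if (isTRUE(spec$assumption)) assumptions <- c(assumptions, section)
      }
      next
    }
    .validate_section(config[[section]], spec, section)
    sec_out <- list()
    for (key in names(spec)) {
      full <- paste(section, key, sep = ".")
      user_val <- config[[section]][[key]]
      if (!is.null(user_val)) {
        sec_out[[key]] <- user_val
      } else {
        sec_out[[key]] <- spec[[key]]$default
        defaulted <- c(defaulted, full)
        if (isTRUE(spec[[key]]$assumption)) assumptions <- c(assumptions, full)
      }
    }
    resolved[[section]] <- sec_out
  }
  .check_config_values(resolved)
  list(config = resolved, defaulted = defaulted, assumptions = assumptions)
}

.check_config_values <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid configuration value for '", field, "': ", why, call. = FALSE)
  }
  pos <- c(
    "tube.diameter_um", "tube.zone_length_um", "tube.lp_low", "tube.lp_high",
    "sap.viscosity_pa_s", "sap.diffusivity_m2_s", "sap.concentration_mm",
    "sap.temperature_k", "pd.desmotubule_nm", "pd.sleeve_nm", "pd.wall_nm",
    "pd.mouth_nm", "census.total"
  )
  for (field in pos) {
    parts <- strsplit(field, ".", fixed = TRUE)[[1]]
    val <- cfg[[parts[1]]][[parts[2]]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0) {
      bad(field, "must be a single strictly positive number")
    }
  }
  if (!is.numeric(cfg$tube$velocity_um_s) || cfg$tube$velocity_um_s < 0) {
    bad("tube.velocity_um_s", "must be non-negative")
  }
  if (cfg$pd$neck_fraction <= 0 || cfg$pd$neck_fraction > 1) {
    bad("pd.neck_fraction", "must lie in (0, 1]")
  }
  if (!cfg$pd$annulus_model %in% c("annulus", "slit")) {
    bad("pd.annulus_model", 'must be "annulus" or "slit"')
  }
  if (!cfg$flags$leak_law %in% c("linear", "exponential")) {
    bad("flags.leak_law", 'must be "linear" or "exponential"')
  }
  fr <- c(
    cfg$census$fraction_pse_ppp, cfg$census$fraction_pse_cc,
    cfg$census$fraction_pse_mse
  )
  if (any(fr < 0) || abs(sum(fr) - 1) > 0.005) {
    bad("census.fraction_*", "fractions must be non-negative and sum to 1 within 0.005")
  }
  counts <- c(
    cfg$populations$n_simple_only, cfg$populations$n_simple_mixed,
    cfg$populations$n_funnel_mixed
  )
  if (any(!is.finite(counts)) || any(counts < 0)) {
    bad("populations.*", "PD counts must be non-negative")
  }
  invisible(cfg)
}

# Build model objects from a resolved configuration.
.config_objects <- function(cfg) {
  tube <- tubeGeometry(
    diameter = cfg$tube$diameter_um, velocity = cfg$tube$velocity_um_s,
    zone = cfg$tube$zone_length_um, lp = c(cfg$tube$lp_low, cfg$tube$lp_high)
  )
  sap <- sapProperties(
    viscosity = cfg$sap$viscosity_pa_s, diffusivity = cfg$sap$diffusivity_m2_s,
    hindrance = cfg$sap$hindrance, concentration = cfg$sap$concentration_mm,
    temperature = cfg$sap$temperature_k
  )
  census <- pdCensus(
    total = cfg$census$total, sd = cfg$census$sd, n = cfg$census$n,
    fractions = c(
      cfg$census$fraction_pse_ppp, cfg$census$fraction_pse_cc,
      cfg$census$fraction_pse_mse
    )
  )
  sgeom <- simplePD(
    desmotubule = cfg$pd$desmotubule_nm, sleeve = cfg$pd$sleeve_nm,
    wall = cfg$pd$wall_nm
  )
  fgeom <- funnelPD(
    mouth = cfg$pd$mouth_nm, desmotubule = cfg$pd$desmotubule_nm,
    sleeve = cfg$pd$sleeve_nm, wall = cfg$pd$wall_nm,
    neckFraction = cfg$pd$neck_fraction
  )
  populations <- list(
    simple_only = list(list(geom = sgeom, count = cfg$populations$n_simple_only)),
    mixed = list(
      list(geom = sgeom, count = cfg$populations$n_simple_mixed),
      list(geom = fgeom, count = cfg$populations$n_funnel_mixed)
    )
  )
  list(tube = tube, sap = sap, census = census, populations = populations)
}
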