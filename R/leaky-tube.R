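#' @include AllClasses.R
NULL

#' Construct leaky-tube parameters
#'
#' @param u0 Plateau velocity in the translocation zone, um/s.
#' @param zoneStart Position (um basipetal from PSE zero) where
#'   deceleration begins.
#' @param zoneLength Length of the decelerating zone, um; defaults to
#'   `zoneStart` (the zone terminates at PSE zero, where the tube ends
#'   and all remaining flow unloads).
#' @return A [LeakyTubeParams-class] object.
#' @examples
#' leakyTubeParams(u0 = 22.6, zoneStart = 350)
#' @export
leakyTubeParams <- function(u0 = .DEFAULT_FLOW_VELOCITY_UM_S,
                            zoneStart = .DEFAULT_ZONE_LENGTH_UM,
                            zoneLength = zoneStart) {
  methods::new("LeakyTubeParams",
    u0 = u0, zoneStart = zoneStart, zoneLength = zoneLength
  )
}

#' Construct a velocity profile
#'
#' @param position Positions, um basipetal from PSE zero (strictly
#'   increasing).
#' @param velocity Velocities, um/s.
#' @param sd Optional per-point standard deviations, um/s.
#' @return A [VelocityProfile-class] object.
#' @export
velocityProfile <- function(position, velocity, sd = numeric()) {
  methods::new("VelocityProfile",
    position = as.numeric(position), velocity = as.numeric(velocity),
    sd = as.numeric(sd)
  )
}

.predict_u <- function(u0, zoneStart, zoneLength, x, law = "linear") {
  if (zoneLength == 0) {
    return(rep(u0, length(x))) # impermeable walls: constant velocity
  }
  zoneEnd <- zoneStart - zoneLength
  if (law == "linear") {
    u <- u0 * (x - zoneEnd) / zoneLength
  } else { # pressure-proportional leak: exponential decline
    u <- u0 * exp((x - zoneStart) / zoneLength)
  }
  pmin(pmax(u, 0), u0)
}

#' Predict sieve-tube velocity along the unloading zone
#'
#' In a tube of constant diameter with impermeable walls the velocity
#' is constant; where the walls leak, axial velocity falls in
#' proportion to the cumulative fluid loss. Under the default uniform
#' leak per unit length the decline is linear from `u0` at `zoneStart`
#' to zero at the end of the zone; `law = "exponential"` instead models
#' pressure-proportional leakage (exponential decline with length scale
#' `zoneLength`).
#'
#' @param params A [LeakyTubeParams-class] object.
#' @param positions Positions, um basipetal from PSE zero.
#' @param law `"linear"` (uniform leak, default) or `"exponential"`.
#' @return A [VelocityProfile-class] object.
#' @examples
#' predictVelocity(leakyTubeParams(22.6, 350), c(0, 175, 350, 500))
#' @export
predictVelocity <- function(params, positions, law = c("linear", "exponential")) {
  stopifnot(methods::is(params, "LeakyTubeParams"))
  methods::validObject(params)
  law <- match.arg(law)
  positions <- sort(as.numeric(positions))
  velocityProfile(
    positions,
    .predict_u(params@u0, params@zoneStart, params@zoneLength, positions, law)
  )
}

# Profiled least squares at a fixed breakpoint b (zone ends at 0):
# basis w(x) = min(x/b, 1), u0_hat = <w, v> / <w, w>.
.profile_fit <- function(x, v, b, law) {
  w <- if (law == "linear") {
    pmin(x / b, 1)
  } else {
    pmin(exp((x - b) / b), 1)
  }
  ww <- sum(w * w)
  if (ww == 0) {
    return(list(u0 = 0, rss = sum(v^2)))
  }
  u0 <- sum(w * v) / ww
  list(u0 = u0, rss = sum((v - u0 * w)^2))
}

.fit_breakpoint <- function(x, v, law) {
  lo <- max(min(x), 1e-6)
  hi <- max(x)
  grid <- sort(unique(c(x[x >= lo], seq(lo, hi, length.out = 201))))
  rss <- vapply(grid, function(b) .profile_fit(x, v, b, law)$rss, numeric(1))
  # ties broken toward the smaller zoneStart
  best <- which(rss <= min(rss) * (1 + 1e-12))[1]
  b <- grid[best]
  lwr <- grid[max(best - 1L, 1L)]
  upr <- grid[min(best + 1L, length(grid))]
  if (upr > lwr) {
    opt <- stats::optimize(
      function(b) .profile_fit(x, v, b, law)$rss,
      interval = c(lwr, upr), tol = 1e-10 * hi
    )
    if (opt$objective <= rss[best]) b <- opt$minimum
  }
  fit <- .profile_fit(x, v, b, law)
  list(u0 = fit$u0, zoneStart = b, rss = fit$rss)
}

#' Fit the unloading zone from a velocity profile
#'
#' Fits the continuous piecewise model (plateau `u0`, linear or
#' exponential decline to zero at PSE zero) by least squares profiled
#' over the breakpoint `zoneStart`: for each candidate breakpoint the
#' plateau velocity has a closed-form solution, and the breakpoint is
#' located by a grid search refined with golden-section minimisation
#' (ties broken toward the smaller `zoneStart`). Percentile confidence
#' intervals come from resampling residuals.
#'
#' A profile with no deceleration signal (constant velocities, or best
#' fit indistinguishable from a constant) is flagged `degenerate` and
#' returned with `zoneLength = 0`.
#'
#' @param profile A [VelocityProfile-class] with at least 5 points
#'   spanning plateau and decline.
#' @param law Leak law, as in [predictVelocity()].
#' @param nboot Number of bootstrap replicates (0 disables the CIs).
#' @param conf Confidence level.
#' @param seed Optional integer seed for the bootstrap.
#' @return An [UnloadingZoneFit-class] object.
#' @examples
#' prof <- predictVelocity(leakyTubeParams(22.6, 350), seq(20, 600, by = 20))
#' fitUnloadingZone(prof, nboot = 0)
#' @export
fitUnloadingZone <- function(profile, law = c("linear", "exponential"),
                             nboot = 199, conf = 0.95, seed = NULL) {
  stopifnot(methods::is(profile, "VelocityProfile"))
  methods::validObject(profile)
  law <- match.arg(law)
  x <- positions(profile)
  v <- velocities(profile)
  if (length(x) < 5L) {
    stop("at least 5 points spanning plateau and decline are required",
      call. = FALSE
    )
  }

  no_ci <- matrix(numeric(), 0, 2)
  if (stats::var(v) == 0) {
    params <- methods::new("LeakyTubeParams",
      u0 = max(mean(v), .Machine$double.eps), zoneStart = 0, zoneLength = 0
    )
    return(methods::new("UnloadingZoneFit",
      params = params, ci = no_ci, degenerate = TRUE, rss = 0,
      boot = matrix(numeric(), 0, 2)
    ))
  }

  fit <- .fit_breakpoint(x, v, law)
  # degenerate if a constant fits essentially as well as the breakpoint model
  rss_const <- sum((v - mean(v))^2)
  if (fit$rss >= rss_const * (1 - 1e-10)) {
    params <- methods::new("LeakyTubeParams",
      u0 = mean(v), zoneStart = 0, zoneLength = 0
    )
    return(methods::new("UnloadingZoneFit",
      params = params, ci = no_ci, degenerate = TRUE, rss = rss_const,
      boot = matrix(numeric(), 0, 2)
    ))
  }

  params <- methods::new("LeakyTubeParams",
    u0 = fit$u0, zoneStart = fit$zoneStart, zoneLength = fit$zoneStart
  )

  ci <- no_ci
  boot <- matrix(numeric(), 0, 2)
  if (nboot > 0) {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
        add = TRUE
      )
      set.seed(seed)
    }
    fitted <- .predict_u(fit$u0, fit$zoneStart, fit$zoneStart, x, law)
    resid <- v - fitted
    boot <- t(vapply(seq_len(nboot), function(i) {
      vb <- pmax(fitted + sample(resid, replace = TRUE), 0)
      fb <- .fit_breakpoint(x, vb, law)
      c(fb$u0, fb$zoneStart)
    }, numeric(2)))
    colnames(boot) <- c("u0", "zoneStart")
    alpha <- (1 - conf) / 2
    ci <- t(apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha)))
    dimnames(ci) <- list(c("u0", "zoneStart"), c("lower", "upper"))
  }

  methods::new("UnloadingZoneFit",
    params = params, ci = ci, degenerate = FALSE, rss = fit$rss, boot = boot
  )
}

#' Read / write velocity profiles as CSV
#'
#' Two- or three-column CSV `position_um, velocity_um_s[, sd]`.
#'
#' @param profile A [VelocityProfile-class] object.
#' @param path CSV file path.
#' @return `writeVelocityCsv` invisibly returns `path`;
#'   `readVelocityCsv` returns a [VelocityProfile-class].
#' @export
writeVelocityCsv <- function(profile, path) {
  df <- data.frame(
    position_um = positions(profile),
    velocity_um_s = velocities(profile)
  )
  if (length(profile@sd)) df$sd <- profile@sd
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVelocityCsv
#' @export
readVelocityCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("position_um", "velocity_um_s") %in% names(df))) {
    stop("velocity CSV must have columns position_um, velocity_um_s",
      call. = FALSE
    )
  }
  velocityProfile(
    df$position_um, df$velocity_um_s,
    if ("sd" %in% names(df)) df$sd else numeric()
  )
}
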