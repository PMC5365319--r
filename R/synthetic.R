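#' @include AllClasses.R
NULL

# Evaluate `expr` under a seeded RNG stream, restoring the caller's
# RNG state afterwards: generators are pure functions of (spec, seed).
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Sample a synthetic measurement set
#'
#' Emulates a reported "mean +/- SD (n)" measurement series (e.g. flow
#' velocity 22.6 +/- 5.1 um/s, tube diameter 3.6 +/- 0.44 um): `n`
#' draws from a normal law with the stated moments, clamped at 0 for
#' physical positivity. At the measurement regimes modelled here the
#' clamp touches well under 1% of draws. Identical `(mean, sd, n,
#' seed)` give bit-identical output; the caller's RNG state is left
#' untouched.
#'
#' @param mean,sd Mean and standard deviation in native units (`sd >= 0`).
#' @param n Number of draws (`>= 1`).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @examples
#' sampleMeasurements(22.6, 5.1, n = 11, seed = 1)
#' @export
sampleMeasurements <- function(mean, sd, n, seed) {
  .assert_scalar(mean, "mean", positive = FALSE)
  .assert_scalar(sd, "sd", positive = FALSE, nonneg = TRUE)
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  .with_seed(seed, pmax(stats::rnorm(n, mean, sd), 0))
}

#' Sample synthetic plasmodesmal censuses
#'
#' For each draw, the domain total comes from a normal law (rounded,
#' clamped at 0) and is then allocated multinomially across the three
#' wall interfaces with the census fractions, so per-draw counts always
#' sum to the drawn total.
#'
#' @param nDraws Number of census realizations.
#' @param census A [PDCensus-class] supplying the total's mean/SD and
#'   the interface fractions.
#' @param seed Integer seed.
#' @return A data frame with columns `total`, `PSE_PPP`, `PSE_CC`,
#'   `PSE_MSE`.
#' @examples
#' samplePDCensus(5, pdCensus(), seed = 1)
#' @export
samplePDCensus <- function(nDraws, census = pdCensus(), seed) {
  stopifnot(methods::is(census, "PDCensus"))
  if (!is.numeric(nDraws) || nDraws < 1) stop("nDraws must be >= 1", call. = FALSE)
  f <- censusFractions(census)
  .with_seed(seed, {
    totals <- pmax(round(stats::rnorm(nDraws, censusTotal(census), census@sd)), 0)
    counts <- vapply(
      totals,
      function(tt) {
        if (tt == 0) c(0, 0, 0) else as.numeric(stats::rmultinom(1, tt, f))
      },
      numeric(3)
    )
    data.frame(
      total = totals, PSE_PPP = counts[1, ], PSE_CC = counts[2, ],
      PSE_MSE = counts[3, ]
    )
  })
}

#' Synthesize a noisy velocity profile
#'
#' [predictVelocity()] output plus seeded Gaussian noise, clamped at 0.
#'
#' @inheritParams predictVelocity
#' @param noiseSd Gaussian noise SD, um/s.
#' @param seed Integer seed.
#' @return A [VelocityProfile-class] with `sd` set to `noiseSd`.
#' @examples
#' synthVelocityProfile(leakyTubeParams(22.6, 350), seq(25, 600, by = 25),
#'   noiseSd = 2, seed = 1
#' )
#' @export
synthVelocityProfile <- function(params, positions, noiseSd, seed,
                                 law = c("linear", "exponential")) {
  law <- match.arg(law)
  .assert_scalar(noiseSd, "noiseSd", positive = FALSE, nonneg = TRUE)
  clean <- predictVelocity(params, positions, law)
  v <- .with_seed(
    seed,
    pmax(velocities(clean) + stats::rnorm(length(positions), 0, noiseSd), 0)
  )
  velocityProfile(positions(clean), v, rep(noiseSd, length(positions)))
}

#' Regenerate all synthetic fixtures
#'
#' Writes the full set of synthetic measurement CSVs (flow velocities,
#' tube diameters, censuses, a noisy velocity profile) under `dir`.
#' Everything derives deterministically from the single `seed`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @return Character vector of files written, invisibly.
#' @export
writeFixtures <- function(dir = "fixtures", seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    velocity = file.path(dir, "flow_velocity_um_s.csv"),
    diameter = file.path(dir, "tube_diameter_um.csv"),
    census = file.path(dir, "pd_census.csv"),
    profile = file.path(dir, "velocity_profile.csv")
  )
  # sub-seeds derived from the master seed keep streams independent
  utils::write.csv(
    data.frame(velocity_um_s = sampleMeasurements(22.6, 5.1, 11, seed = seed)),
    files["velocity"],
    row.names = FALSE
  )
  utils::write.csv(
    data.frame(diameter_um = sampleMeasurements(3.6, 0.44, 11, seed = seed + 1)),
    files["diameter"],
    row.names = FALSE
  )
  utils::write.csv(
    samplePDCensus(4, pdCensus(), seed = seed + 2),
    files["census"],
    row.names = FALSE
  )
  writeVelocityCsv(
    synthVelocityProfile(
      leakyTubeParams(), seq(25, 600, by = 25),
      noiseSd = 2, seed = seed + 3
    ),
    files["profile"]
  )
  invisible(files)
}
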