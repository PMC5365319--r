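#' @include AllClasses.R
NULL

#' Construct a plasmodesmal census
#'
#' Defaults are the serial block-face EM census of one protophloem
#' unloading domain: 527 +/- 58 plasmodesmata (n = 4 domains)
#' distributed 45.3% / 40.8% / 13.9% across the PSE-PPP, PSE-CC and
#' PSE-MSE wall interfaces.
#'
#' @param total Mean total plasmodesmata per unloading domain.
#' @param sd Standard deviation of the total.
#' @param n Number of domains measured.
#' @param fractions Three fractions for interfaces
#'   (PSE-PPP, PSE-CC, PSE-MSE); must sum to 1 within 0.005.
#' @return A [PDCensus-class] object.
#' @examples
#' pdCensus()
#' interfaceCounts(pdCensus())
#' @export
pdCensus <- function(total = .DEFAULT_CENSUS_TOTAL,
                     sd = .DEFAULT_CENSUS_SD,
                     n = .DEFAULT_CENSUS_N,
                     fractions = .DEFAULT_CENSUS_FRACTIONS) {
  fractions <- stats::setNames(
    as.numeric(fractions),
    c("PSE_PPP", "PSE_CC", "PSE_MSE")
  )
  methods::new("PDCensus", total = total, sd = sd, n = n, fractions = fractions)
}

#' Plasmodesma counts per wall interface
#'
#' Allocates the census total across the three interfaces by nearest-
#' integer rounding of `round(total) * fraction`. Because the three
#' rounding errors each lie in \[-0.5, 0.5\] and must sum to an integer,
#' the counts always sum to within 1 of the (rounded) total. The
#' PSE-PPP count is additionally reported to the nearest ten in the
#' `reported` column, matching how such censuses are quoted
#' (527 x 45.3% = 238.7, "approximately 240").
#'
#' @param census A [PDCensus-class] object.
#' @return A data frame with columns `interface`, `fraction`, `count`
#'   (nearest integer) and `reported` (PSE-PPP to the nearest ten,
#'   others as `count`).
#' @examples
#' interfaceCounts(pdCensus()) # counts 239, 215, 73; reported 240, 215, 73
#' @export
interfaceCounts <- function(census) {
  stopifnot(methods::is(census, "PDCensus"))
  methods::validObject(census)
  total <- round(censusTotal(census))
  f <- censusFractions(census)
  counts <- as.integer(round(total * f))
  reported <- counts
  reported[1] <- as.integer(round(total * f[1], -1))
  data.frame(
    interface = c("PSE-PPP", "PSE-CC", "PSE-MSE"),
    fraction = unname(f),
    count = counts,
    reported = reported,
    stringsAsFactors = FALSE
  )
}

#' Read / write an interface-count table as CSV
#'
#' The on-disk format is `interface,fraction,count` (the `reported`
#' column is additionally written but ignored on read).
#'
#' @param census A [PDCensus-class] object.
#' @param path CSV file path.
#' @return `writeCensusCsv` invisibly returns `path`; `readCensusCsv`
#'   returns the data frame.
#' @export
writeCensusCsv <- function(census, path) {
  utils::write.csv(interfaceCounts(census), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCensusCsv
#' @export
readCensusCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("interface", "fraction", "count")
  if (!all(need %in% names(df))) {
    stop("census CSV must have columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  df[need]
}
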