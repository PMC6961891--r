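#' Construct a population time series
#'
#' A `population_series` is the sole input of the shift-detection
#' machinery: one abundance value per consecutive year. Abundance units
#' are arbitrary (individuals, mean trap captures, hectares occupied) —
#' the Ricker parameters inherit whatever unit the series carries.
#'
#' @param years Integer vector of time labels, strictly increasing by
#'   exactly 1 (annual steps with no gaps).
#' @param abundance Numeric vector of positive, finite population sizes,
#'   one per year.
#' @return An object of class `population_series`: a `data.frame` with
#'   columns `year` and `abundance`.
#' @examples
#' population_series(2000:2011, 500 * exp(rnorm(12, 0, 0.1)))
#' @export
population_series <- function(years, abundance) {
  years <- as.integer(years)
  abundance <- as.numeric(abundance)
  if (length(years) != length(abundance)) {
    stop("`years` and `abundance` must have the same length", call. = FALSE)
  }
  if (length(years) < 4L) {
    stop("a population series needs at least 4 data points ",
         "(the minimum fittable segment)", call. = FALSE)
  }
  if (anyNA(years)) stop("`years` contains missing values", call. = FALSE)
  dup <- unique(years[duplicated(years)])
  if (length(dup)) {
    stop("duplicate year(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(years, strictly = TRUE)) {
    o <- order(years)
    years <- years[o]
    abundance <- abundance[o]
  }
  gaps <- which(diff(years) != 1L)
  if (length(gaps)) {
    missing_years <- unlist(lapply(gaps, function(i) {
      seq(years[i] + 1L, years[i + 1L] - 1L)
    }))
    stop("series has gaps; missing year(s): ",
         paste(missing_years, collapse = ", "),
         " (the method assumes consecutive annual steps)", call. = FALSE)
  }
  if (any(!is.finite(abundance)) || any(abundance <= 0)) {
    bad <- years[!is.finite(abundance) | abundance <= 0]
    stop("abundance must be finite and > 0; offending year(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    data.frame(year = years, abundance = abundance),
    class = c("population_series", "data.frame")
  )
}

#' Read a population time series from CSV
#'
#' Expects two columns, year and abundance, in that order (a header row
#' is detected and tolerated; extra columns are ignored). Rows are
#' sorted by year; gaps, duplicate years and non-positive abundances are
#' hard errors because the detector's transition-pair likelihood assumes
#' consecutive annual steps.
#'
#' @param path Path to a CSV file.
#' @return A [population_series].
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- utils::read.csv(path, header = FALSE, nrows = 1,
                           strip.white = TRUE)
  has_header <- is.na(suppressWarnings(as.numeric(first[[1]][1])))
  d <- utils::read.csv(path, header = has_header, strip.white = TRUE)
  if (ncol(d) < 2) stop("need at least two columns (year, abundance)",
                        call. = FALSE)
  yr <- suppressWarnings(as.numeric(d[[1]]))
  ab <- suppressWarnings(as.numeric(d[[2]]))
  if (anyNA(yr) || any(yr != round(yr))) {
    stop("first column must be integer years", call. = FALSE)
  }
  if (anyNA(ab)) stop("second column must be numeric abundance", call. = FALSE)
  population_series(yr, ab)
}

#' Write a population time series to CSV
#'
#' @param series A [population_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  series <- as_population_series(series)
  utils::write.csv(as.data.frame(series)[c("year", "abundance")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

as_population_series <- function(x) {
  if (inherits(x, "population_series")) return(x)
  if (is.data.frame(x) && all(c("year", "abundance") %in% names(x))) {
    return(population_series(x$year, x$abundance))
  }
  stop("cannot interpret input as a population series", call. = FALSE)
}

#' @export
print.population_series <- function(x, ...) {
  cat(sprintf("Population time series: %d annual observations, %d-%d\n",
              nrow(x), min(x$year), max(x$year)))
  cat(sprintf("  abundance range: %.4g-%.4g (mean %.4g)\n",
              min(x$abundance), max(x$abundance), mean(x$abundance)))
  tb <- attr(x, "true_breaks")
  if (!is.null(tb)) {
    cat("  simulated; true break(s) after year(s): ",
        if (length(tb)) paste(tb, collapse = ", ") else "none", "\n",
        sep = "")
  }
  invisible(x)
}
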