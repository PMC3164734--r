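#' Age-rate series
#'
#' An observed or simulated table of death rates by age: either single ages
#' or half-open age intervals `[low, high)`, rates per 100,000 person-years,
#' and optional per-age population counts (used for Poisson simulation and
#' group aggregation weights).
#'
#' @param ages numeric vector of strictly increasing age coordinates
#'   (years), or `NULL` when `age_low`/`age_high` are supplied.
#' @param rates non-negative rates, same length as the age coordinates.
#' @param age_low,age_high optional strictly increasing interval bounds;
#'   when given, the series is interval-typed and the point coordinate is
#'   the interval midpoint.
#' @param population optional positive per-age population counts.
#' @param label free-text provenance tag (e.g. country, year, gender).
#'
#' @return a data frame of class `"age_rate_series"` with columns `age`,
#'   `age_low`, `age_high` (NA for point series), `rate` and optionally
#'   `population`; the label is stored as the `"label"` attribute.
#' @examples
#' s <- age_rate_series(ages = 10:15, rates = c(0, 0.1, 0.5, 1, 1.7, 2.1))
#' @export
age_rate_series <- function(ages = NULL, rates, age_low = NULL,
                            age_high = NULL, population = NULL, label = "") {
  interval <- !is.null(age_low)
  if (interval) {
    if (is.null(age_high) || length(age_low) != length(age_high))
      stop("age_low and age_high must both be given, with equal length")
    if (any(age_high <= age_low))
      stop("age intervals must have age_high > age_low")
    ages <- (age_low + age_high) / 2
  } else {
    if (is.null(ages)) stop("either ages or age_low/age_high is required")
    age_low <- rep(NA_real_, length(ages))
    age_high <- rep(NA_real_, length(ages))
  }
  if (length(ages) == 0L) stop("series must contain at least one point")
  if (length(rates) != length(ages))
    stop("ages and rates must have equal length")
  if (any(!is.finite(ages)) || any(!is.finite(rates)))
    stop("ages and rates must be finite")
  if (any(diff(ages) <= 0)) stop("ages must be strictly increasing")
  if (any(rates < 0)) stop("rates must be >= 0")
  out <- data.frame(age = as.numeric(ages), age_low = as.numeric(age_low),
                    age_high = as.numeric(age_high),
                    rate = as.numeric(rates))
  if (!is.null(population)) {
    if (length(population) != length(ages))
      stop("population must match the number of ages")
    if (any(population <= 0)) stop("population counts must be > 0")
    out$population <- as.numeric(population)
  }
  structure(out, label = as.character(label),
            class = c("age_rate_series", "data.frame"))
}

#' @rdname age_rate_series
#' @param x object to test.
#' @export
is_age_rate_series <- function(x) inherits(x, "age_rate_series")

#' @rdname age_rate_series
#' @export
series_label <- function(x) attr(x, "label") %||% ""

#' @export
print.age_rate_series <- function(x, ...) {
  kind <- if (all(is.na(x$age_low))) "point ages" else "age intervals"
  cat(sprintf("Age-rate series (%d points, %s)", nrow(x), kind))
  if (nzchar(series_label(x))) cat(" -", series_label(x))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
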