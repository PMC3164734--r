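#' Per-year parameter trajectory
#'
#' Orders per-year fit results (or published fixture parameter sets) by
#' calendar year as input to [extrapolate_parameters()]. All entries must
#' share the same exponent and the same fixed-parameter layout.
#'
#' @param years strictly increasing calendar years.
#' @param results list of `"tbm_fit"` or `"tbm_fixture"` objects, one per
#'   year. The critical age travels with each entry (the fitted or printed
#'   value, with its standard error).
#' @return an object of class `"tbm_trajectory"`.
#' @export
parameter_trajectory <- function(years, results) {
  if (length(years) != length(results))
    stop("years and results must have equal length")
  if (length(years) && any(diff(years) <= 0))
    stop("years must be strictly increasing")
  entries <- lapply(results, trajectory_entry)
  if (length(entries) > 1) {
    n0 <- entries[[1]]$exponent
    f0 <- entries[[1]]$fixed
    for (e in entries[-1]) {
      if (e$exponent != n0)
        stop("all entries must share the same exponent")
      if (!setequal(e$fixed, f0))
        stop("all entries must share the same fixed-parameter layout")
    }
  }
  structure(list(years = as.numeric(years), entries = entries),
            class = "tbm_trajectory")
}

trajectory_entry <- function(r) {
  if (inherits(r, "tbm_fit")) {
    list(values = c(unlist(r$params[c("K", "theta", "a", "t_m", "d0")]),
                    t_c = r$critical_age),
         se = c(r$std_errors, t_c = r$critical_age_se),
         exponent = r$params$n, fixed = r$fixed)
  } else if (inherits(r, "tbm_fixture")) {
    list(values = c(unlist(r$params[c("K", "theta", "a", "t_m", "d0")]),
                    t_c = r$critical_age),
         se = c(r$std_errors, t_c = r$critical_age_se),
         exponent = r$params$n, fixed = r$fixed)
  } else if (inherits(r, "tbm_report")) {
    list(values = c(unlist(r$params[c("K", "theta", "a", "t_m", "d0")]),
                    t_c = r$critical_age),
         se = c(r$std_errors[c("K", "theta", "a", "t_m", "d0")],
                t_c = r$critical_age_se),
         exponent = r$params$n, fixed = r$fixed)
  } else {
    stop("trajectory entries must be tbm_fit, tbm_fixture or tbm_report ",
         "objects")
  }
}

#' Linear extrapolation of fitted parameters to a target year
#'
#' For each parameter independently, fits a straight line of value against
#' calendar year (exact through two points, ordinary least squares for
#' more) and evaluates it at the target year. Standard errors are carried
#' forward by the same linear rule, which reproduces published forecast
#' errors for the parameters whose inputs close under printed rounding;
#' cross-year error propagation formulas are deliberately not assumed (see
#' the methods vignette). Fixed parameters (NA standard errors throughout)
#' keep NA errors.
#'
#' @param trajectory a [parameter_trajectory()] with at least two entries.
#' @param target_year calendar year at which to evaluate the lines.
#' @return an object of class `"tbm_forecast"`: `params` (a
#'   [tbm_params()]), `std_errors`, `critical_age`, `critical_age_se`,
#'   `year`, `fixed`.
#' @export
extrapolate_parameters <- function(trajectory, target_year) {
  if (!inherits(trajectory, "tbm_trajectory"))
    stop("trajectory must be a parameter_trajectory()")
  if (length(trajectory$years) < 2)
    stop("extrapolation needs at least two yearly entries")
  yrs <- trajectory$years
  nm <- names(trajectory$entries[[1]]$values)
  vals <- sapply(trajectory$entries, function(e) e$values[nm])
  ses <- sapply(trajectory$entries, function(e) e$se[nm])
  extr <- function(y) {
    if (any(is.na(y))) return(NA_real_)
    if (length(unique(y)) == 1) return(y[1])
    unname(stats::predict(stats::lm(y ~ yrs),
                          newdata = data.frame(yrs = target_year)))
  }
  v <- apply(vals, 1, extr)
  s <- apply(ses, 1, extr)
  names(v) <- names(s) <- nm
  params <- tbm_params(v[["K"]], v[["theta"]], v[["a"]], v[["t_m"]],
                       v[["d0"]], trajectory$entries[[1]]$exponent)
  structure(list(params = params,
                 std_errors = s[c("K", "theta", "a", "t_m", "d0")],
                 critical_age = v[["t_c"]], critical_age_se = s[["t_c"]],
                 year = target_year,
                 fixed = trajectory$entries[[1]]$fixed),
            class = "tbm_forecast")
}

#' @export
print.tbm_forecast <- function(x, ...) {
  cat("TBM parameter forecast for year", x$year, "\n")
  nm <- c("K", "theta", "a", "t_m", "d0")
  print(data.frame(value = unlist(x$params[nm]), std.error = x$std_errors[nm],
                   row.names = nm))
  cat(sprintf("  critical age %.3g (%.2g) yr; exponent n = %d\n",
              x$critical_age, x$critical_age_se, x$params$n))
  invisible(x)
}

band_source <- function(object) {
  if (inherits(object, c("tbm_forecast", "tbm_fixture")))
    list(params = object$params, se = object$std_errors)
  else if (inherits(object, "tbm_fit"))
    list(params = object$params, se = object$std_errors)
  else stop("expected a tbm_forecast, tbm_fixture or tbm_fit object")
}

#' Rate curve with confidence or prediction band
#'
#' Central curve from [evaluate_rate()]; band half-widths from first-order
#' propagation of the per-parameter standard errors through the model
#' (gradients by central finite differences with step `1e-6` of each
#' parameter's scale), scaled by the normal quantile for the requested
#' confidence level (factor 1.0 at the one-standard-deviation level 0.682).
#' A prediction band additionally carries the residual standard deviation
#' `sigma_resid` (envelope for a new observation); a confidence band does
#' not (envelope for the fitted mean curve). Cross-parameter covariance is
#' ignored - only per-parameter errors propagate - which is the convention
#' matching published per-parameter error tables; see the vignette for the
#' conservatism caveat. The lower envelope is floored at zero (rates are
#' non-negative).
#'
#' @param object a `"tbm_forecast"`, `"tbm_fixture"` or `"tbm_fit"` with
#'   standard errors for all non-fixed parameters.
#' @param ages evaluation grid in years.
#' @param level confidence level in (0, 1); 0.682 is one standard
#'   deviation, 0.95 the conventional band level.
#' @param band `"prediction"` or `"confidence"`.
#' @param sigma_resid residual standard deviation added in quadrature for
#'   prediction bands (default 0).
#' @return a data frame of class `"tbm_band"` with columns `age`,
#'   `central`, `lower`, `upper`; level and band type as attributes.
#' @export
predict_curve <- function(object, ages, level = 0.682,
                          band = c("prediction", "confidence"),
                          sigma_resid = 0) {
  band <- match.arg(band)
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  src <- band_source(object)
  p <- src$params
  se <- src$se
  free <- names(se)[!is.na(se)]
  if (length(free) == 0)
    stop("standard errors are missing; cannot construct a band")
  central <- evaluate_rate(ages, p)
  var <- rep(0, length(ages))
  for (nm in free) {
    h <- 1e-6 * max(abs(p[[nm]]), 1e-3)
    pp <- p; pp[[nm]] <- pp[[nm]] + h
    pm <- p; pm[[nm]] <- pm[[nm]] - h
    g <- (rate_kernel(ages, pp, raw_tc(pp)) -
            rate_kernel(ages, pm, raw_tc(pm))) / (2 * h)
    var <- var + (g * se[[nm]])^2
  }
  if (band == "prediction") var <- var + sigma_resid^2
  half <- stats::qnorm((1 + level) / 2) * sqrt(var)
  structure(data.frame(age = ages, central = central,
                       lower = pmax(central - half, 0),
                       upper = central + half),
            level = level, band_type = paste0(band, "-band"),
            class = c("tbm_band", "data.frame"))
}

# critical age without validation (finite-difference probes may sit at the
# admissibility boundary)
raw_tc <- function(p) {
  p$t_m - max(p$theta - p$d0, 0)^(1 / p$n) / p$a^((p$n + 1) / p$n)
}

#' Goodness of a fixed-curve prediction against observed data
#'
#' Compares an observed series with the model curve for a given (e.g.
#' extrapolated) parameter set, with zero free parameters: conventional
#' chi-square over admitted points, degrees of freedom equal to the number
#' of admitted points, and its upper-tail p-value. The Origin-style
#' statistic is reported absent (`NA`), as no fit took place.
#'
#' @param series an [age_rate_series()] of observations.
#' @param params a [tbm_params()] object, or a `"tbm_forecast"` /
#'   `"tbm_fixture"` whose parameters are used.
#' @return a list of class `"tbm_prediction_report"` with `chi2_origin`
#'   (`NA`), `chi2_conventional`, `dof`, `p_value`, `n_points`,
#'   `n_excluded`.
#' @export
evaluate_prediction <- function(series, params) {
  if (!is_age_rate_series(series)) stop("series must be an age_rate_series")
  if (inherits(params, c("tbm_forecast", "tbm_fixture")))
    params <- params$params
  expected <- evaluate_rate(series$age, params)
  chi2 <- chi_square_conventional(series$rate, expected)
  dof <- attr(chi2, "n_used")
  structure(list(params = params, chi2_origin = NA_real_,
                 chi2_conventional = chi2, dof = dof,
                 p_value = p_value(as.numeric(chi2), dof),
                 n_points = nrow(series),
                 n_excluded = attr(chi2, "n_excluded")),
            class = "tbm_prediction_report")
}

#' @export
print.tbm_prediction_report <- function(x, ...) {
  cat(sprintf(
    "TBM prediction check: chi2 (conventional) %.4g | df %d | p %.3g\n",
    as.numeric(x$chi2_conventional), x$dof, x$p_value))
  if (x$n_excluded > 0)
    cat("  ", x$n_excluded, "point(s) below the expected-value floor excluded\n")
  invisible(x)
}
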