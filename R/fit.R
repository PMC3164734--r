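#' Fitting configuration
#'
#' @param initial a [tbm_params()] object of starting values, or `NULL` to
#'   derive them with [initialize_parameters()] at fit time.
#' @param fixed character vector of parameter names (among `"K"`,
#'   `"theta"`, `"a"`, `"t_m"`, `"d0"`) held constant during optimization
#'   (e.g. `c("t_m", "d0")`, the convention used for female series whose
#'   fits do not otherwise converge).
#' @param exponent_candidates odd integers to grid over in
#'   [select_exponent()].
#' @param max_iterations Levenberg-Marquardt iteration cap. Reference fits
#'   converge in 22-30 iterations; the default cap is generous.
#' @param tolerance convergence tolerance on the relative change of the
#'   residual sum of squares.
#' @param free_critical_age logical; if `TRUE` the critical age is an
#'   additional free cut parameter of the optimizer (the convention under
#'   which published tables report a standard error for it). The default
#'   `FALSE` derives it from the other parameters via [critical_age()];
#'   the choice is recorded in the returned fit.
#' @return an object of class `"tbm_fit_config"`.
#' @export
fit_config <- function(initial = NULL, fixed = character(),
                       exponent_candidates = c(7L, 9L, 11L, 13L, 15L),
                       max_iterations = 500L, tolerance = 1e-8,
                       free_critical_age = FALSE) {
  if (!is.null(initial)) validate_tbm_params(initial)
  bad <- setdiff(fixed, c("K", "theta", "a", "t_m", "d0"))
  if (length(bad)) stop("unknown fixed parameter(s): ",
                        paste(bad, collapse = ", "))
  if (any(exponent_candidates < 1 | exponent_candidates %% 2 != 1))
    stop("exponent_candidates must all be odd integers >= 1")
  structure(list(initial = initial, fixed = unique(fixed),
                 exponent_candidates = as.integer(exponent_candidates),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 free_critical_age = isTRUE(free_critical_age)),
            class = "tbm_fit_config")
}

# Documented default starting values used when nothing better is known
# (typical magnitudes for national all-method suicide series fitted with
# exponent 9). Overridable through fit_config(initial = ...).
tbm_default_start <- c(theta = 15, a = 0.15, d0 = 0.002)

#' Heuristic starting values for a fit
#'
#' Implements the standard initialization protocol: the middle age starts
#' at half the population's life expectancy when supplied (otherwise at the
#' rate-weighted median age of the series, a proxy for the location of the
#' central plateau); the product `theta * K` is matched to the observed
#' rate nearest the middle-age start (so `K` starts at that rate divided by
#' the default threshold); the remaining values come from the package
#' defaults `theta = 15`, `a = 0.15 /yr`, `d0 = 0.002 /yr`, `n = 9`.
#'
#' @param series an [age_rate_series()].
#' @param life_expectancy optional life expectancy in years.
#' @param exponent odd exponent for the returned parameter set.
#' @return a [tbm_params()] object of starting values.
#' @export
initialize_parameters <- function(series, life_expectancy = NULL,
                                  exponent = 9L) {
  if (!is_age_rate_series(series)) stop("series must be an age_rate_series")
  if (all(series$rate == 0))
    stop("degenerate series: all rates are zero, no starting values exist")
  t_m0 <- if (!is.null(life_expectancy)) life_expectancy / 2
          else weighted_median(series$age, series$rate)
  r_mid <- series$rate[which.min(abs(series$age - t_m0))]
  if (r_mid <= 0) r_mid <- mean(series$rate[series$rate > 0])
  th0 <- tbm_default_start[["theta"]]
  tbm_params(apex_constant = r_mid / th0, threshold = th0,
             maturation_rate = tbm_default_start[["a"]], middle_age = t_m0,
             quiescent_drive = tbm_default_start[["d0"]],
             exponent = exponent)
}

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

#' Origin-style chi-square statistic
#'
#' The non-conventional reduced form used by the original fitting software:
#' the residual sum of squares divided by the number of data points minus
#' the number of free parameters,
#' \deqn{\chi^2_{orig} = \frac{\sum_i (o_i - e_i)^2}{N - P}.}
#' Unlike the Pearson form it depends on the free-parameter count, which is
#' why fitted tables report two different chi-square columns.
#'
#' @param observed,expected equal-length rate vectors.
#' @param n_free number of free model parameters.
#' @return the statistic (0 iff all residuals are 0).
#' @export
chi_square_origin <- function(observed, expected, n_free) {
  if (length(observed) != length(expected))
    stop("observed and expected must have equal length")
  if (length(observed) <= n_free)
    stop("need more data points than free parameters")
  sum((observed - expected)^2) / (length(observed) - n_free)
}

#' Conventional (Pearson) chi-square statistic
#'
#' `sum((observed - expected)^2 / expected)` over admitted points. Points
#' whose expected rate is below `floor` (for instance ages at or below the
#' critical age, where the model is exactly zero) are excluded to avoid
#' division by zero; the number excluded is attached as attribute
#' `"n_excluded"` and the number admitted as `"n_used"`.
#'
#' @inheritParams chi_square_origin
#' @param floor minimum expected value for a point to enter the sum.
#' @return the statistic, with attributes `n_used` and `n_excluded`.
#' @export
chi_square_conventional <- function(observed, expected, floor = 1e-6) {
  if (length(observed) != length(expected))
    stop("observed and expected must have equal length")
  keep <- expected >= floor
  if (!any(keep))
    stop("all points excluded by the expected-value floor; ",
         "conventional chi-square is undefined")
  structure(sum((observed[keep] - expected[keep])^2 / expected[keep]),
            n_used = sum(keep), n_excluded = sum(!keep))
}

#' Upper-tail chi-square probability
#'
#' Survival probability of the chi-square distribution: the convention that
#' reproduces published p-values computed from conventional chi-squares and
#' their degrees of freedom.
#'
#' @param chi2 statistic, `>= 0`.
#' @param dof degrees of freedom, integer `>= 1`.
#' @return probability in `[0, 1]`.
#' @examples
#' round(p_value(25.08, 10), 3)  # 0.005
#' round(p_value(14.54, 8), 3)   # 0.069
#' @export
p_value <- function(chi2, dof) {
  if (!is.finite(chi2) || chi2 < 0) stop("chi2 must be >= 0")
  if (!is.finite(dof) || dof < 1 || dof != round(dof))
    stop("dof must be an integer >= 1")
  stats::pchisq(chi2, df = dof, lower.tail = FALSE)
}

free_param_names <- function(config) {
  nm <- setdiff(c("K", "theta", "a", "t_m", "d0"), config$fixed)
  if (config$free_critical_age) nm <- c(nm, "t_c")
  nm
}

# Build a full parameter list (plus cut age) from the free vector and the
# fixed template; returns NULL outside the admissible region.
assemble_params <- function(free, template, config) {
  p <- template
  for (nm in setdiff(names(free), "t_c")) p[[nm]] <- free[[nm]]
  if (p$K <= 0 || p$a <= 0 || p$t_m < 0 || p$theta < p$d0 || p$theta < 0)
    return(NULL)
  tc <- if (config$free_critical_age) free[["t_c"]]
        else p$t_m - (p$theta - p$d0)^(1 / p$n) / p$a^((p$n + 1) / p$n)
  list(p = p, tc = tc)
}

#' Fit the TBM to an age-rate series
#'
#' Unweighted least squares by the Levenberg-Marquardt algorithm
#' ([minpack.lm::nls.lm()]): minimizes the residual sum of squares between
#' the observed rates and [evaluate_rate()] at the series' age coordinates
#' (interval ages enter at their midpoints). Parameters listed in
#' `config$fixed` are held at their starting values. Standard errors are
#' the square roots of the diagonal of the residual-variance-scaled
#' covariance `s2 * (J'J)^{-1}` evaluated at convergence, with the Jacobian
#' obtained by central finite differences. The residual variance `s2` is
#' estimated over the on-support points only (model expectation above the
#' floor of [chi_square_conventional()]): below the critical age the model
#' is identically zero with zero gradient, so those points carry no
#' parameter information and would dilute the estimate. The derived
#' critical age's standard error follows by first-order (delta-method)
#' propagation.
#'
#' @param series an [age_rate_series()] with more points than free
#'   parameters.
#' @param config a [fit_config()].
#' @return an object of class `"tbm_fit"`: fitted `params`, `std_errors`
#'   (named; `NA` for fixed parameters), `covariance` (free parameters
#'   only), `critical_age` and `critical_age_se`, `chi2_origin`,
#'   `chi2_conventional` (with exclusion attributes), `dof`, `p_value`,
#'   `n_points`, `iterations`, `converged`, `fixed`, and
#'   `free_critical_age`. Non-convergence within the iteration cap is not
#'   an error: the best-so-far state is returned with `converged = FALSE`.
#' @export
fit_tbm <- function(series, config = fit_config()) {
  if (!is_age_rate_series(series)) stop("series must be an age_rate_series")
  start <- config$initial %||% initialize_parameters(series)
  free_nm <- free_param_names(config)
  n_free <- length(free_nm)
  if (nrow(series) <= n_free)
    stop("series must have more points (", nrow(series),
         ") than free parameters (", n_free, ")")
  ages <- series$age
  obs <- series$rate
  scale <- max(obs)

  start_vec <- unlist(start[setdiff(free_nm, "t_c")])
  if (config$free_critical_age)
    start_vec <- c(start_vec, t_c = critical_age(start))

  resid_fn <- function(v) {
    ap <- assemble_params(as.list(v), start, config)
    if (is.null(ap)) return(rep(1e6 * scale, length(ages)))
    obs - rate_kernel(ages, ap$p, ap$tc)
  }

  fit <- minpack.lm::nls.lm(
    par = start_vec, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = config$max_iterations, ftol = config$tolerance,
      maxfev = max(600L, config$max_iterations *
                     (length(start_vec) + 1L))))

  est <- fit$par
  ap <- assemble_params(as.list(est), start, config)
  if (is.null(ap))
    stop("optimizer terminated outside the admissible parameter region")
  params <- ap$p
  tc <- ap$tc
  expected <- rate_kernel(ages, params, tc)
  rss <- sum((obs - expected)^2)
  n_pts <- length(obs)
  dof <- n_pts - n_free

  # covariance from a central-difference Jacobian at the optimum
  jac <- vapply(seq_along(est), function(j) {
    h <- 1e-6 * max(abs(est[j]), 1e-3)
    vp <- est; vp[j] <- vp[j] + h
    vm <- est; vm[j] <- vm[j] - h
    (resid_fn(vm) - resid_fn(vp)) / (2 * h)  # d(model)/d(par)
  }, numeric(n_pts))
  # Residual variance for the covariance scaling is estimated over the
  # on-support points only (model expectation above the same floor the
  # Pearson statistic uses): below the critical age the model is
  # identically zero with zero gradient, so those points carry no
  # parameter information, and with zero-truncated observations their
  # residuals are underdispersed and would dilute the variance estimate.
  adm <- expected >= 1e-6
  s2 <- if (sum(adm) > n_free)
    sum((obs[adm] - expected[adm])^2) / (sum(adm) - n_free)
  else rss / dof
  covm <- tryCatch(solve(crossprod(jac)) * s2, error = function(e) NULL)
  se <- c(K = NA_real_, theta = NA_real_, a = NA_real_, t_m = NA_real_,
          d0 = NA_real_)
  tc_se <- NA_real_
  if (is.null(covm)) {
    warning("singular covariance at convergence; standard errors unavailable")
  } else {
    dimnames(covm) <- list(free_nm, free_nm)
    dg <- diag(covm)
    if (any(dg < 0)) {
      warning("non positive-definite covariance; standard errors unavailable")
      covm <- NULL
    } else {
      for (nm in setdiff(free_nm, "t_c")) se[[nm]] <- sqrt(dg[[nm]])
      tc_se <- if (config$free_critical_age) sqrt(dg[["t_c"]])
               else critical_age_se_delta(params, covm, free_nm)
    }
  }

  chi2c <- chi_square_conventional(obs, expected)
  structure(list(
    params = params,
    std_errors = se,
    covariance = covm,
    critical_age = tc,
    critical_age_se = tc_se,
    chi2_origin = chi_square_origin(obs, expected, n_free),
    chi2_conventional = chi2c,
    dof = dof,
    p_value = p_value(as.numeric(chi2c), dof),
    n_points = n_pts,
    iterations = fit$niter,
    converged = fit$info %in% 1:4,
    message = fit$message,
    rss_trace = fit$rsstrace,
    fixed = config$fixed,
    free_critical_age = config$free_critical_age,
    label = series_label(series)), class = "tbm_fit")
}

# first-order propagation of parameter uncertainty through the closed-form
# critical age t_c = t_m - (theta - d0)^(1/n) a^(-(n+1)/n)
critical_age_se_delta <- function(p, covm, free_nm) {
  n <- p$n
  root <- (p$theta - p$d0)^(1 / n)
  apow <- p$a^(-(n + 1) / n)
  g <- c(K = 0,
         theta = -(1 / n) * (p$theta - p$d0)^(1 / n - 1) * apow,
         a = ((n + 1) / n) * root * apow / p$a,
         t_m = 1,
         d0 = (1 / n) * (p$theta - p$d0)^(1 / n - 1) * apow)
  g <- g[free_nm[free_nm %in% names(g)]]
  v <- drop(t(g) %*% covm[names(g), names(g), drop = FALSE] %*% g)
  if (v < 0) NA_real_ else sqrt(v)
}

#' @export
print.tbm_fit <- function(x, ...) {
  cat("TBM fit", if (nzchar(x$label %||% "")) paste0("(", x$label, ")"),
      "\n")
  nm <- c("K", "theta", "a", "t_m", "d0")
  vals <- unlist(x$params[nm])
  tab <- data.frame(estimate = vals, std.error = x$std_errors[nm],
                    fixed = nm %in% x$fixed, row.names = nm)
  print(tab)
  cat(sprintf("  exponent n = %d (fixed); critical age %.3g (%.2g) yr [%s]\n",
              x$params$n, x$critical_age, x$critical_age_se,
              if (x$free_critical_age) "free" else "derived"))
  cat(sprintf("  chi2 (origin-style) %.4g | chi2 (conventional) %.4g | df %d | p %.3g\n",
              x$chi2_origin, as.numeric(x$chi2_conventional), x$dof,
              x$p_value))
  cat(sprintf("  %d points, %d iterations, %sconverged\n", x$n_points,
              x$iterations, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Select the maturational exponent by grid search
#'
#' Fits the series once per candidate odd exponent and returns the fit with
#' the smallest Origin-style (reduced residual) chi-square; ties break
#' toward the smaller exponent (parsimony). The published selection
#' criterion is multi-objective (standard errors, chi-square, band widths);
#' the chi-square it refers to is the one the fitting software reports,
#' i.e. the reduced residual form of [chi_square_origin()], which is what
#' is minimized here. (The Pearson form is unsuitable as a selector for
#' steep-onset curves: its value is dominated by whichever grid point
#' happens to sit just above the fitted cut age, where the expected rate is
#' arbitrarily small.)
#'
#' @inheritParams fit_tbm
#' @return the winning `"tbm_fit"`, with the per-candidate chi-squares in
#'   the `"candidates"` attribute. Errors only if every candidate fails,
#'   aggregating the per-candidate diagnostics.
#' @export
select_exponent <- function(series, config = fit_config()) {
  cands <- sort(config$exponent_candidates)
  fits <- vector("list", length(cands))
  errs <- character(length(cands))
  for (i in seq_along(cands)) {
    cfg <- config
    cfg$exponent_candidates <- cands[i]
    if (!is.null(cfg$initial)) cfg$initial$n <- cands[i]
    else cfg$initial <- initialize_parameters(series, exponent = cands[i])
    fits[[i]] <- tryCatch(fit_tbm(series, cfg),
                          error = function(e) {
                            errs[i] <<- conditionMessage(e)
                            NULL
                          })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("all exponent candidates failed:\n",
         paste(sprintf("  n = %d: %s", cands, errs), collapse = "\n"))
  chi2 <- vapply(fits, function(f)
    if (is.null(f)) Inf else f$chi2_origin, numeric(1))
  best <- which.min(chi2)  # first minimum = smallest exponent on ties
  structure(fits[[best]],
            candidates = data.frame(exponent = cands, chi2_origin =
                                      ifelse(is.finite(chi2), chi2, NA)))
}
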