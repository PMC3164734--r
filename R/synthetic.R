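#' Noise specification for synthetic rate tables
#'
#' @param kind one of `"none"`, `"gaussian"`, `"poisson"`.
#' @param sigma rate-scale standard deviation (required for Gaussian noise).
#' @param population per-age person counts, scalar or one per age (required
#'   for Poisson noise: expected count = rate * population / 100000).
#' @param seed integer random seed; mandatory for stochastic kinds so that
#'   every generated table is reproducible. Randomness uses R's default
#'   Mersenne-Twister generator via an isolated [withr::with_seed()] scope.
#' @return an object of class `"tbm_noise"`.
#' @export
noise_spec <- function(kind = c("none", "gaussian", "poisson"), sigma = NULL,
                       population = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    if (is.null(sigma) || sigma <= 0) stop("gaussian noise requires sigma > 0")
  }
  if (kind == "poisson") {
    if (is.null(population) || any(population <= 0))
      stop("poisson noise requires population > 0")
  }
  if (kind != "none" && (is.null(seed) || !is.finite(seed)))
    stop("stochastic noise requires an explicit integer seed")
  structure(list(kind = kind, sigma = sigma, population = population,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "tbm_noise")
}

#' Generate a synthetic age-rate series from known TBM parameters
#'
#' The noise-free path returns [evaluate_rate()] exactly. Gaussian noise
#' adds seeded i.i.d. perturbations truncated at zero (rates cannot be
#' negative; the slight upward bias this causes on near-zero rates is
#' documented in the methods vignette). Poisson noise draws death counts at
#' the implied expectation `rate * population / 100000` and converts back
#' to rates. Output is deterministic given the seed.
#'
#' @param params a [tbm_params()] object (the generating truth).
#' @param ages numeric age grid (default single years 10-84, mirroring the
#'   support of national single-year-of-age suicide tables), or a
#'   two-column matrix / data frame of interval bounds (rates are then
#'   evaluated at interval midpoints and the series is interval-typed).
#' @param noise a [noise_spec()].
#' @param label provenance tag for the series.
#' @return an [age_rate_series()].
#' @export
generate_series <- function(params, ages = 10:84,
                            noise = noise_spec("none"), label = "synthetic") {
  validate_tbm_params(params)
  if (!inherits(noise, "tbm_noise")) stop("noise must be a noise_spec()")
  interval <- is.matrix(ages) || is.data.frame(ages)
  if (interval) {
    ages <- as.matrix(ages)
    if (ncol(ages) != 2) stop("interval ages need exactly two columns")
    mid <- rowMeans(ages)
  } else {
    mid <- as.numeric(ages)
  }
  mu <- evaluate_rate(mid, params)
  rates <- switch(noise$kind,
    none = mu,
    gaussian = withr::with_seed(noise$seed,
      pmax(mu + stats::rnorm(length(mu), 0, noise$sigma), 0)),
    poisson = {
      pop <- rep_len(noise$population, length(mu))
      lam <- mu * pop / 1e5
      counts <- withr::with_seed(noise$seed, {
        # rpois cannot represent counts beyond integer range; fall back to
        # the asymptotically exact normal approximation for huge means
        big <- lam >= 2^30
        k <- numeric(length(lam))
        k[!big] <- stats::rpois(sum(!big), lam[!big])
        k[big] <- pmax(round(stats::rnorm(sum(big), lam[big],
                                          sqrt(lam[big]))), 0)
        k
      })
      counts / pop * 1e5
    })
  pop <- if (noise$kind == "poisson") rep_len(noise$population, length(mu))
         else NULL
  if (interval)
    age_rate_series(age_low = ages[, 1], age_high = ages[, 2], rates = rates,
                    population = pop, label = label)
  else
    age_rate_series(ages = mid, rates = rates, population = pop,
                    label = label)
}

#' Aggregate a single-age series into wide age groups
#'
#' Emulates the reporting coarseness of published tables that use wide age
#' groups: each group's rate is the population-weighted mean of its member
#' rates. Groups are half-open `[low, low + width)` starting at the first
#' age of the series.
#'
#' @param series an [age_rate_series()] with point ages.
#' @param group_width width of the groups in years, `>= 1` and at least the
#'   grid spacing.
#' @param population per-age weights; defaults to the series' own
#'   `population` column, or uniform weights if absent.
#' @return an interval-typed [age_rate_series()].
#' @export
aggregate_groups <- function(series, group_width, population = NULL) {
  if (!is_age_rate_series(series)) stop("series must be an age_rate_series")
  if (!all(is.na(series$age_low)))
    stop("series is already interval-typed")
  spacing <- min(diff(series$age))
  if (group_width < 1 || group_width < spacing)
    stop("group_width must be >= 1 year and >= the grid spacing (",
         spacing, ")")
  w <- population %||% series$population %||% rep(1, nrow(series))
  if (length(w) != nrow(series)) stop("population must match the series")
  idx <- floor((series$age - series$age[1]) / group_width)
  lows <- series$age[1] + unique(idx) * group_width
  grates <- as.numeric(tapply(series$rate * w, idx, sum) /
                         tapply(w, idx, sum))
  gpop <- as.numeric(tapply(w, idx, sum))
  age_rate_series(age_low = lows, age_high = lows + group_width,
                  rates = grates,
                  population = if (is.null(population) &&
                                   is.null(series$population)) NULL else gpop,
                  label = series_label(series))
}

table1_env <- new.env(parent = emptyenv())

table1_registry <- function() {
  if (is.null(table1_env$reg)) {
    path <- system.file("extdata", "table1_parameters.json",
                        package = "tbmodel")
    if (path == "") path <- file.path("inst", "extdata",
                                      "table1_parameters.json")
    table1_env$reg <- jsonlite::read_json(path, simplifyVector = TRUE,
                                          simplifyDataFrame = FALSE)
  }
  table1_env$reg
}

#' Published reference parameter sets
#'
#' Returns one of the published country-year-gender TBM parameter sets
#' shipped with the package (values and standard errors exactly as printed;
#' parameters that were held fixed during the original fits carry `NA`
#' standard errors). The registry also stores each row's printed
#' goodness-of-fit summary and, for the forecast row, the fact that its
#' values were obtained by linear extrapolation rather than fitting.
#'
#' The printed critical age in these tables behaves as a freely fitted
#' parameter (it carries a standard error); it is stored verbatim in
#' `$critical_age` and generally differs from the value [critical_age()]
#' derives from the other parameters. See the methods vignette.
#'
#' @param name registry key, e.g. `"usa-2001-both"`. Unknown keys raise an
#'   error that lists the available keys.
#' @return a list of class `"tbm_fixture"` with elements `params`
#'   ([tbm_params()]), `std_errors` (named, `NA` for fixed parameters),
#'   `fixed` (names of fixed parameters), `critical_age`,
#'   `critical_age_se`, `gof` (printed chi-square summary), `method`
#'   (`"fitted"` or `"extrapolated"`) and `label`.
#' @export
table1_fixture <- function(name) {
  reg <- table1_registry()
  if (!name %in% names(reg))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  r <- reg[[name]]
  params <- tbm_params(r$K[1], r$theta[1], r$a[1], r$t_m[1], r$d0[1],
                       r$exponent)
  se <- c(K = r$K[2], theta = r$theta[2], a = r$a[2], t_m = r$t_m[2],
          d0 = r$d0[2])
  structure(list(
    params = params,
    std_errors = se,
    fixed = names(se)[is.na(se)],
    critical_age = r$t_c[1],
    critical_age_se = r$t_c[2],
    gof = list(chi2_origin = r$chi2_origin, chi2_conventional = r$chi2_conv,
               dof = r$dof, p_value = r$p),
    method = r$method,
    label = r$label), class = "tbm_fixture")
}

#' @rdname table1_fixture
#' @export
table1_keys <- function() names(table1_registry())
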