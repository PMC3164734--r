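#' Average drive function
#'
#' The decreasing function of age representing the fused 'life drives' and
#' 'death drives': positive during youth, approximately the quiescent value
#' `d0` near the middle age (where it has its inflection point for
#' `n >= 3`), and negative in old age,
#' \deqn{D(t) = a^{n+1} (t_m - t)^n + d_0.}
#' With `n = 1` it reduces to a straight line with slope `-a^2`. `D` is odd
#' about the point `(t_m, d0)`.
#'
#' @param age age(s) in years; vectorized.
#' @param params a [tbm_params()] object.
#' @return drive value(s), units 1/years.
#' @export
average_drive <- function(age, params) {
  validate_tbm_params(params)
  params$a^(params$n + 1) * (params$t_m - age)^params$n + params$d0
}

#' Consciousness function
#'
#' Closed-form solution of the consciousness growth law `dC/dt = C * D(t)`,
#' with the integration constant fixed so that `C(t_m) = K` (the apex
#' constant):
#' \deqn{C(t) = K \exp\left[d_0 (t - t_m) -
#'   \frac{(a (t_m - t))^{n+1}}{n+1}\right].}
#' `C` is strictly positive, reaches its maximum near the middle age, and
#' decays super-exponentially toward zero at very advanced ages (the
#' polynomial term dominates the linear `d0` term since `n + 1 >= 2`).
#'
#' @inheritParams average_drive
#' @return consciousness level(s), dimensionless scale set by `K`.
#' @export
consciousness <- function(age, params) {
  validate_tbm_params(params)
  params$K * exp(params$d0 * (age - params$t_m) -
                   (params$a * (params$t_m - age))^(params$n + 1) /
                   (params$n + 1))
}

#' Threshold bias function
#'
#' The self-destructive impulsivity factor: the excess of the threshold
#' level over the average drive,
#' \deqn{B(t) = \theta - D(t).}
#' `B` is strictly increasing in age, vanishes exactly at the (derived)
#' critical age, and is therefore non-negative on `[t_c, Inf)`.
#'
#' @inheritParams average_drive
#' @return bias value(s); same units as `theta`.
#' @export
threshold_bias <- function(age, params) {
  params$theta - average_drive(age, params)
}

#' Evaluate the TBM rate curve
#'
#' The piecewise model distribution: zero at and below the critical age,
#' and the product of the threshold-bias and consciousness factors above it,
#' \deqn{S(t) = [\theta - D(t)] \, C(t), \quad t > t_c; \qquad S(t) = 0,
#'   \quad t \le t_c.}
#' At the middle age the rate is the product of `(theta - d0)` and the apex
#' constant `K`. When `theta = 0`, `d0 = 0` and `t_m = 0` the curve is
#' exactly `K` times a Weibull density with shape `n + 1` and scale
#' `(n+1)^(1/(n+1)) / a`.
#'
#' @inheritParams average_drive
#' @param age age(s) in years, `>= 0`; vectorized.
#' @param critical override for the cut age. `NULL` (default) derives it
#'   from the parameters via [critical_age()]; a number treats the critical
#'   age as an independently stored (e.g. freely fitted) parameter. With an
#'   override the bias factor is floored at zero so rates are never
#'   negative.
#' @return rate(s), deaths per 100,000 person-years when `K` is calibrated
#'   to rates on that scale.
#' @export
evaluate_rate <- function(age, params, critical = NULL) {
  validate_tbm_params(params)
  if (any(age < 0)) stop("age must be >= 0")
  tc <- if (is.null(critical)) critical_age(params) else as.numeric(critical)
  rate_kernel(age, params, tc)
}

# Unvalidated piecewise kernel shared with the optimizer. `tc` may sit
# anywhere (including above t_m during free-critical-age fits); the bias
# factor is floored at 0 so the returned rate is never negative.
rate_kernel <- function(age, params, tc) {
  b <- pmax(params$theta - (params$a^(params$n + 1) *
                              (params$t_m - age)^params$n + params$d0), 0)
  cf <- exp(params$d0 * (age - params$t_m) -
              (params$a * (params$t_m - age))^(params$n + 1) /
              (params$n + 1))
  ifelse(age <= tc, 0, params$K * b * cf)
}
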