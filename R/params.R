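#' Threshold Bias Model parameter set
#'
#' Bundles the six model parameters together with the fixed odd maturational
#' exponent. The rate distribution is the product of a threshold-bias
#' (impulsivity) factor and a consciousness factor above the critical age,
#' and is identically zero below it; see [evaluate_rate()].
#'
#' @param apex_constant `K`, positive rate-scale constant: the consciousness
#'   apex arising as the integration constant of the consciousness growth
#'   law, anchored so that the consciousness factor equals `K` at the middle
#'   age.
#' @param threshold `theta`, non-negative threshold parameter: the shift from
#'   the average drive needed to trigger self-destructive behaviour. Must
#'   exceed (or equal, for the degenerate boundary) `quiescent_drive` so that
#'   the critical age has a real solution at or below the middle age.
#' @param maturation_rate `a`, positive maturational constant, units 1/years.
#' @param middle_age `t_m`, the inflection point of the average drive
#'   function, in years. Non-negative.
#' @param quiescent_drive `d0`, the value of the average drive function at
#'   the middle age, units 1/years. May be zero or slightly negative.
#' @param exponent `n`, odd positive integer maturational exponent. Not
#'   fitted; the reference analyses use 9, and values between 7 and 15 are
#'   recommended for human populations.
#'
#' @return An object of class `"tbm_params"`: a named list with elements
#'   `K`, `theta`, `a`, `t_m`, `d0`, `n`.
#' @seealso [critical_age()], [evaluate_rate()], [table1_fixture()]
#' @examples
#' p <- tbm_params(apex_constant = 94.3, threshold = 15.2,
#'                 maturation_rate = 0.147, middle_age = 47.49,
#'                 quiescent_drive = 0.00195)
#' critical_age(p)
#' @export
tbm_params <- function(apex_constant, threshold, maturation_rate, middle_age,
                       quiescent_drive = 0, exponent = 9L) {
  p <- structure(
    list(K = as.numeric(apex_constant),
         theta = as.numeric(threshold),
         a = as.numeric(maturation_rate),
         t_m = as.numeric(middle_age),
         d0 = as.numeric(quiescent_drive),
         n = as.integer(exponent)),
    class = "tbm_params")
  validate_tbm_params(p)
  p
}

#' @rdname tbm_params
#' @param x object to test or print.
#' @export
is_tbm_params <- function(x) inherits(x, "tbm_params")

#' Validate a TBM parameter set
#'
#' Checks the invariants: odd exponent >= 1, positive `K` and `a`,
#' non-negative `t_m`, and `theta >= d0` (so the threshold crossing that
#' defines the critical age has a real solution at or below the middle age).
#'
#' @param p a [tbm_params()] object (or bare named list with the same
#'   fields).
#' @return `p`, invisibly; errors with an informative message otherwise.
#' @export
validate_tbm_params <- function(p) {
  need <- c("K", "theta", "a", "t_m", "d0", "n")
  if (!all(need %in% names(p)))
    stop("parameter set must contain fields: ", paste(need, collapse = ", "))
  num <- unlist(p[need])
  if (any(!is.finite(num)))
    stop("all TBM parameters must be finite")
  n <- p$n
  if (n < 1 || n %% 2 != 1)
    stop("exponent must be an odd positive integer (got ", n, ")")
  if (p$K <= 0) stop("apex_constant must be > 0")
  if (p$a <= 0) stop("maturation_rate must be > 0")
  if (p$t_m < 0) stop("middle_age must be >= 0")
  if (p$theta < 0) stop("threshold must be >= 0")
  if (p$theta < p$d0)
    stop("threshold must be >= quiescent_drive, otherwise the critical-age ",
         "equation has no real solution below the middle age")
  invisible(p)
}

#' @export
print.tbm_params <- function(x, ...) {
  cat("Threshold Bias Model parameters\n")
  cat(sprintf("  apex constant K      : %g\n", x$K))
  cat(sprintf("  threshold theta      : %g\n", x$theta))
  cat(sprintf("  maturation rate a    : %g /yr\n", x$a))
  cat(sprintf("  middle age t_m       : %g yr\n", x$t_m))
  cat(sprintf("  quiescent drive d0   : %g /yr\n", x$d0))
  cat(sprintf("  exponent n (fixed)   : %d\n", x$n))
  cat(sprintf("  derived critical age : %.4g yr\n", critical_age(x)))
  invisible(x)
}

#' @export
as.data.frame.tbm_params <- function(x, ...) {
  data.frame(K = x$K, theta = x$theta, a = x$a, t_m = x$t_m, d0 = x$d0,
             n = x$n)
}

#' Critical age of a TBM parameter set
#'
#' The age at which the threshold-bias factor crosses zero, i.e. the root of
#' `theta - D(t) = 0` where `D` is the average drive function. Below this
#' age the model rate is identically zero. Closed form:
#' `t_c = t_m - (theta - d0)^(1/n) / a^((n+1)/n)`.
#'
#' In published parameter tables the critical age is typically reported as a
#' freely fitted parameter with its own standard error; the value derived
#' here from the remaining parameters then serves as a consistency
#' diagnostic rather than an identity (see the methods vignette).
#'
#' @param params a [tbm_params()] object.
#' @return the critical age in years (equals `t_m` when `theta == d0`).
#' @export
critical_age <- function(params) {
  validate_tbm_params(params)
  params$t_m - (params$theta - params$d0)^(1 / params$n) /
    params$a^((params$n + 1) / params$n)
}
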