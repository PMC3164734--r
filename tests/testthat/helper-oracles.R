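# Independent oracles and shared generators for the test suite.

usa_2001_both <- function() table1_fixture("usa-2001-both")$params
usa_2001_males <- function() table1_fixture("usa-2001-males")$params

# Bisection oracle for the critical age: expanding bracket below the middle
# age, then plain bisection on the threshold-bias sign change. Independent
# of the closed form.
bisect_critical_age <- function(params, tol = 1e-12) {
  lo <- params$t_m - 1
  while (threshold_bias(lo, params) >= 0 && is.finite(lo))
    lo <- params$t_m - 2 * (params$t_m - lo)
  hi <- params$t_m
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (threshold_bias(mid, params) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# High-order numerical integration of the consciousness growth law
# dC/dt = C * D(t), anchored at C(t_m) = K; integrates forward and
# backward from the anchor so the times vector is monotone in each call.
ode_consciousness <- function(params, ages) {
  rhs <- function(t, y, parms) list(y * average_drive(t, parms))
  run <- function(times) {
    if (length(times) < 2) return(NULL)
    deSolve::lsoda(c(C = params$K), times = times, func = rhs,
                   parms = params, rtol = 1e-11, atol = 1e-300)
  }
  up <- sort(unique(c(params$t_m, ages[ages >= params$t_m])))
  dn <- sort(unique(c(params$t_m, ages[ages < params$t_m])),
             decreasing = TRUE)
  sol <- rbind(run(dn), run(up))
  sol[match(ages, sol[, "time"]), "C"]
}

# Random valid parameter sets in the regime of national suicide tables;
# ranges keep the derived critical age strictly positive.
random_valid_params <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      tbm_params(apex_constant = stats::runif(1, 10, 500),
                 threshold = stats::runif(1, 5, 30),
                 maturation_rate = stats::runif(1, 0.1, 0.35),
                 middle_age = stats::runif(1, 40, 50),
                 quiescent_drive = stats::runif(1, -0.001, 0.005),
                 exponent = sample(c(7L, 9L, 11L), 1))
    })
  })
}

# One seeded replicate ensemble of Gaussian-noise fits from a known truth;
# returns per-parameter matrices of estimates and standard errors.
fit_ensemble <- function(truth, n_rep, sigma = 0.5, ages = 10:84,
                         seed_base = 1000L) {
  nm <- c("K", "theta", "a", "t_m", "d0")
  est <- se <- matrix(NA_real_, n_rep, length(nm),
                      dimnames = list(NULL, nm))
  ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    s <- generate_series(truth, ages,
                         noise_spec("gaussian", sigma = sigma,
                                    seed = seed_base + r))
    f <- fit_tbm(s, fit_config(
      initial = initialize_parameters(s, life_expectancy = 95)))
    est[r, ] <- unlist(f$params[nm])
    se[r, ] <- f$std_errors[nm]
    ok[r] <- f$converged && all(is.finite(se[r, ]))
  }
  list(est = est, se = se, ok = ok)
}
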