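usa_traj <- function() {
  parameter_trajectory(c(2001, 2002),
                       list(table1_fixture("usa-2001-both"),
                            table1_fixture("usa-2002-both")))
}

test_that("two-year linear extrapolation reproduces the published forecast row", {
  fc <- extrapolate_parameters(usa_traj(), 2003)
  pub <- table1_fixture("usa-2003-both")
  expect_equal(fc$params$theta, pub$params$theta)            # 18.4 exactly
  expect_equal(round(fc$params$a, 3), pub$params$a)          # 0.163
  expect_equal(round(fc$params$t_m, 1), pub$params$t_m)      # 47.9
  expect_equal(round(fc$params$d0, 3), pub$params$d0)        # 0.003
  expect_equal(round(fc$critical_age, 1), pub$critical_age)  # 12.6
  # standard errors carried forward by the same linear rule
  expect_equal(fc$std_errors[["theta"]], pub$std_errors[["theta"]])  # 2.4
  expect_equal(round(fc$std_errors[["a"]], 3), pub$std_errors[["a"]])
  expect_equal(round(fc$std_errors[["d0"]], 3), pub$std_errors[["d0"]])
})

test_that("extrapolation is exact interpolation at the observed years", {
  traj <- usa_traj()
  at2001 <- extrapolate_parameters(traj, 2001)
  at2002 <- extrapolate_parameters(traj, 2002)
  expect_equal(at2001$params$theta, 15.2)
  expect_equal(at2002$params$theta, 16.8)
  expect_equal(at2001$params$K, 94.3)
})

test_that("constant parameter values extrapolate to themselves", {
  traj <- parameter_trajectory(c(2001, 2002),
                               list(table1_fixture("usa-2001-both"),
                                    table1_fixture("usa-2001-both")))
  fc <- extrapolate_parameters(traj, 2050)
  expect_equal(fc$params$theta, 15.2)
  expect_equal(fc$critical_age, 12.2)
})

test_that("trajectory preconditions are enforced", {
  f1 <- table1_fixture("usa-2001-both")
  expect_error(parameter_trajectory(c(2002, 2001), list(f1, f1)), "increasing")
  expect_error(parameter_trajectory(
    c(2001, 2002), list(f1, table1_fixture("usa-2002-females"))), "layout")
  expect_error(extrapolate_parameters(
    parameter_trajectory(2001, list(f1)), 2003), "two")
})

test_that("three-point trajectories use ordinary least squares", {
  # straight-line inputs are reproduced exactly; bent inputs are smoothed
  mk <- function(theta) {
    fx <- table1_fixture("usa-2001-both")
    fx$params$theta <- theta
    fx
  }
  traj <- parameter_trajectory(2001:2003, list(mk(10), mk(12), mk(14)))
  expect_equal(extrapolate_parameters(traj, 2004)$params$theta, 16)
  bent <- parameter_trajectory(2001:2003, list(mk(10), mk(13), mk(13)))
  expect_equal(extrapolate_parameters(bent, 2004)$params$theta, 15)
})

test_that("bands collapse for zero errors and scale linearly in sigma", {
  fc <- extrapolate_parameters(usa_traj(), 2003)
  ages <- seq(10, 85, by = 2.5)
  zero <- fc
  zero$std_errors[] <- 0
  zero$critical_age_se <- 0
  b0 <- predict_curve(zero, ages, level = 0.682)
  expect_equal(b0$lower, b0$central)
  expect_equal(b0$upper, b0$central)
  b1 <- predict_curve(fc, ages, level = 0.682, band = "confidence")
  dbl <- fc
  dbl$std_errors <- fc$std_errors * 2
  b2 <- predict_curve(dbl, ages, level = 0.682, band = "confidence")
  h1 <- b2$upper - b2$central
  expect_equal(h1, 2 * (b1$upper - b1$central), tolerance = 1e-9)
  # the lower envelope is additionally floored at zero
  expect_true(all(b2$lower >= 0))
})

test_that("a 95% band contains the one-standard-deviation band pointwise", {
  fc <- extrapolate_parameters(usa_traj(), 2003)
  ages <- seq(10, 85, by = 1)
  narrow <- predict_curve(fc, ages, level = 0.682)
  wide <- predict_curve(fc, ages, level = 0.95)
  expect_true(all(wide$lower <= narrow$lower + 1e-12))
  expect_true(all(wide$upper >= narrow$upper - 1e-12))
  expect_true(all(narrow$lower <= narrow$central &
                    narrow$central <= narrow$upper))
})

test_that("prediction bands add the residual term to confidence bands", {
  fc <- extrapolate_parameters(usa_traj(), 2003)
  ages <- seq(15, 80, by = 5)
  conf <- predict_curve(fc, ages, level = 0.682, band = "confidence")
  pred <- predict_curve(fc, ages, level = 0.682, band = "prediction",
                        sigma_resid = 2)
  expect_true(all(pred$upper - pred$central >=
                    conf$upper - conf$central))
  # at an age where the curve is zero with zero gradient, the prediction
  # half-width reduces to sigma_resid itself
  expect_equal(pred$upper[1] - pred$central[1],
               stats::qnorm(0.841) * 2, tolerance = 1e-3)
})

test_that("band envelopes achieve near-nominal coverage of parameter draws", {
  fc <- extrapolate_parameters(usa_traj(), 2003)
  ages <- seq(38, 58, by = 1)      # region where the curve responds to the errors
  band <- predict_curve(fc, ages, level = 0.682, band = "confidence")
  nm <- c("K", "theta", "a", "t_m", "d0")
  n_rep <- 400L
  inside <- matrix(FALSE, n_rep, length(ages))
  withr::with_seed(99, {
    for (r in seq_len(n_rep)) {
      p <- fc$params
      for (v in nm) p[[v]] <- p[[v]] + stats::rnorm(1, 0, fc$std_errors[[v]])
      p$a <- max(p$a, 1e-3)
      p$K <- max(p$K, 1e-3)
      p$theta <- max(p$theta, p$d0)
      draw <- evaluate_rate(ages, p)
      inside[r, ] <- draw >= band$lower & draw <= band$upper
    }
  })
  cover <- mean(inside)
  expect_gt(cover, 0.60)           # near the nominal 0.682 ...
  expect_lt(cover, 0.85)           # ... but first-order, not exact
})

test_that("fixed-curve prediction reports have zero free parameters", {
  p <- usa_2001_both()
  s <- generate_series(p, 40:56)      # ages where the curve is on-support
  rep0 <- evaluate_prediction(s, p)
  expect_equal(as.numeric(rep0$chi2_conventional), 0)
  expect_equal(rep0$p_value, 1)
  expect_equal(rep0$dof, 17L)                  # every point admitted
  expect_true(is.na(rep0$chi2_origin))
  one <- age_rate_series(50, evaluate_rate(50, p))
  rep1 <- evaluate_prediction(one, p)
  expect_equal(rep1$dof, 1L)
  noisy <- generate_series(p, 40:60,
                           noise_spec("gaussian", sigma = 2, seed = 31))
  rep2 <- evaluate_prediction(noisy, p)
  expect_gt(as.numeric(rep2$chi2_conventional), 0)
  expect_true(rep2$p_value >= 0 && rep2$p_value <= 1)
})
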