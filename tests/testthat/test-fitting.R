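test_that("initialization follows the stated heuristics", {
  truth <- usa_2001_both()
  s <- generate_series(truth, 10:84)
  init <- initialize_parameters(s, life_expectancy = 95)
  expect_equal(init$t_m, 47.5)
  r_mid <- s$rate[which.min(abs(s$age - 47.5))]
  expect_equal(init$theta * init$K, r_mid)   # product matches mid-age rate
  expect_true(init$n %% 2 == 1)
  init2 <- initialize_parameters(s)          # no life expectancy given
  expect_gt(init2$t_m, min(s$age))
  expect_lt(init2$t_m, max(s$age))
  zero <- age_rate_series(10:20, rep(0, 11))
  expect_error(initialize_parameters(zero), "degenerate")
})

test_that("noise-free fits recover the generating parameters", {
  truth <- usa_2001_both()
  s <- generate_series(truth, 10:84)
  f <- fit_tbm(s, fit_config(initial =
                               initialize_parameters(s, life_expectancy = 95)))
  expect_true(f$converged)
  for (nm in c("K", "theta", "a", "t_m", "d0"))
    expect_equal(f$params[[nm]], truth[[nm]], tolerance = 1e-4)
  expect_lt(f$chi2_origin, 1e-8)
  expect_lt(as.numeric(f$chi2_conventional), 1e-6)
  expect_gt(f$p_value, 0.999999)
  expect_equal(f$dof, 75 - 5)
})

test_that("fixed parameters are honored and the dof bookkeeping moves with them", {
  truth <- usa_2001_both()
  s <- generate_series(truth, 10:84,
                       noise_spec("gaussian", sigma = 0.5, seed = 5))
  init <- initialize_parameters(s, life_expectancy = 95)
  init$t_m <- 47.49
  init$d0 <- 0.00195
  free_fit <- fit_tbm(s, fit_config(initial = init))
  fixed_fit <- fit_tbm(s, fit_config(initial = init,
                                     fixed = c("t_m", "d0")))
  expect_equal(fixed_fit$params$t_m, 47.49)
  expect_equal(fixed_fit$params$d0, 0.00195)
  expect_true(all(is.na(fixed_fit$std_errors[c("t_m", "d0")])))
  expect_false(anyNA(fixed_fit$std_errors[c("K", "theta", "a")]))
  # fixing k parameters raises the dof by exactly k on the same series
  expect_equal(fixed_fit$dof, free_fit$dof + 2)
})

test_that("the optimizer objective is non-increasing across accepted iterations", {
  truth <- usa_2001_both()
  s <- generate_series(truth, 10:84,
                       noise_spec("gaussian", sigma = 0.5, seed = 8))
  f <- fit_tbm(s, fit_config(initial =
                               initialize_parameters(s, life_expectancy = 95)))
  expect_true(all(diff(f$rss_trace) <= 1e-8 * f$rss_trace[1]))
})

test_that("underdetermined series and iteration caps are reported, not hidden", {
  truth <- usa_2001_both()
  tiny <- generate_series(truth, seq(40, 48, by = 2))
  expect_error(fit_tbm(tiny), "more points")
  s <- generate_series(truth, 10:84,
                       noise_spec("gaussian", sigma = 2, seed = 9))
  init <- initialize_parameters(s, life_expectancy = 95)
  capped <- suppressWarnings(
    fit_tbm(s, fit_config(initial = init, max_iterations = 1)))
  expect_false(capped$converged)
  expect_s3_class(capped, "tbm_fit")          # best-so-far state returned
  expect_true(is.finite(capped$chi2_origin))
})

test_that("the Origin-style chi-square is the reduced residual sum", {
  expect_equal(chi_square_origin(c(4, 6), c(4, 6), 0), 0)
  # hand evaluation: ((4-5)^2 + (6-5)^2) / (2 - 0) = 1
  expect_equal(chi_square_origin(c(4, 6), c(5, 5), 0), 1)
  # same residuals, one free parameter: denominator shrinks
  expect_equal(chi_square_origin(c(4, 6), c(5, 5), 1), 2)
  expect_error(chi_square_origin(c(4, 6), c(5, 5, 5), 0), "length")
})

test_that("the conventional chi-square is the Pearson sum with a floor", {
  expect_equal(as.numeric(chi_square_conventional(c(4, 6), c(4, 6))), 0)
  x <- chi_square_conventional(c(4, 6), c(5, 5))
  expect_equal(as.numeric(x), 0.4)            # 0.2 + 0.2 by hand
  expect_equal(attr(x, "n_used"), 2L)
  y <- chi_square_conventional(c(10, 4), c(0, 5))
  expect_equal(as.numeric(y), 0.2)            # zero-expected point excluded
  expect_equal(attr(y, "n_excluded"), 1L)
  expect_error(chi_square_conventional(10, 0), "excluded")
  # invariance to the free-parameter count, unlike the Origin form
  expect_equal(as.numeric(chi_square_conventional(c(4, 6), c(5, 5))),
               as.numeric(chi_square_conventional(c(4, 6), c(5, 5))))
})

test_that("p-values reproduce the published upper-tail convention", {
  expect_equal(round(p_value(25.08, 10), 3), 0.005)
  expect_equal(round(p_value(14.54, 8), 3), 0.069)
  expect_gte(p_value(1.076, 11), 0.999)
  expect_equal(p_value(0, 7), 1)
  expect_error(p_value(-1, 5), "chi2")
  expect_error(p_value(3, 0), "dof")
})

test_that("a singleton exponent grid reduces selection to a plain fit", {
  truth <- usa_2001_both()
  s <- generate_series(truth, 10:84,
                       noise_spec("gaussian", sigma = 0.5, seed = 12))
  init <- initialize_parameters(s, life_expectancy = 95)
  sel <- select_exponent(s, fit_config(initial = init,
                                       exponent_candidates = 9L))
  plain <- fit_tbm(s, fit_config(initial = init))
  expect_equal(sel$params, plain$params)
  expect_equal(as.numeric(sel$chi2_conventional),
               as.numeric(plain$chi2_conventional))
})

test_that("exponent selection recovers the generating exponent on clean data", {
  truth <- usa_2001_both()
  s <- generate_series(truth, 10:84)
  # misspecified candidates may fit degenerately on noise-free data and
  # warn about their covariance; only the selected fit matters here
  sel <- suppressWarnings(select_exponent(s, fit_config(
    initial = initialize_parameters(s, life_expectancy = 95),
    exponent_candidates = c(7L, 9L, 11L))))
  expect_equal(sel$params$n, 9L)
  expect_equal(nrow(attr(sel, "candidates")), 3L)
})

test_that("free-critical-age fits expose the alternative bookkeeping", {
  truth <- usa_2001_both()
  s <- generate_series(truth, 10:84,
                       noise_spec("gaussian", sigma = 0.5, seed = 14))
  init <- initialize_parameters(s, life_expectancy = 95)
  # the cut parameter has zero gradient once the bias factor vanishes at
  # the derived crossing, so its covariance is singular by construction
  expect_warning(
    f <- fit_tbm(s, fit_config(initial = init, free_critical_age = TRUE)),
    "singular covariance")
  expect_true(f$free_critical_age)
  expect_equal(f$dof, 75 - 6)              # t_c counts as a free parameter
  expect_s3_class(f, "tbm_fit")
})
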