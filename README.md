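# tbmodel

Fitting, testing and forecasting age-specific suicide rates with the
Threshold Bias Model (TBM), a six-parameter piecewise distribution for the
rate as a function of age. The package is aimed at suicidologists,
epidemiologists and demographers who need comparable parametric summaries
of national age-rate tables and short-range projections with uncertainty
bands.

## The model

The rate at age `t` (deaths per 100,000 person-years) is the product of a
threshold-bias (impulsivity) factor and a consciousness (planning) factor
above a critical age `t_c`, and is identically zero below it:

    D(t) = a^(n+1) (t_m - t)^n + d0              average drive
    C(t) = K exp[ d0 (t - t_m) - (a (t_m - t))^(n+1) / (n+1) ]
    S(t) = [theta - D(t)] * C(t)   for t > t_c,   0 otherwise
    t_c  = t_m - (theta - d0)^(1/n) / a^((n+1)/n)

with `K` the apex constant (rate scale), `theta` the threshold
(impulsivity indicator), `a` a maturational constant (1/yr), `t_m` the
middle age (inflection of the drive), `d0` the quiescent drive at `t_m`
(1/yr), and `n` a fixed odd maturational exponent (9 by default, 7-15
recommended). When `theta` and `d0` vanish the curve reduces exactly to a
Weibull density of shape `n + 1`.

The package provides closed-form evaluation (`evaluate_rate()`,
`critical_age()`), Levenberg-Marquardt least-squares fitting with fixed-
parameter support and odd-exponent selection (`fit_tbm()`,
`select_exponent()`), the two goodness-of-fit chi-squares of the original
workflow with upper-tail p-values, year-over-year linear parameter
extrapolation with delta-method confidence and prediction bands
(`extrapolate_parameters()`, `predict_curve()`), a seeded synthetic
rate-table generator (`generate_series()`, `aggregate_groups()`),
published reference parameter sets (`table1_fixture()`), CSV/TSV and JSON
I/O, and a command-line interface (`tbm_cli()`, `inst/scripts/tbm`).

## Worked example

Simulate a noisy series from the published USA-2001 both-gender parameter
set, refit it, and extrapolate the published 2001/2002 rows to 2003:

```r
library(tbmodel)

fx <- table1_fixture("usa-2001-both")
series <- generate_series(fx$params, ages = 10:84,
                          noise = noise_spec("gaussian", sigma = 0.5, seed = 1),
                          label = "USA 2001 synthetic")
fit <- fit_tbm(series, fit_config(
  initial = initialize_parameters(series, life_expectancy = 95)))
fit
#> TBM fit (USA 2001 synthetic)
#>           estimate    std.error fixed
#> K     94.080309880 9.223486e+00 FALSE
#> theta 15.235475767 1.493961e+00 FALSE
#> a      0.146994009 6.113595e-06 FALSE
#> t_m   47.489878500 6.423309e-03 FALSE
#> d0     0.001952617 1.753804e-05 FALSE
#>   exponent n = 9 (fixed); critical age 36.1 (0.12) yr [derived]
#>   chi2 (origin-style) 0.1468 | chi2 (conventional) 1.408e+04 | df 70 | p 0
#>   75 points, 6 iterations, converged
```

Every estimate sits within one reported standard error of the generating
values (K 94.3, theta 15.2, a 0.147, t_m 47.49, d0 0.00195). The derived
critical age 36.1 is the closed-form crossing for these parameter values;
published tables instead report a freely fitted cut age (12.2 for this
row), a distinction the package keeps explicit — see the methods vignette.
The conventional chi-square is inflated here by onset-region points whose
expected rate is near zero under truncated Gaussian noise; the
origin-style value 0.147 is the reduced residual sum.

```r
traj <- parameter_trajectory(c(2001, 2002),
                             list(table1_fixture("usa-2001-both"),
                                  table1_fixture("usa-2002-both")))
fc <- extrapolate_parameters(traj, 2003)
fc
#> TBM parameter forecast for year 2003
#>          value std.error
#> K     88.50000   9.90000
#> theta 18.40000   2.40000
#> a      0.16300   0.01900
#> t_m   47.89000   0.62000
#> d0     0.00299   0.00098
#>   critical age 12.6 (0.7) yr; exponent n = 9
round(p_value(14.54, 8), 3)
#> [1] 0.069
```

The extrapolated row matches the published 2003 values at printed
precision for theta (18.4), a (0.163), t_m (47.9), d0 (0.003) and t_c
(12.6). `predict_curve(fc, 10:85, level = 0.682)` turns the forecast into
a rate curve with one-standard-deviation bands.

The same pipeline is available from a shell:

    tbm simulate --fixture usa-2001-both --noise gaussian --sigma 0.5 \
        --seed 1 --output usa2001.csv
    tbm fit --input usa2001.csv --output fit.json --life-expectancy 95
    tbm pvalue 25.08 10
    # 0.005

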