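---
title: "The Threshold Bias Model: methods and design notes"
author: "tbmodel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Threshold Bias Model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbmodel)
```

## The model

Age-specific suicide rates are difficult to compare across countries and to
project forward, because they are usually published as bare tabulations
with no parametric summary. The Threshold Bias Model (TBM) addresses this
with a six-parameter piecewise distribution for the rate $S(t)$ at age $t$
(deaths per 100,000 person-years): suicides are treated as the product of a
*self-destructive impulsivity* factor and a *consciousness* (planning)
factor, and they do not occur at all below a critical age $t_c$.

The construction starts from an **average drive function** $D(t)$, a
decreasing function of age that is positive during youth, close to a small
quiescent value $d_0$ around the middle age $t_m$ (its inflection point),
and negative in old age:

$$D(t) = a^{\,n+1}\,(t_m - t)^n + d_0 ,$$

with $a > 0$ a maturational constant (units $\mathrm{yr}^{-1}$) and $n$ an
odd positive integer, fixed rather than fitted. With $n = 1$ the drive is a
straight line of slope $-a^2$; neurological and psychological maturation is
not linear in age, so values well above 1 (between 7 and 15, typically 9)
describe human populations better. Note that $D$ has units
$\mathrm{yr}^{-1}$ for every $n$, matching the printed units of $a$ and
$d_0$ in published parameter tables.

The **consciousness level** $C(t)$ obeys the growth law
$\mathrm{d}C/\mathrm{d}t = C(t)\,D(t)$: the more aware the individual, the
faster awareness changes under the drives. Solving and anchoring the
integration constant at the middle age gives

$$C(t) = K \exp\!\left[d_0\,(t - t_m) -
  \frac{\bigl(a\,(t_m - t)\bigr)^{n+1}}{n+1}\right],
  \qquad C(t_m) = K ,$$

where $K$, the *apex constant*, represents the cohort's average apex of
mental skills. $C$ is positive, peaks where $D$ crosses zero (at $t_m$
exactly when $d_0 = 0$, a few years later when $d_0 > 0$), and decays
super-exponentially toward zero at very advanced ages. The anchor
convention $C(t_m) = K$ is a design choice: the growth law determines $C$
only up to a constant, and anchoring at $t_m$ makes the mid-age rate the
product of the threshold-bias factor and the apex constant exactly.

Suicidal behaviour is triggered when the fused drives depart from their
average by a **threshold** $\theta \ge 0$. The *threshold-bias* factor is
the excess of the threshold over the average drive,

$$B(t) = \theta - D(t),$$

which increases with age and crosses zero at the **critical age**

$$t_c = t_m - \frac{(\theta - d_0)^{1/n}}{a^{(n+1)/n}} .$$

The model rate is then

$$S(t) = \begin{cases} 0, & t \le t_c \\
  \bigl[\theta - D(t)\bigr]\, C(t), & t > t_c . \end{cases}$$

Two limiting behaviours characterize the family. When $\theta \to 0$ and
$d_0 \to 0$ (and the middle age is placed at the origin), $S$ is exactly
$K$ times a Weibull density with shape $n + 1$ and scale
$(n+1)^{1/(n+1)}/a$ — the tests verify this to machine precision. At the
other end of life, $B$ grows polynomially while $C$ collapses, so rates
rise into old age, peak, and then decay monotonically to zero.

## The critical age in published tables: derived vs free

The algebra above *derives* $t_c$ from $(\theta, a, t_m, d_0)$. Published
parameter tables, however, report the critical age with its own standard
error, and their degrees-of-freedom bookkeeping (e.g. 68 residual degrees
of freedom from roughly 74 single-year ages with all parameters free)
indicates that the original fitting software treated the cut age as a
*free sixth parameter*. The two conventions do not coincide: evaluating the
derived expression at the published USA-2001 both-gender estimates gives
$t_c \approx 36$ years, far from the printed $12.2$.

The package therefore exposes both paths and keeps them clearly apart:

* `critical_age(params)` is the derived closed form, used by default in
  `evaluate_rate()` and `fit_tbm()`, with a delta-method standard error;
* `fit_config(free_critical_age = TRUE)` adds the cut age to the optimizer
  (the published-table convention), and `evaluate_rate(..., critical = x)`
  evaluates the curve with a stored cut. With a free cut the bias factor is
  floored at zero so rates are never negative, and the cut parameter is
  only weakly identified whenever the bias factor already vanishes at the
  derived crossing — its covariance is then singular by construction and
  the fit says so.

`table1_fixture()` ships the published parameter rows verbatim, including
the printed critical ages; the derived value from the same row is a
consistency diagnostic, not an identity, and no headline computation
depends on reconciling the two.

## Fitting

`fit_tbm()` minimizes the unweighted residual sum of squares between the
observed rates and the model, by the Levenberg–Marquardt algorithm
(`minpack.lm::nls.lm`; interval-typed ages enter at their midpoints, the
standard convention for wide age groups). The convergence tolerance is
$10^{-8}$ on the relative change of the objective with an iteration cap of
500 — reference fits converge in well under 50 iterations. Non-convergence
is reported as a flagged result carrying the best-so-far state, never
silently.

**Initialization** (`initialize_parameters()`) follows the standard
protocol: the middle age starts at half the population's life expectancy
when known, else at the rate-weighted median age of the series; the
product $\theta K$ is matched to the observed rate nearest the middle-age
start; and the remaining starts are package defaults
($\theta = 15$, $a = 0.15\ \mathrm{yr}^{-1}$, $d_0 = 0.002\
\mathrm{yr}^{-1}$, $n = 9$), chosen as typical magnitudes for national
all-method series and overridable through `fit_config(initial = )`.

**Fixed parameters.** Some published analyses only converge for female
series when $t_m$ and $d_0$ are held fixed; `fit_config(fixed = c("t_m",
"d0"))` reproduces that workflow, and fixing $k$ parameters raises the
residual degrees of freedom by exactly $k$.

**Standard errors.** The covariance at convergence is
$s^2 (J^\top J)^{-1}$ with $J$ the central-finite-difference Jacobian of
the model curve. The residual variance $s^2$ is estimated over the
*on-support* points only — those where the fitted expectation exceeds the
same $10^{-6}$ floor used by the Pearson statistic. Below the critical age
the model is identically zero with zero gradient: such points carry no
parameter information, and when observations there are zero-truncated
noise their residuals are underdispersed, so including them would dilute
$s^2$. A 100-replicate simulation at the packaged study conditions shows
this convention is well calibrated (empirical SD over mean reported SE
within a few percent of 1 for every parameter), whereas pooling all points
understates the errors by 20–40%. The derived critical age's error follows
by first-order propagation through the closed form, using the full free-
parameter covariance.

**Goodness of fit.** Two chi-square statistics are reported, because the
original fitting software's value is non-conventional:

* `chi_square_origin()`: $\sum_i (o_i - e_i)^2 / (N - P)$, the residual
  sum reduced by points minus free parameters — the value the fitting
  software displays;
* `chi_square_conventional()`: the Pearson form $\sum_i (o_i - e_i)^2 /
  e_i$, from which `p_value()` computes the upper-tail chi-square
  probability on $N - P$ degrees of freedom. Points with expectation below
  $10^{-6}$ (in particular everything at or below the cut) are excluded,
  and the exclusion count is reported. The upper-tail convention is the
  one that reproduces published p-values (e.g. $\chi^2 = 25.08$, 10 df
  $\to 0.005$; $14.54$, 8 df $\to 0.069$).

**Exponent selection.** `select_exponent()` grids over odd candidates
(default 7–15) and keeps the fit with the smallest *Origin-style*
chi-square, breaking ties toward the smaller exponent. The published
selection criterion — minimize standard errors, chi-square and band widths
— refers to the chi-square the fitting software shows, which is the
reduced-residual form. The Pearson form is deliberately not used as the
selector: for a steep-onset curve its value is dominated by whichever grid
point happens to sit just above the fitted cut, where the expectation is
arbitrarily small, and in simulation that noise masks the true exponent in
about half the replicates.

## Forecasting

`parameter_trajectory()` orders per-year fits (or published rows) and
`extrapolate_parameters()` runs, for each parameter independently, a
straight line of value against calendar year — exact through two points,
ordinary least squares for more — evaluated at the target year. Standard
errors are carried forward by the same linear rule. This simple rule is a
design choice: it reproduces the published 2003 forecast errors for
$\theta$, $a$ and $d_0$ exactly from the printed 2001/2002 values, and
$t_m$, $t_c$, $K$ to printed rounding; published work does not state its
propagation rule, and inventing a formal one would suggest more rigour
than two yearly points can support. (From the *rounded* inputs, $K$
extrapolates to 88.5 against a printed 88.4, and the $t_c$ error to 0.7
against 0.6 — consistent with the original extrapolation having used
unrounded estimates.)

`predict_curve()` evaluates the central curve and propagates per-parameter
standard errors through the model by central finite differences (step
$10^{-6}$ of each parameter's scale), scaled by the normal quantile of the
requested level — factor 1.0 at the one-standard-deviation level 0.682,
1.96 at 0.95. Prediction bands add the residual standard deviation in
quadrature; confidence bands do not. Cross-parameter covariance is
ignored, since published tables print per-parameter errors only; with the
strong $K$–$\theta$ anti-correlation this typically *overstates* band
widths, a conservatism worth keeping in mind. Lower envelopes are floored
at zero. `evaluate_prediction()` scores an observed series against a fixed
(e.g. extrapolated) curve with zero free parameters: degrees of freedom
equal the number of admitted points.

## The synthetic-data generator

`generate_series()` draws age–rate tables from known parameters so every
other module is testable without any external download. The default grid
is single years of age 10–84, mirroring the support of national
single-year tables. Three noise models:

* `none` — the exact model curve;
* `gaussian` — i.i.d. perturbations of standard deviation `sigma`,
  truncated at zero because rates cannot be negative. The truncation
  biases near-zero rates upward by about $0.4\sigma$; this is accepted and
  matters only below the critical age;
* `poisson` — death counts drawn at expectation
  $\text{rate} \times \text{population} / 10^5$ and converted back to
  rates; for means beyond integer range the asymptotically exact normal
  approximation is used.

All randomness flows through an explicit integer seed (R's default
Mersenne–Twister generator inside an isolated `withr::with_seed()` scope),
so identical calls are identical byte for byte. `aggregate_groups()`
population-weights single-year rates into wide half-open age groups,
emulating the coarse reporting the model was designed to work around; in
paired simulations, fits to 10-year groups recover the generating
parameters measurably worse than fits to single years.

What the generator does *not* emulate: cohort effects, year-to-year shocks,
age-dependent reporting completeness, and method- or gender-specific
mixtures. Passing the packaged tests therefore demonstrates internal
consistency of estimator and model, not that real national series follow
the TBM.

## Numerical choices and degenerate inputs

* The exponential in $C$ underflows once $\bigl(a\,|t - t_m|\bigr)^{n+1}$
  exceeds about 700 — roughly 16 years from $t_m$ at $a = 0.147$, $n = 9$.
  The rate is then exactly 0 in double precision, which is the correct
  limit; oracle comparisons against the integrated growth law are run on
  windows where $C$ is representable (±14 years at $a = 0.147$, the full
  ±40 years at $a = 0.05$), at relative error below $10^{-8}$.
* Parameter validation accepts the boundary cases $\theta = d_0$ (cut at
  the middle age itself) and $t_m = 0$ (the Weibull limit), which the
  model's limiting behaviour requires.
* All-zero series are rejected at initialization as degenerate; series
  with fewer points than free parameters are rejected before fitting;
  singular covariances yield absent standard errors with a warning, not an
  error.
* The optimizer explores through an admissibility wall (large residuals
  outside $K, a > 0$, $\theta \ge d_0$) rather than a reparameterization,
  keeping reported covariances in the natural units of the printed tables.

## Problem sizes

The packaged simulations use 100-replicate ensembles for coverage checks
(a few seconds of CPU), 1000 random parameter sets for the piecewise
support property, and 11–15 replicates for selection-majority checks;
these sizes give binomial margins comfortably tighter than the properties
being asserted while keeping the whole suite interactive.

## Known limitations

* The within-sample Pearson statistic on Gaussian-noise synthetic series
  is inflated by onset-region points with tiny expectations; it is
  reported faithfully but is not chi-square distributed under that noise
  model.
* Forecasting is a two-point (or few-point) straight line per parameter —
  adequate for one-year-ahead projection, not a trend model.
* The derived and published-table conventions for the critical age differ
  (see above); cross-study comparisons should state which convention they
  use.
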