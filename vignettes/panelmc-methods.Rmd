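---
title: "Comparing random-, fixed- and within-between effects estimators by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing random-, fixed- and within-between effects estimators by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(panelmc)
library(dplyr)
```

## The problem

Observational health data are usually clustered: patients within
facilities, facilities within regions, repeated measures within subjects.
Unmeasured group-level characteristics (budgets, policies, disease
patterns) shift the outcome of every member of a group. The working model
is

$$y_{jn} = \beta x_{jn} + \mu_j + \varepsilon_{jn},$$

with groups $j = 1,\dots,J$, members $n = 1,\dots,N$, a latent group
effect $\mu_j$ and an i.i.d. residual $\varepsilon_{jn}$. Three standard
estimators of the marginal effect $\beta$ differ in how they treat
$\mu_j$:

* **Pooled OLS** ignores it. When $\rho = \mathrm{corr}(\mu, x) \ne 0$
  the pooled slope converges to $\beta + \rho\,\sigma_\mu/\sigma_x$
  (omitted-variable bias).
* **Fixed effects (FE, "within")** removes group means, using only
  within-group variation. Unbiased at any $\rho$, but imprecise when most
  covariate variation lies between groups, and identical to the
  least-squares dummy-variable (LSDV) regression.
* **Random effects (RE)** quasi-demeans by
  $\theta = 1 - \sqrt{\sigma^2_\varepsilon/(\sigma^2_\varepsilon +
  N\sigma^2_\mu)}$ and runs OLS (feasible GLS). Efficient when
  $\mu \perp x$, increasingly biased as $\rho$ grows.
* **Within-between (WB, Mundlak correlated random effects)** applies RE
  machinery to the group-demeaned covariate plus the group mean,
  recovering the FE (within) effect while also estimating a between-group
  effect $\gamma$.

The practitioner faces a bias-precision tradeoff that theory alone does
not settle, conventionally adjudicated by the Hausman test. This package
quantifies the tradeoff by Monte Carlo: a parameterised generator of
clustered datasets, from-scratch implementations of the four estimators
and the Hausman test, and a scenario-grid runner that aggregates
coefficient errors, MSEs and prediction RMSEs into practical
estimator-selection statistics.

## The data-generating process

`generate_dataset()` follows a four-step recipe. With
$\sigma^2_W = \tau \sigma^2_x$ and $\sigma^2_B = (1-\tau)\sigma^2_x$ the
within/between split of the covariate variance:

1. lay out $J \times N$ observation slots;
2. draw $(\mu_j, \bar x_j)$ from a bivariate normal with
   $\mathrm{Var}(\mu) = 1$, $\mathrm{Var}(\bar x) = \sigma^2_B$ and
   $\mathrm{Cov}(\mu, \bar x) = \rho\,\sigma_x$;
3. draw $(w_{jn}, \varepsilon_{jn})$ with $\mathrm{Var}(w) = \sigma^2_W$,
   $\mathrm{corr}(w, \varepsilon) = \psi$, and residual variance
   $\sigma^2_\varepsilon$ calibrated so the residual accounts for a share
   $\pi$ of $\mathrm{Var}(y)$;
4. assemble $x = \bar x_j + w$, $y = \beta x + \mu_j + \varepsilon$.

Design choices worth spelling out:

* **$\rho$ targets the total covariate.** We interpret $\rho$ as
  $\mathrm{corr}(\mu, x)$, implemented through
  $\mathrm{Cov}(\mu, \bar x) = \rho \sigma_x$. Positive semi-definiteness
  of the step-2 covariance then requires $\rho \le \sqrt{1 - \tau}$, which
  matches the design's stated impossibility of generating $\rho > 0.7$
  while holding the variance split (at the default $\tau = 0.5$,
  $\rho_{\max} = \sqrt{0.5} \approx 0.707$). The alternative reading,
  $\rho = \mathrm{corr}(\mu, \bar x)$, would make every $\rho < 1$
  feasible and is exposed as `rho_target = "between"` for sensitivity
  work. Infeasible grid cells are enumerated and flagged, never silently
  dropped.
* **Residual calibration honours the variance contract literally.**
  $\mathrm{Var}(y) = \beta^2\sigma^2_x + 1 + 2\beta\rho\sigma_x +
  2\beta\psi\sigma_W\sigma_\varepsilon + \sigma^2_\varepsilon$; at
  $\psi = 0$ the closed form
  $\sigma^2_\varepsilon = \frac{\pi}{1-\pi}(\beta^2\sigma^2_x + 1 +
  2\beta\rho\sigma_x)$ applies, otherwise the defining equation is solved
  as a quadratic in $\sigma_\varepsilon$ (positive root).
* **Autocorrelated residuals are stationarity-normalised.** Under
  $\upsilon \ne 0$ the within-group residual is a stationary AR(1) with
  innovation variance $\sigma^2_\varepsilon(1 - \upsilon^2)$ and the first
  draw from the stationary law, so $\sigma^2_\varepsilon$ remains the
  marginal variance and $\pi$ keeps its meaning.
* **Misspecification is one-at-a-time.** The grid crosses every other
  dimension with three conditions — correct specification, endogeneity
  ($\psi = 0.2$), autocorrelation ($\upsilon = 0.2$) — rather than a full
  $\psi \times \upsilon$ product; this reproduces the designed 16,200
  scenarios (3 J x 3 N x 8 $\rho$ x 3 $\sigma^2_x$ x 5 $\tau$ x 5 $\pi$ x
  3 conditions).
* **No intercept is generated**; every estimator still fits one.

## Estimators and numerical choices

All regressions are solved by normal equations on explicit design
matrices (two or three well-conditioned columns), and the test suite pins
them to independent oracles: LSDV against `lm()` with explicit dummies,
the within slope against the hand-demeaned closed form, and FGLS against
brute-force GLS with the explicit block covariance
$\Omega = \sigma^2_\varepsilon I + \sigma^2_\mu ZZ'$.

* **Variance components** use the balanced-panel moment method
  (Swamy-Arora type): $\hat\sigma^2_\varepsilon$ from the within SSR over
  $JN - J - 1$, $\hat\sigma^2_\mu = \max(0, \mathrm{MS}_B -
  \hat\sigma^2_\varepsilon/N)$ from the group-means regression. Truncation
  at zero makes $\theta = 0$ and RE collapses to pooled OLS exactly.
* **RE and WB standard errors** are the FGLS covariance at the estimated
  components, $\hat\sigma^2_\varepsilon (X^{*\prime}X^*)^{-1}$ — the
  convention of standard panel software — rather than the
  transformed-regression residual variance. The choice matters for the
  Hausman test's finite-sample power and was fixed by matching the
  published per-cell agreement shares.
* **Hausman test** in the scalar form
  $H = (\hat\beta_{FE} - \hat\beta_{RE})^2/(se^2_{FE} - se^2_{RE})$,
  $\chi^2_1$, which is exact with a single slope. A non-positive variance
  difference (possible in finite samples) is flagged `degenerate` and
  mapped deterministically to fail-to-reject, i.e. the conventional RE
  recommendation.
* **Predictions** use the fixed part for RE and WB and the recovered group
  intercepts for FE, matching the default behaviour of the software era
  the study design reflects; empirical-Bayes (BLUP) group predictions are
  available behind `blup = TRUE` for sensitivity analysis.
* **Ties** (equal absolute errors) count as agreement in the Hausman
  agreement share — a probability-zero event, fixed only for determinism.
  Percentiles use linear interpolation between order statistics
  (`quantile()` type 7).

## The two within-between variants

On a balanced panel the group-demeaned covariate is exactly orthogonal to
the group-level regressors, so the WB within coefficient computed from
*empirical* group means equals the FE slope to machine precision — their
finite-sample MSEs cannot differ. `fit_wb()` defaults to this estimator,
which is the only one available on real data.

A simulation study, however, also has the generator's *latent* components
$w_{jn}$ and $\bar x_j$ in hand, and regressing on those instead
(`group_means = "latent"`) breaks the exact orthogonality: the sample
group means of $w$ do not vanish, so the within coefficient uses a little
between-group information. The result stays unbiased but is typically
slightly more precise than FE in small samples with strong between-group
variation — and this is the only variant for which "WB versus FE in
finite samples" is a non-degenerate question. The experiment runner
therefore tracks the latent variant in its WB columns; the gap shrinks
with $J$, $N$ and $\tau$ and grows with the residual share $\pi$, which is
exactly the correlation structure the grid analysis reports. The
`mundlak_variant` flag additionally exposes the undemeaned
parameterisation ($x$ and $\bar x_j$); its raw group-mean coefficient is
the between-minus-within difference, and the reported between effect adds
the two raw coefficients so both parameterisations return the same
(within, between) pair.

## Scenario grid, seeds and scale

`dimension_spec()` defaults reproduce the full factorial design; 2,430 of
the 16,200 cells are infeasible ($\rho > \sqrt{1-\tau}$ at
$\tau \in \{0.75, 0.9\}$) and are reported as skipped. Each scenario runs
on its own RNG substream derived from the master seed and the scenario id
(a Lehmer-style hash kept below $2^{31}$), so grid results are identical
for any worker count and any cell is reproducible in isolation.

Problem sizes used by the package's own acceptance checks (chosen as
desk-scale renditions of the full 16,200 x 1,000 experiment, which is a
compute-cluster job):

* per-cell Hausman agreement shares: the full 8 $\rho$-values x 1,000
  replicates for the quoted cells;
* grid-wide shares and medians: the full grid at 24 replicates per
  scenario;
* small-sample WB-FE gap statistics: the $JN < 500$ slice at 100
  replicates per scenario.

Shares and medians are unbiased under replicate reduction; per-scenario
MSEs are noisier, which inflates both tails of the gap-share statistics
and attenuates (at very low replicate counts) or sharpens (as replicates
grow) the gap correlations, so those checks carry wider bands.

## Rule-of-thumb aggregation

`summarize_rules_of_thumb()` pools replicates across scenarios (every
scenario carries the same replicate count, so pooled shares equal means of
per-scenario shares). By default it excludes the endogenous condition
($\psi \ne 0$): with a correlated residual *no* estimator is consistent —
the within-deviation bias $\psi\sigma_\varepsilon/\sigma_W$ dwarfs
everything else at small $\tau$ — so error-magnitude rules of thumb are
computed over designs where the estimators estimate what they claim to.
The pooled FE/RE error medians reproduce the published values only under
this convention, which is how the convention was identified; passing all
three condition labels overrides it. Subset bounds follow the exact
phrasing of each statistic: strictly more than 500 observations for the
large-sample medians, at least 1,000 for the large-sample agreement share,
strictly fewer than 500 for the small-sample shares. The LSDV $R^2$
(overall $R^2$ of the dummy-variable regression, computed via the
within-residual identity) is the goodness-of-fit measure behind the
"poorly fit model" filter.

## What the generator does and does not emulate

The generator covers balanced panels, one normal covariate, a single
normal group effect, and the two misspecifications above. It does not
emulate unbalanced groups, non-normal or heavy-tailed effects, multiple
covariates, heteroskedastic residuals, binary outcomes, survey weights,
or multiple clustering dimensions. Passing tests therefore demonstrate
correctness of the estimators and the bias-precision phenomenology under
this stylised design — not that the numeric rules of thumb transfer to
data violating it.

## Worked example

```{r example}
scen <- enumerate_scenarios(dimension_spec(
  J_values = 50, N_values = 10, rho_values = c(0, 0.3, 0.6),
  sigma2_x_values = 1, tau_values = 0.5, pi_values = 0.5,
  psi_values = 0, upsilon_values = 0))
grid <- run_grid(scen, replicates = 200, master_seed = 1)
grid$summaries |>
  select(rho, mean_err_re, mean_err_fe, mse_re, mse_fe,
         hausman_fail_to_reject_share, preference_label)
```

At $\rho = 0$ RE has the smaller MSE (efficiency), inside the trivial
band; by $\rho = 0.6$ it is visibly biased and FE is MSE-preferred, and
the Hausman rejection rate rises with $\rho$.

```{r plots, fig.width = 7, fig.height = 4}
plot_error_distribution(grid$summaries)
```

## Known limitations

* The latent-means WB variant is a reconstruction of the original
  experiment's estimator, identified from the printed finite-sample gap
  structure; its gap-versus-$\pi$ correlation runs somewhat stronger than
  the published value, so that check is held to sign, significance, rank
  and a wide magnitude band.
* Variance components are method-of-moments, not ML; the two are
  asymptotically equivalent but can differ in very small samples.
* The runner keeps replicate-level records in memory when requested;
  full-grid runs at 1,000 replicates should write checkpoints and drop
  records, or run in slices.
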