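# panelmc

Monte-Carlo comparison of the three standard estimators for clustered
(grouped/panel) data — random effects (RE, feasible GLS), fixed effects
(FE, within/LSDV) and the within-between (WB, Mundlak correlated random
effects) specification — plus pooled OLS and the Hausman test.

Observational health studies routinely analyse observations nested in
groups that share unmeasured characteristics. Under the clustered model

```
y_jn = beta * x_jn + mu_j + eps_jn,     j = 1..J groups, n = 1..N members
```

the choice of estimator is a bias-precision tradeoff governed by
`rho = corr(mu, x)`: FE is unbiased at any `rho` but uses only
within-group variation; RE is efficient when `rho = 0` and biased
otherwise (its quasi-demeaning weight is
`theta = 1 - sqrt(sigma2_eps / (sigma2_eps + N * sigma2_mu))`); the WB
specification regresses `y` on the group-demeaned covariate plus the
group mean, recovering the FE within effect inside the flexible RE
machinery together with a between-group effect `gamma`. The Hausman
statistic `H = (b_FE - b_RE)^2 / (se_FE^2 - se_RE^2) ~ chi^2(1)`
conventionally adjudicates RE vs FE.

panelmc provides, tidyverse-style (tibbles in and out, `tidy()`/
`glance()` methods, `autoplot()`):

* a parameterised generator of balanced clustered datasets
  (`generate_dataset()`) with controllable group count `J`, group size
  `N`, effect-covariate correlation `rho`, covariate variance and its
  within-group share (`sigma2_x`, `tau`), residual variance share `pi`,
  endogeneity `psi`, and residual AR(1) autocorrelation `upsilon`;
* from-scratch estimators (`fit_pooled()`, `fit_fe_within()`,
  `fit_fe_lsdv()`, `fit_re_fgls()`, `fit_wb()`) and `hausman_test()`;
* a 16,200-cell factorial scenario grid (`dimension_spec()`,
  `enumerate_scenarios()`) with positive-semi-definiteness feasibility
  flagging (`rho <= sqrt(1 - tau)`), a seeded, checkpointable,
  worker-invariant runner (`run_scenario()`, `run_grid()`), and
  evaluation metrics through `summarize_rules_of_thumb()` and
  `mse_gap_correlations()`.

## Worked example

```r
library(panelmc)
library(dplyr)

scen <- enumerate_scenarios(dimension_spec(
  J_values = 50, N_values = 10, rho_values = c(0, 0.3, 0.6),
  sigma2_x_values = 1, tau_values = 0.5, pi_values = 0.5,
  psi_values = 0, upsilon_values = 0))
grid <- run_grid(scen, replicates = 200, master_seed = 1)
grid$summaries |>
  select(rho, mean_err_re, mean_err_fe, mse_re, mse_fe,
         hausman_fail_to_reject_share, preference_label)
#> # A tibble: 3 x 7
#>     rho mean_err_re mean_err_fe  mse_re  mse_fe hausman_fail_to_reject_share preference_label
#>   <dbl>       <dbl>       <dbl>   <dbl>   <dbl>                        <dbl> <chr>
#> 1   0       0.00799     0.0101  0.00689 0.00842                        0.92  trivial
#> 2   0.3     0.124      -0.00351 0.0231  0.00997                        0.225 FE
#> 3   0.6     0.379      -0.0183  0.159   0.0151                         0     FE
```

At `rho = 0` both estimators are centred on the truth, RE has the
smaller MSE (efficiency), the difference is below the 0.005 triviality
threshold, and the Hausman test fails to reject in 92% of replicates. By
`rho = 0.6` the RE slope is biased upward (mean error 0.38) while FE
stays centred, FE is MSE-preferred by an order of magnitude, and the
test rejects in every replicate.
`plot_error_distribution()`, `plot_mse()`, `plot_hausman()` and
`plot_prediction_rmse()` (or `autoplot(grid, type = ...)`) draw the
corresponding panel figures.

A command-line front end wrapping the same functions lives at
`inst/cli/panelmc.R` (`run`, `summarize`, `list-grid`), with YAML
configuration files mirroring the `dimension_spec()` arguments.

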