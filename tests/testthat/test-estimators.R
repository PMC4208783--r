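test_that("pooled OLS matches lm and catches degenerate designs", {
  set.seed(11)
  ds <- generate_dataset(baseline_scenario(J = 20, N = 5, rho = 0.3))
  fit <- fit_pooled(ds)
  ref <- lm(y ~ x, data = ds)
  expect_equal(fit$beta_hat, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(fit$se_beta, unname(sqrt(diag(vcov(ref)))[2]),
               tolerance = 1e-10)
  expect_equal(fit$fitted, unname(fitted(ref)), tolerance = 1e-10)
  # exact fit: y = 2x
  exact <- tibble::tibble(group_id = rep(1:2, each = 3),
                          obs_id = rep(1:3, 2), x = c(1:3, 4:6),
                          y = 2 * c(1:3, 4:6))
  expect_equal(fit_pooled(exact)$beta_hat, 2, tolerance = 1e-12)
  exact$x <- 1
  expect_error(fit_pooled(exact), "zero variance")
})

test_that("the within estimator reproduces the hand-worked example", {
  toy <- toy_two_group_panel()
  fit <- fit_fe_within(toy)
  expect_equal(fit$beta_hat, 1, tolerance = 1e-12)
  expect_equal(unname(fit$alpha), c(0, 4), tolerance = 1e-12)
  expect_equal(fit$fitted, toy$y, tolerance = 1e-12)
  # within-invariance: shifting one group's y leaves the slope unchanged
  shifted <- toy
  shifted$y[shifted$group_id == 2] <- shifted$y[shifted$group_id == 2] + 100
  expect_equal(fit_fe_within(shifted)$beta_hat, fit$beta_hat,
               tolerance = 1e-12)
  # no within variation -> inestimable
  toy$x <- rep(c(0, 5), each = 2)
  expect_error(fit_fe_within(toy), "within-group variation")
})

test_that("LSDV and within estimation are numerically equivalent", {
  # LSDV cross-checked against base lm with explicit dummies
  set.seed(12)
  for (cfg in list(baseline_scenario(J = 10, N = 5, rho = 0.4),
                   baseline_scenario(J = 30, N = 8, rho = 0, tau = 0.9),
                   baseline_scenario(J = 15, N = 4, rho = 0.2, pi = 0.9))) {
    ds <- generate_dataset(cfg)
    fe <- fit_fe_within(ds)
    lsdv <- fit_fe_lsdv(ds)
    expect_equal(lsdv$beta_hat, fe$beta_hat, tolerance = 1e-8)
    expect_equal(lsdv$se_beta, fe$se_beta, tolerance = 1e-8)
    ref <- lm(y ~ x + factor(group_id), data = ds)
    expect_equal(lsdv$beta_hat, unname(coef(ref)["x"]), tolerance = 1e-8)
    expect_equal(lsdv$r_squared, summary(ref)$r.squared, tolerance = 1e-8)
  }
  # exact toy fit has R^2 = 1; pure noise has R^2 near 0
  expect_equal(fit_fe_lsdv(toy_two_group_panel())$r_squared, 1,
               tolerance = 1e-12)
  set.seed(13)
  noise <- tibble::tibble(group_id = rep(1:10, each = 1000),
                          obs_id = rep(1:1000, 10),
                          x = rnorm(10000), y = rnorm(10000))
  expect_lt(fit_fe_lsdv(noise)$r_squared, 0.05)
})

test_that("variance components are consistent and truncate at zero", {
  # DGP with sigma2_eps = 2, sigma2_mu = 1 (baseline rho = 0, pi = 0.5)
  set.seed(14)
  ds <- generate_dataset(baseline_scenario(J = 2000, N = 50))
  vc <- estimate_variance_components(ds)
  expect_equal(vc$sigma2_eps, 2, tolerance = 0.05)
  expect_equal(vc$sigma2_mu, 1, tolerance = 0.1)
  # mu == 0 data: the group-effect component is truncated at zero
  set.seed(15)
  flat <- tibble::tibble(group_id = rep(1:50, each = 10),
                         obs_id = rep(1:10, 50), x = rnorm(500))
  flat$y <- flat$x + rnorm(500)
  vc0 <- estimate_variance_components(flat)
  expect_gte(vc0$sigma2_mu, 0)
  expect_lt(vc0$sigma2_mu, 0.05)
})

test_that("FGLS equals brute-force GLS with the explicit block covariance", {
  set.seed(16)
  for (cfg in list(baseline_scenario(J = 10, N = 5, rho = 0.4),
                   baseline_scenario(J = 20, N = 10, rho = 0.6, tau = 0.25),
                   baseline_scenario(J = 40, N = 5, rho = 0, pi = 0.9))) {
    ds <- generate_dataset(cfg)
    re <- fit_re_fgls(ds)
    oracle <- gls_slope_explicit_omega(ds, re$sigma2_eps_hat,
                                       re$sigma2_mu_hat)
    expect_equal(re$beta_hat, oracle, tolerance = 1e-6)
  }
})

test_that("the quasi-demeaning weight obeys its boundary identities", {
  # sigma2_mu truncated to 0 -> theta = 0 -> RE slope equals pooled exactly
  set.seed(17)
  flat <- tibble::tibble(group_id = rep(1:40, each = 5),
                         obs_id = rep(1:5, 40), x = rnorm(200))
  flat$y <- flat$x + rnorm(200, sd = 3)
  re <- fit_re_fgls(flat)
  if (re$sigma2_mu_hat == 0) {
    expect_equal(re$theta, 0)
    expect_equal(re$beta_hat, fit_pooled(flat)$beta_hat, tolerance = 1e-12)
  }
  # dominant group effects -> theta near 1 -> RE approaches within
  set.seed(18)
  ds <- generate_dataset(baseline_scenario(J = 50, N = 10, rho = 0))
  ds$y <- ds$y + 50 * ds$mu
  re <- fit_re_fgls(ds)
  expect_gt(re$theta, 0.95)
  expect_equal(re$beta_hat, fit_fe_within(ds)$beta_hat, tolerance = 0.01)
  expect_true(re$theta >= 0 && re$theta <= 1)
  # theta formula: components (1, 1) at N = 3 give theta = 0.5; verified
  # through the fitted object's own components
  set.seed(19)
  ds3 <- generate_dataset(baseline_scenario(J = 500, N = 3, rho = 0,
                                            pi = 1 / 3))
  re3 <- fit_re_fgls(ds3)
  theta_expected <- 1 - sqrt(re3$sigma2_eps_hat /
                               (re3$sigma2_eps_hat + 3 * re3$sigma2_mu_hat))
  expect_equal(re3$theta, theta_expected, tolerance = 1e-12)
  # and with sigma2_eps == sigma2_mu (pi = 1/3 targets both at 1), near 0.5
  expect_lt(abs(re3$theta - 0.5), 0.06)
})

test_that("the WB within coefficient equals the FE slope on balanced data", {
  set.seed(20)
  for (cfg in list(baseline_scenario(J = 10, N = 5, rho = 0.6, tau = 0.1),
                   baseline_scenario(J = 30, N = 8, rho = 0.3),
                   baseline_scenario(J = 20, N = 4, rho = 0, tau = 0.9))) {
    ds <- generate_dataset(cfg)
    fe <- fit_fe_within(ds)
    wb <- fit_wb(ds)
    expect_equal(wb$beta_hat, fe$beta_hat, tolerance = 1e-8)
    # the undemeaned parameterisation reports the same (within, between)
    mk <- fit_wb(ds, mundlak_variant = TRUE)
    expect_equal(mk$beta_hat, wb$beta_hat, tolerance = 1e-8)
    expect_equal(mk$gamma_hat, wb$gamma_hat, tolerance = 1e-8)
  }
})

test_that("WB is unbiased where RE is not, and degenerates are caught", {
  set.seed(21)
  ds <- generate_dataset(baseline_scenario(J = 2000, N = 50, rho = 0.6))
  expect_equal(fit_wb(ds)$beta_hat, 1, tolerance = 0.05)
  expect_gt(fit_re_fgls(ds)$beta_hat, 1.05)  # biased upward at rho = 0.6
  # latent-means variant: close to but not identical with the FE slope
  wb_lat <- fit_wb(ds, group_means = "latent")
  expect_equal(wb_lat$beta_hat, 1, tolerance = 0.05)
  expect_false(identical(wb_lat$beta_hat, fit_fe_within(ds)$beta_hat))
  # no within variation in x
  deg <- tibble::tibble(group_id = rep(1:20, each = 3),
                        obs_id = rep(1:3, 20),
                        x = rep(rnorm(20), each = 3))
  deg$y <- rnorm(60)
  expect_error(fit_wb(deg), "within")
  expect_error(fit_wb(dplyr::select(ds, -"x_between"),
                      group_means = "latent"), "x_between")
})

test_that("the Hausman test follows the chi-squared contract", {
  set.seed(22)
  ds <- generate_dataset(baseline_scenario(J = 20, N = 5, rho = 0.3))
  fe <- fit_fe_within(ds)
  re <- fit_re_fgls(ds)
  h <- hausman_test(fe, re)
  expect_equal(h$statistic,
               (fe$beta_hat - re$beta_hat)^2 /
                 (fe$se_beta^2 - re$se_beta^2))
  expect_equal(h$p_value, pchisq(h$statistic, 1, lower.tail = FALSE))
  expect_equal(h$recommend_re, h$p_value > 0.1)

  # worked case: diff 0.2, variance difference 0.04 -> H = 1, p = 0.3173
  fe2 <- fe; re2 <- re
  fe2$beta_hat <- 1.2; re2$beta_hat <- 1.0
  fe2$se_beta <- sqrt(0.05); re2$se_beta <- sqrt(0.01)
  h2 <- hausman_test(fe2, re2)
  expect_equal(h2$statistic, 1, tolerance = 1e-12)
  expect_equal(h2$p_value, 0.3173, tolerance = 1e-4)
  expect_true(h2$recommend_re)

  # identical slopes -> H = 0, p = 1
  re3 <- re2; re3$beta_hat <- fe2$beta_hat
  h3 <- hausman_test(fe2, re3)
  expect_equal(h3$statistic, 0)
  expect_equal(h3$p_value, 1)

  # non-positive variance difference -> deterministic degenerate path
  fe4 <- fe2; fe4$se_beta <- 0.01; re4 <- re2; re4$se_beta <- 0.5
  h4 <- hausman_test(fe4, re4)
  expect_true(h4$degenerate)
  expect_true(h4$recommend_re)

  # fits from different datasets are rejected
  set.seed(23)
  other <- generate_dataset(baseline_scenario(J = 20, N = 5, rho = 0.3))
  expect_error(hausman_test(fit_fe_within(other), re), "different datasets")
})

test_that("tidy and glance return the broom-style shapes", {
  set.seed(24)
  ds <- generate_dataset(baseline_scenario(J = 20, N = 5))
  wb <- fit_wb(ds)
  td <- tidy(wb)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_true("x_group_mean" %in% td$term)
  gl <- glance(fit_re_fgls(ds))
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("beta_hat", "theta", "sigma2_mu_hat", "dof") %in%
                    names(gl)))
})

test_that("BLUP predictions shrink group effects and reduce RMSE", {
  set.seed(25)
  ds <- generate_dataset(baseline_scenario(J = 50, N = 10, rho = 0))
  re_fixed <- fit_re_fgls(ds)
  re_blup <- fit_re_fgls(ds, blup = TRUE)
  expect_lt(prediction_rmse(re_blup$fitted, ds$y),
            prediction_rmse(re_fixed$fitted, ds$y))
})
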