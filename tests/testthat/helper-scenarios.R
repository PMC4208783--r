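# Scenario constructors used across the test files.

baseline_scenario <- function(J = 50L, N = 10L, rho = 0, sigma2_x = 1,
                              tau = 0.5, pi = 0.5, psi = 0, upsilon = 0,
                              beta = 1, scenario_id = 1L) {
  list(scenario_id = scenario_id, J = as.integer(J), N = as.integer(N),
       rho = rho, sigma2_x = sigma2_x, tau = tau, pi = pi, psi = psi,
       upsilon = upsilon, beta = beta)
}

# Tiny two-group panel with an exact within slope of 1 and group
# intercepts 0 and 4 (worked by hand).
toy_two_group_panel <- function() {
  tibble::tibble(
    group_id = c(1L, 1L, 2L, 2L),
    obs_id = c(1L, 2L, 1L, 2L),
    x = c(0, 1, 0, 1),
    y = c(0, 1, 4, 5)
  )
}

# Explicit-covariance GLS slope: the independent oracle for the FGLS path.
gls_slope_explicit_omega <- function(ds, sigma2_eps, sigma2_mu) {
  Z <- stats::model.matrix(~ 0 + factor(ds$group_id))
  Omega <- sigma2_eps * diag(nrow(ds)) + sigma2_mu * tcrossprod(Z)
  X <- cbind(1, ds$x)
  W <- solve(Omega)
  drop(solve(t(X) %*% W %*% X, t(X) %*% W %*% ds$y))[2]
}
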