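#' Group-level covariance of the latent effect and the group-mean covariate
#'
#' The group effect \eqn{\mu_j} has unit variance; the between-group
#' component of the covariate, \eqn{\bar x_j}, has variance
#' \eqn{\sigma^2_B = (1-\tau)\sigma^2_x}; and their covariance is
#' \eqn{\rho\,\sigma_x}, so that \eqn{\rho} is the correlation between
#' \eqn{\mu} and the *total* covariate \eqn{x} (see the package vignette for
#' why the covariance targets total rather than between-group correlation:
#' it reproduces the feasibility cap \eqn{\rho \le \sqrt{1-\tau}}).
#'
#' @param cfg A scenario row (see [enumerate_scenarios()]).
#' @param rho_target Either `"total"` (default; `rho` is the correlation
#'   between \eqn{\mu} and `x`) or `"between"` (`rho` is the correlation
#'   between \eqn{\mu} and \eqn{\bar x_j}).
#' @return A 2x2 covariance matrix with rows/columns `mu`, `xbar`.
#' @export
#' @examples
#' group_level_covariance(list(J = 10, N = 5, rho = 0.6, sigma2_x = 1,
#'   tau = 0.5, pi = 0.5, psi = 0, upsilon = 0, beta = 1))
group_level_covariance <- function(cfg, rho_target = c("total", "between")) {
  cfg <- as_scenario(cfg)
  rho_target <- match.arg(rho_target)
  sigma2_B <- (1 - cfg$tau) * cfg$sigma2_x
  cov_mu_xbar <- switch(rho_target,
    total = cfg$rho * sqrt(cfg$sigma2_x),
    between = cfg$rho * sqrt(sigma2_B)
  )
  S <- matrix(c(1, cov_mu_xbar, cov_mu_xbar, sigma2_B), 2, 2,
              dimnames = list(c("mu", "xbar"), c("mu", "xbar")))
  if (cov_mu_xbar^2 > sigma2_B + 1e-12) {
    feas <- check_feasibility(cfg)
    stop(sprintf(
      "infeasible scenario: rho = %.3f exceeds rho_max = sqrt(1 - tau) = %.4f",
      cfg$rho, feas$rho_max), call. = FALSE)
  }
  S
}

#' Draw the group-level components
#'
#' Draws `J` pairs \eqn{(\mu_j, \bar x_j)} from a bivariate normal with mean
#' zero and covariance [group_level_covariance()].
#'
#' @inheritParams group_level_covariance
#' @return A tibble with `J` rows and columns `group_id`, `mu`, `xbar`.
#' @export
draw_group_level <- function(cfg, rho_target = "total") {
  cfg <- as_scenario(cfg)
  S <- group_level_covariance(cfg, rho_target)
  # Cholesky-like square root valid on the PSD boundary (rho == rho_max),
  # where chol() can fail: S = [[1,c],[c,b]] factors as [[1,0],[c,sqrt(b-c^2)]].
  c_ <- S[1, 2]
  b <- S[2, 2]
  z <- matrix(stats::rnorm(2L * cfg$J), ncol = 2L)
  mu <- z[, 1L]
  xbar <- c_ * z[, 1L] + sqrt(max(b - c_^2, 0)) * z[, 2L]
  tibble::tibble(group_id = seq_len(cfg$J), mu = mu, xbar = xbar)
}

#' Residual variance required to hit the outcome-variance share pi
#'
#' Returns \eqn{\sigma^2_\epsilon} such that
#' \eqn{\mathrm{Var}(\epsilon)/\mathrm{Var}(y) = \pi} under the generating
#' model \eqn{y = \beta x + \mu + \epsilon}, where
#' \deqn{\mathrm{Var}(y) = \beta^2\sigma^2_x + 1 + 2\beta\rho\sigma_x
#'   + 2\beta\psi\sigma_W\sigma_\epsilon + \sigma^2_\epsilon.}
#' With \eqn{\psi = 0} this is the closed form
#' \eqn{\sigma^2_\epsilon = \frac{\pi}{1-\pi}(\beta^2\sigma^2_x + 1 +
#' 2\beta\rho\sigma_x)}; with \eqn{\psi \ne 0} the defining equation is a
#' quadratic in \eqn{\sigma_\epsilon} and the positive root is taken.
#'
#' @inheritParams group_level_covariance
#' @return The scalar \eqn{\sigma^2_\epsilon}.
#' @export
#' @examples
#' residual_scale(list(J = 10, N = 5, rho = 0, sigma2_x = 1, tau = 0.5,
#'   pi = 0.5, psi = 0, upsilon = 0, beta = 1)) # 2
residual_scale <- function(cfg) {
  cfg <- as_scenario(cfg)
  if (cfg$pi <= 0 || cfg$pi >= 1) {
    stop("pi must lie strictly in (0, 1)", call. = FALSE)
  }
  sigma_x <- sqrt(cfg$sigma2_x)
  signal <- cfg$beta^2 * cfg$sigma2_x + 1 + 2 * cfg$beta * cfg$rho * sigma_x
  if (cfg$psi == 0) {
    return(cfg$pi / (1 - cfg$pi) * signal)
  }
  # (1 - pi) s^2 - 2 pi beta psi sigma_W s - pi * signal = 0, s = sigma_eps
  sigma_W <- sqrt(cfg$tau * cfg$sigma2_x)
  a <- 1 - cfg$pi
  b <- -2 * cfg$pi * cfg$beta * cfg$psi * sigma_W
  cc <- -cfg$pi * signal
  s <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  s^2
}

#' Draw the observation-level components
#'
#' Draws within-group covariate deviations \eqn{w_{jn} \sim N(0,
#' \tau\sigma^2_x)} and residuals \eqn{\epsilon_{jn}} with marginal variance
#' `sigma2_eps`. Under endogeneity (`psi != 0`) the pair
#' \eqn{(w_{jn}, \epsilon_{jn})} is bivariate normal with correlation
#' \eqn{\psi}. Under autocorrelation (`upsilon != 0`) the residual follows a
#' stationary AR(1) within each group: \eqn{\epsilon_{j1}} is drawn from the
#' stationary law and \eqn{\epsilon_{jn} = \upsilon\,\epsilon_{j,n-1} +
#' \eta_{jn}} with \eqn{\mathrm{Var}(\eta) = \sigma^2_\epsilon(1 -
#' \upsilon^2)}, so the marginal residual variance is `sigma2_eps`
#' regardless of \eqn{\upsilon}.
#'
#' @inheritParams group_level_covariance
#' @param sigma2_eps Marginal residual variance (see [residual_scale()]).
#' @return A list with numeric `J*N`-vectors `w` and `eps`, ordered by
#'   group then observation.
#' @export
draw_observation_level <- function(cfg, sigma2_eps) {
  cfg <- as_scenario(cfg)
  if (!is.finite(sigma2_eps) || sigma2_eps <= 0) {
    stop("sigma2_eps must be positive", call. = FALSE)
  }
  if (abs(cfg$psi) >= 1 || abs(cfg$upsilon) >= 1) {
    stop("psi and upsilon must lie in (-1, 1)", call. = FALSE)
  }
  n_tot <- cfg$J * cfg$N
  sigma_W <- sqrt(cfg$tau * cfg$sigma2_x)
  sigma_eps <- sqrt(sigma2_eps)
  z1 <- stats::rnorm(n_tot)
  w <- sigma_W * z1
  if (cfg$upsilon == 0) {
    z2 <- stats::rnorm(n_tot)
    eps <- sigma_eps * (cfg$psi * z1 + sqrt(1 - cfg$psi^2) * z2)
  } else {
    # stationary AR(1) within each group; rows = groups, cols = observations
    z2 <- matrix(stats::rnorm(n_tot), nrow = cfg$J, ncol = cfg$N)
    e <- matrix(0, nrow = cfg$J, ncol = cfg$N)
    e[, 1L] <- sigma_eps * z2[, 1L]
    if (cfg$N > 1L) {
      innov_sd <- sigma_eps * sqrt(1 - cfg$upsilon^2)
      for (n in 2:cfg$N) {
        e[, n] <- cfg$upsilon * e[, n - 1L] + innov_sd * z2[, n]
      }
    }
    eps <- as.numeric(t(e)) # row-major: group-blocked, obs fastest
  }
  list(w = w, eps = eps)
}

#' Generate one balanced clustered dataset
#'
#' Four-step generation: (1) lay out `J * N` observation slots; (2) draw the
#' group-level pair \eqn{(\mu_j, \bar x_j)}; (3) draw the observation-level
#' pair \eqn{(w_{jn}, \epsilon_{jn})} with the residual scaled so a share
#' \eqn{\pi} of the outcome variance is residual; (4) assemble
#' \eqn{x_{jn} = \bar x_j + w_{jn}} and
#' \eqn{y_{jn} = \beta x_{jn} + \mu_j + \epsilon_{jn}}.
#'
#' The latent components `mu`, `eps` and the between-group covariate
#' component `x_between` (\eqn{\bar x_j} of step 2) are retained as columns
#' so that diagnostics can verify the generating moments exactly and so the
#' latent-means within-between variant (see [fit_wb()]) is available.
#'
#' @inheritParams group_level_covariance
#' @return A tibble of class `panel_dataset` with `J * N` rows, ordered by
#'   `(group_id, obs_id)`, and columns `group_id`, `obs_id`, `x`, `y`, `mu`,
#'   `eps`, `x_between`; the scenario is attached as attribute `"config"`.
#' @export
#' @examples
#' scen <- enumerate_scenarios(dimension_spec(J_values = 10, N_values = 5,
#'   rho_values = 0.3, sigma2_x_values = 1, tau_values = 0.5,
#'   pi_values = 0.5))[1, ]
#' set.seed(1)
#' ds <- generate_dataset(scen)
#' all.equal(ds$y, ds$x + ds$mu + ds$eps)
generate_dataset <- function(cfg, rho_target = "total") {
  cfg <- as_scenario(cfg)
  if (rho_target != "total") {
    # rare path: redo the group draw under the alternative rho reading
    groups <- draw_group_level(cfg, rho_target)
    sigma2_eps <- residual_scale(cfg)
    obs <- draw_observation_level(cfg, sigma2_eps)
    idx <- rep(seq_len(cfg$J), each = cfg$N)
    core <- list(x = groups$xbar[idx] + obs$w, eps = obs$eps, idx = idx,
                 mu_g = groups$mu, xbar_g = groups$xbar, w = obs$w)
    core$y <- cfg$beta * core$x + core$mu_g[idx] + core$eps
  } else {
    core <- generate_panel_core(cfg, residual_scale(cfg))
  }
  out <- tibble::tibble(
    group_id = core$idx,
    obs_id = rep(seq_len(cfg$N), times = cfg$J),
    x = core$x,
    y = core$y,
    mu = core$mu_g[core$idx],
    eps = core$eps,
    x_between = core$xbar_g[core$idx]
  )
  attr(out, "config") <- cfg
  class(out) <- c("panel_dataset", class(out))
  out
}

#' Write a simulated dataset to CSV
#'
#' @param ds A `panel_dataset`.
#' @param path Output file path.
#' @param latent Include the latent `mu` and `eps` columns (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(ds, path, latent = FALSE) {
  cols <- c("group_id", "obs_id", "x", "y", if (latent) c("mu", "eps"))
  utils::write.csv(as.data.frame(ds)[, cols], path, row.names = FALSE)
  invisible(path)
}
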