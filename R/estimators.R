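# Shared internals -----------------------------------------------------------

# Per-group index and means for a (possibly unordered) panel.
panel_groups <- function(ds) {
  g <- ds$group_id
  if (is.integer(g) && length(g) > 0 && min(g) >= 1L) {
    idx <- g
    cnt <- tabulate(g)
    if (any(cnt == 0L)) {
      f <- factor(g)
      idx <- as.integer(f)
      cnt <- tabulate(idx)
    }
  } else {
    f <- factor(g)
    idx <- as.integer(f)
    cnt <- tabulate(idx)
  }
  list(
    idx = idx,
    cnt = cnt,
    J = length(cnt),
    xbar = rowsum(ds$x, idx, reorder = FALSE)[, 1L] / cnt,
    ybar = rowsum(ds$y, idx, reorder = FALSE)[, 1L] / cnt
  )
}

# OLS on an explicit design matrix; se computed with the supplied dof.
ols_fit <- function(X, y, dof) {
  XtX <- crossprod(X)
  b <- drop(solve(XtX, crossprod(X, y)))
  fitted <- drop(X %*% b)
  ssr <- sum((y - fitted)^2)
  sigma2 <- ssr / dof
  se <- sqrt(pmax(diag(solve(XtX)), 0) * sigma2)
  list(coef = b, se = se, fitted = fitted, ssr = ssr, sigma2 = sigma2)
}

new_panel_fit <- function(estimator, ds, ...) {
  structure(
    c(list(estimator = estimator, n = nrow(ds), y_checksum = sum(ds$y)),
      list(...)),
    class = "panel_fit"
  )
}

check_design <- function(ds) {
  if (nrow(ds) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(ds$x) <= 0) {
    stop("degenerate design: x has zero variance", call. = FALSE)
  }
  invisible(ds)
}

# Estimators ------------------------------------------------------------------

#' Pooled OLS estimator
#'
#' Ordinary least squares of `y` on `x` with a constant, ignoring the group
#' structure entirely (the latent group effect is folded into the residual).
#' Serves as the baseline estimator and as the omitted-variable-bias oracle:
#' with an exogenous residual its large-sample slope is
#' \eqn{\beta + \rho\,\sigma_\mu/\sigma_x}.
#'
#' @param ds A data frame with columns `y`, `x`, `group_id` (a
#'   `panel_dataset` or anything of the same shape).
#' @return A `panel_fit` object; see [tidy.panel_fit()].
#' @family estimators
#' @export
fit_pooled <- function(ds) {
  check_design(ds)
  n <- nrow(ds)
  f <- ols_fit(cbind(const = 1, x = ds$x), ds$y, dof = n - 2L)
  new_panel_fit("pooled", ds,
    beta_hat = f$coef[["x"]], se_beta = f$se[[2L]],
    intercept = f$coef[["const"]], fitted = f$fitted,
    sigma2_hat = f$sigma2, dof = n - 2L
  )
}

#' Fixed-effects (within) estimator
#'
#' OLS of the group-demeaned outcome on the group-demeaned covariate. Uses
#' only within-group variation, so it is consistent under any dependence
#' between the group effect and the covariate. Degrees of freedom account
#' for the `J` absorbed group intercepts (`J*N - J - 1`), which the standard
#' error uses; the group intercepts are recovered as
#' \eqn{\hat\alpha_j = \bar y_j - \hat\beta \bar x_j} and enter the fitted
#' values.
#'
#' @inheritParams fit_pooled
#' @return A `panel_fit` with the recovered group intercepts in `alpha`.
#' @family estimators
#' @export
fit_fe_within <- function(ds) {
  gi <- panel_groups(ds)
  n <- nrow(ds)
  xd <- ds$x - gi$xbar[gi$idx]
  yd <- ds$y - gi$ybar[gi$idx]
  sxx <- sum(xd^2)
  if (sxx <= 1e-12 * max(1, sum(ds$x^2))) {
    stop("no within-group variation in x: fixed-effects slope inestimable",
         call. = FALSE)
  }
  beta <- sum(xd * yd) / sxx
  res <- yd - beta * xd
  dof <- n - gi$J - 1L
  if (dof <= 0L) stop("not enough observations for FE dof", call. = FALSE)
  sigma2 <- sum(res^2) / dof
  alpha <- gi$ybar - beta * gi$xbar
  new_panel_fit("fe", ds,
    beta_hat = beta, se_beta = sqrt(sigma2 / sxx),
    alpha = alpha, fitted = unname(alpha[gi$idx]) + beta * ds$x,
    sigma2_hat = sigma2, ssr_within = sum(res^2), dof = dof
  )
}

#' Fixed-effects estimator via least-squares dummy variables
#'
#' OLS of `y` on `x`, a constant and `J - 1` group indicators. Numerically
#' equivalent to [fit_fe_within()] (asserted in the test suite to 1e-8) but
#' computationally heavier; its overall \eqn{R^2} is the goodness-of-fit
#' statistic used by the estimator-selection rules of thumb.
#'
#' @inheritParams fit_pooled
#' @return A `panel_fit` with `r_squared` set.
#' @family estimators
#' @export
fit_fe_lsdv <- function(ds) {
  gi <- panel_groups(ds)
  n <- nrow(ds)
  xd <- ds$x - gi$xbar[gi$idx]
  if (sum(xd^2) <= 1e-12 * max(1, sum(ds$x^2))) {
    stop("no within-group variation in x: fixed-effects slope inestimable",
         call. = FALSE)
  }
  Z <- stats::model.matrix(~ factor(gi$idx))  # constant + J-1 dummies
  X <- cbind(Z, x = ds$x)
  dof <- n - ncol(X)
  f <- ols_fit(X, ds$y, dof = dof)
  tss <- sum((ds$y - mean(ds$y))^2)
  new_panel_fit("fe_lsdv", ds,
    beta_hat = f$coef[["x"]], se_beta = f$se[[ncol(X)]],
    fitted = f$fitted, sigma2_hat = f$sigma2,
    r_squared = if (tss > 0) 1 - f$ssr / tss else NA_real_,
    dof = dof
  )
}

#' Variance components of the error structure
#'
#' Moment-based (Swamy-Arora-type) estimates for the balanced
#' random-intercept model: the idiosyncratic variance
#' \eqn{\hat\sigma^2_\epsilon} is the within-regression SSR over
#' `J*N - J - 1`, and the group-effect variance is
#' \eqn{\hat\sigma^2_\mu = \max(0, \mathrm{MS}_B - \hat\sigma^2_\epsilon/N)}
#' where \eqn{\mathrm{MS}_B} is the residual mean square of the regression
#' of group means \eqn{\bar y_j} on \eqn{\bar x_j} (dof `J - 2`).
#'
#' @inheritParams fit_pooled
#' @return A tibble with columns `sigma2_eps` and `sigma2_mu`.
#' @export
estimate_variance_components <- function(ds) {
  gi <- panel_groups(ds)
  if (gi$J < 3L) stop("need at least 3 groups for variance components",
                      call. = FALSE)
  if (length(unique(gi$cnt)) != 1L) {
    stop("variance components require a balanced panel", call. = FALSE)
  }
  N <- gi$cnt[[1L]]
  fe <- fit_fe_within(ds)
  sigma2_eps <- fe$sigma2_hat
  # between regression on the group means
  xb <- gi$xbar
  yb <- gi$ybar
  if (stats::var(xb) > 1e-12 * max(1, mean(xb^2))) {
    bb <- stats::cov(xb, yb) / stats::var(xb)
    ssr_b <- sum((yb - mean(yb) - bb * (xb - mean(xb)))^2)
    ms_b <- ssr_b / (gi$J - 2L)
  } else {
    ms_b <- sum((yb - mean(yb))^2) / (gi$J - 1L)
  }
  tibble::tibble(sigma2_eps = sigma2_eps,
                 sigma2_mu = max(0, ms_b - sigma2_eps / N))
}

#' Random-effects estimator via feasible generalized least squares
#'
#' Estimates the variance components, forms the quasi-demeaning weight
#' \deqn{\theta = 1 - \sqrt{\hat\sigma^2_\epsilon / (\hat\sigma^2_\epsilon +
#' N\,\hat\sigma^2_\mu)},}
#' and applies OLS to the partially demeaned data \eqn{y - \theta\bar y_j}
#' on \eqn{x - \theta\bar x_j} and the quasi-demeaned constant
#' \eqn{1-\theta}. At \eqn{\theta = 0} this is pooled OLS; at
#' \eqn{\theta \to 1} it approaches the within estimator. Efficient when the
#' group effect is independent of the covariate, biased otherwise.
#'
#' Standard errors are the FGLS covariance evaluated at the estimated
#' variance components, \eqn{\hat\sigma^2_\epsilon (X^{*\prime}X^*)^{-1}}
#' (the convention of standard panel software), rather than the
#' transformed-regression residual variance.
#'
#' Fitted values use the fixed part \eqn{\hat\alpha + \hat\beta x} by
#' default; `blup = TRUE` adds the shrunken (empirical-Bayes) group-effect
#' predictions \eqn{\hat\mu_j = \frac{N\hat\sigma^2_\mu}
#' {\hat\sigma^2_\epsilon + N\hat\sigma^2_\mu}\,\bar r_j} based on the
#' group-mean fixed-part residuals \eqn{\bar r_j}.
#'
#' @inheritParams fit_pooled
#' @param blup Add empirical-Bayes group predictions to the fitted values.
#' @return A `panel_fit` with `theta`, `sigma2_eps_hat`, `sigma2_mu_hat`.
#' @family estimators
#' @export
fit_re_fgls <- function(ds, blup = FALSE) {
  gi <- panel_groups(ds)
  vc <- estimate_variance_components(ds)
  N <- gi$cnt[[1L]]
  theta <- 1 - sqrt(vc$sigma2_eps / (vc$sigma2_eps + N * vc$sigma2_mu))
  ystar <- ds$y - theta * gi$ybar[gi$idx]
  xstar <- ds$x - theta * gi$xbar[gi$idx]
  n <- nrow(ds)
  X <- cbind(const = 1 - theta, x = xstar)
  f <- ols_fit(X, ystar, dof = n - 2L)
  # FGLS covariance evaluated at the estimated components:
  # Var(b) = sigma2_eps * (X*'X*)^{-1}
  se_fgls <- sqrt(vc$sigma2_eps * diag(solve(crossprod(X))))
  intercept <- f$coef[["const"]]
  beta <- f$coef[["x"]]
  fitted <- intercept + beta * ds$x
  if (blup) {
    shrink <- N * vc$sigma2_mu / (vc$sigma2_eps + N * vc$sigma2_mu)
    rbar <- gi$ybar - intercept - beta * gi$xbar
    fitted <- fitted + (shrink * rbar)[gi$idx]
  }
  new_panel_fit("re", ds,
    beta_hat = beta, se_beta = se_fgls[[2L]], intercept = intercept,
    theta = theta, sigma2_eps_hat = vc$sigma2_eps,
    sigma2_mu_hat = vc$sigma2_mu, fitted = fitted,
    sigma2_hat = f$sigma2, dof = n - 2L
  )
}

#' Within-between (Mundlak correlated random effects) estimator
#'
#' Random-effects FGLS applied to the augmented specification
#' \deqn{y_{jn} = \alpha + \beta (x_{jn} - \bar x_j) + \gamma \bar x_j +
#' \mu_j + \epsilon_{jn}.}
#' Including the group mean makes the remaining regressors independent of
#' the group effect, so `beta_hat` (the within effect) is unbiased at any
#' correlation between effect and covariate, while `gamma_hat` additionally
#' measures the between-group effect of `x`.
#'
#' `group_means` controls what \eqn{\bar x_j} is:
#'
#' * `"empirical"` (default): the observed group means — the only option on
#'   real data. The demeaned regressor is then exactly orthogonal to the
#'   group-level columns on a balanced panel, so `beta_hat` equals the
#'   fixed-effects slope to machine precision.
#' * `"latent"`: the generator's between-group component `x_between`
#'   retained in a simulated dataset. The sample group means of the
#'   within deviations no longer vanish, so `beta_hat` differs from the FE
#'   slope in finite samples (while remaining unbiased) and is typically
#'   more precise in small samples with strong between-group variation;
#'   this is the variant whose finite-sample WB-FE differences the
#'   simulation experiment quantifies.
#'
#' With `mundlak_variant = TRUE` the regressors are the undemeaned `x` and
#' \eqn{\bar x_j}. In that parameterisation the raw coefficient on
#' \eqn{\bar x_j} is the difference between the between and within effects,
#' so the reported `gamma_hat` adds the two raw coefficients back together;
#' both parameterisations report the same (within, between) pair.
#'
#' Standard errors use the FGLS covariance at the estimated components, as
#' in [fit_re_fgls()].
#'
#' @inheritParams fit_re_fgls
#' @param mundlak_variant Use the undemeaned-`x` parameterisation.
#' @param group_means `"empirical"` or `"latent"` (see Details).
#' @return A `panel_fit` with `beta_hat` (within effect), `gamma_hat`
#'   (between effect), `theta` and variance components.
#' @family estimators
#' @export
fit_wb <- function(ds, mundlak_variant = FALSE, blup = FALSE,
                   group_means = c("empirical", "latent")) {
  group_means <- match.arg(group_means)
  gi <- panel_groups(ds)
  if (group_means == "latent") {
    if (is.null(ds[["x_between"]])) {
      stop("group_means = \"latent\" needs the x_between column that ",
           "generate_dataset() retains", call. = FALSE)
    }
    xb <- ds[["x_between"]]
  } else {
    xb <- gi$xbar[gi$idx]
  }
  xd <- ds$x - xb
  wd <- ds$x - gi$xbar[gi$idx]  # empirical within deviation
  if (sum(wd^2) <= 1e-12 * max(1, sum(ds$x^2))) {
    stop("no within-group variation in x: within effect inestimable",
         call. = FALSE)
  }
  if (stats::var(xb) <= 1e-12 * max(1, mean(xb^2))) {
    stop("no between-group variation in x: between effect inestimable",
         call. = FALSE)
  }
  vc <- estimate_variance_components(ds)
  N <- gi$cnt[[1L]]
  theta <- 1 - sqrt(vc$sigma2_eps / (vc$sigma2_eps + N * vc$sigma2_mu))
  ystar <- ds$y - theta * gi$ybar[gi$idx]
  n <- nrow(ds)
  gmean <- function(v) (rowsum(v, gi$idx, reorder = FALSE)[, 1L] /
                          gi$cnt)[gi$idx]
  if (!mundlak_variant) {
    X <- cbind(const = 1 - theta, xd = xd - theta * gmean(xd),
               xb = xb - theta * gmean(xb))
    f <- ols_fit(X, ystar, dof = n - 3L)
    se_fgls <- sqrt(vc$sigma2_eps * diag(solve(crossprod(X))))
    beta <- f$coef[["xd"]]
    gamma <- f$coef[["xb"]]
    se_beta <- se_fgls[[2L]]
    se_gamma <- se_fgls[[3L]]
  } else {
    X <- cbind(const = 1 - theta, x = ds$x - theta * gi$xbar[gi$idx],
               xb = xb - theta * gmean(xb))
    f <- ols_fit(X, ystar, dof = n - 3L)
    se_fgls <- sqrt(vc$sigma2_eps * diag(solve(crossprod(X))))
    beta <- f$coef[["x"]]                    # within effect
    gamma <- f$coef[["x"]] + f$coef[["xb"]]  # between = within + raw xb coef
    se_beta <- se_fgls[[2L]]
    se_gamma <- NA_real_  # covariance of the two raw coefficients not kept
  }
  intercept <- f$coef[["const"]]
  fitted <- intercept + beta * xd + gamma * xb
  if (mundlak_variant) fitted <- intercept + beta * ds$x +
      (gamma - beta) * xb
  if (blup) {
    shrink <- N * vc$sigma2_mu / (vc$sigma2_eps + N * vc$sigma2_mu)
    rbar_g <- rowsum(ds$y - fitted, gi$idx, reorder = FALSE)[, 1L] / gi$cnt
    fitted <- fitted + (shrink * rbar_g)[gi$idx]
  }
  new_panel_fit("wb", ds,
    beta_hat = beta, se_beta = se_beta, gamma_hat = gamma,
    se_gamma = se_gamma, intercept = intercept, theta = theta,
    sigma2_eps_hat = vc$sigma2_eps, sigma2_mu_hat = vc$sigma2_mu,
    fitted = fitted, sigma2_hat = f$sigma2, dof = n - 3L
  )
}

#' Hausman specification test
#'
#' Compares the fixed-effects and random-effects slopes. Under the null both
#' estimators are consistent (RE additionally efficient), so
#' \deqn{H = \frac{(\hat\beta_{FE} - \hat\beta_{RE})^2}
#' {se^2_{FE} - se^2_{RE}} \sim \chi^2_1.}
#' Failing to reject at level `alpha` conventionally licenses the efficient
#' RE estimator. With a single slope the scalar form above is exact. When
#' the variance difference is non-positive (possible in finite samples) the
#' test is degenerate; the result is flagged and mapped deterministically to
#' fail-to-reject, i.e. `recommend_re = TRUE`.
#'
#' @param fe A `panel_fit` from [fit_fe_within()].
#' @param re A `panel_fit` from [fit_re_fgls()].
#' @param alpha Significance level (default 0.1).
#' @return A one-row tibble of class `hausman_result` with columns
#'   `statistic`, `p_value`, `recommend_re`, `alpha`, `degenerate`.
#' @export
hausman_test <- function(fe, re, alpha = 0.1) {
  stopifnot(inherits(fe, "panel_fit"), inherits(re, "panel_fit"))
  if (fe$n != re$n || abs(fe$y_checksum - re$y_checksum) >
      1e-8 * max(1, abs(fe$y_checksum))) {
    stop("fe and re fits come from different datasets", call. = FALSE)
  }
  vdiff <- fe$se_beta^2 - re$se_beta^2
  diff <- fe$beta_hat - re$beta_hat
  if (vdiff <= 0) {
    out <- tibble::tibble(statistic = 0, p_value = 1, recommend_re = TRUE,
                          alpha = alpha, degenerate = TRUE)
  } else {
    H <- diff^2 / vdiff
    p <- stats::pchisq(H, df = 1, lower.tail = FALSE)
    out <- tibble::tibble(statistic = H, p_value = p,
                          recommend_re = p > alpha, alpha = alpha,
                          degenerate = FALSE)
  }
  class(out) <- c("hausman_result", class(out))
  out
}

# Methods ---------------------------------------------------------------------

#' @export
print.panel_fit <- function(x, ...) {
  cat("<panel_fit> ", x$estimator, "\n", sep = "")
  cat(sprintf("  beta_hat = %.6g (se %.3g)\n", x$beta_hat, x$se_beta))
  if (!is.null(x$gamma_hat)) {
    cat(sprintf("  gamma_hat = %.6g\n", x$gamma_hat))
  }
  if (!is.null(x$theta)) cat(sprintf("  theta = %.4f\n", x$theta))
  cat(sprintf("  n = %d, dof = %d\n", x$n, x$dof))
  invisible(x)
}

#' Tidy a panel estimator fit
#'
#' @param x A `panel_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`,
#'   `std.error`).
#' @method tidy panel_fit
#' @export
tidy.panel_fit <- function(x, ...) {
  terms <- tibble::tibble(term = "x", estimate = x$beta_hat,
                          std.error = x$se_beta)
  if (!is.null(x$gamma_hat)) {
    terms <- dplyr::bind_rows(
      tibble::tibble(term = "x_demeaned", estimate = x$beta_hat,
                     std.error = x$se_beta),
      tibble::tibble(term = "x_group_mean", estimate = x$gamma_hat,
                     std.error = x$se_gamma %||% NA_real_)
    )
  }
  if (!is.null(x$intercept)) {
    terms <- dplyr::bind_rows(
      tibble::tibble(term = "(Intercept)", estimate = x$intercept,
                     std.error = NA_real_),
      terms
    )
  }
  terms |> dplyr::mutate(estimator = x$estimator, .before = 1L)
}

#' One-row summary of a panel estimator fit
#'
#' @inheritParams tidy.panel_fit
#' @return A one-row tibble with the slope, its standard error, the
#'   quasi-demeaning weight and variance components where defined, the
#'   LSDV R-squared where computed, and the degrees of freedom.
#' @method glance panel_fit
#' @export
glance.panel_fit <- function(x, ...) {
  tibble::tibble(
    estimator = x$estimator,
    beta_hat = x$beta_hat,
    se_beta = x$se_beta,
    gamma_hat = x$gamma_hat %||% NA_real_,
    theta = x$theta %||% NA_real_,
    sigma2_eps_hat = x$sigma2_eps_hat %||% NA_real_,
    sigma2_mu_hat = x$sigma2_mu_hat %||% NA_real_,
    r_squared = x$r_squared %||% NA_real_,
    dof = x$dof,
    n = x$n
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang %||% .data
NULL
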