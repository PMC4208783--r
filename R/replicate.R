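# Internal fast path used by run_scenario(): one draw + all four fits with
# shared group means and closed-form OLS. Consumes the RNG in exactly the
# same order as generate_dataset(), and reproduces the public estimator
# functions bit-for-bit (asserted in the test suite); it exists purely to
# avoid re-deriving group means and variance components once per estimator
# inside the hot replicate loop.

# Draw one panel as plain vectors (RNG order: group level, then observation
# level, as in generate_dataset()).
generate_panel_core <- function(cfg, sigma2_eps) {
  S <- group_level_covariance(cfg)
  c_ <- S[1, 2]
  b <- S[2, 2]
  z <- matrix(stats::rnorm(2L * cfg$J), ncol = 2L)
  mu_g <- z[, 1L]
  xbar_g <- c_ * z[, 1L] + sqrt(max(b - c_^2, 0)) * z[, 2L]
  obs <- draw_observation_level(cfg, sigma2_eps)
  idx <- rep(seq_len(cfg$J), each = cfg$N)
  x <- xbar_g[idx] + obs$w
  y <- cfg$beta * x + mu_g[idx] + obs$eps
  list(x = x, y = y, mu_g = mu_g, xbar_g = xbar_g, w = obs$w,
       eps = obs$eps, idx = idx)
}

# All four estimators + Hausman on one draw; returns a flat named list.
# When the latent components (w, xbar_latent) are supplied, the WB fit uses
# them as regressors (the latent-means variant run_scenario tracks);
# otherwise it uses empirical group means and its slope equals the FE slope
# exactly on these balanced panels.
fit_replicate <- function(x, y, J, N, alpha = 0.1, w = NULL,
                          xbar_latent = NULL) {
  n <- J * N
  xbar_g <- .colMeans(matrix(x, nrow = N), N, J)
  ybar_g <- .colMeans(matrix(y, nrow = N), N, J)
  xbar <- rep(xbar_g, each = N)
  ybar <- rep(ybar_g, each = N)

  # within (FE)
  xd <- x - xbar
  yd <- y - ybar
  sxx_w <- sum(xd^2)
  sxy_w <- sum(xd * yd)
  beta_fe <- sxy_w / sxx_w
  ssr_w <- sum((yd - beta_fe * xd)^2)
  sigma2_eps <- ssr_w / (n - J - 1)
  se2_fe <- sigma2_eps / sxx_w
  rmse_fe <- sqrt(ssr_w / n)

  # between regression -> variance components (Swamy-Arora-type)
  mxb <- mean(xbar_g)
  myb <- mean(ybar_g)
  sxx_b <- sum((xbar_g - mxb)^2)
  bb <- sum((xbar_g - mxb) * (ybar_g - myb)) / sxx_b
  ssr_b <- sum((ybar_g - myb - bb * (xbar_g - mxb))^2)
  sigma2_mu <- max(0, ssr_b / (J - 2) - sigma2_eps / N)

  # RE via FGLS quasi-demeaning
  theta <- 1 - sqrt(sigma2_eps / (sigma2_eps + N * sigma2_mu))
  c0 <- 1 - theta
  ystar <- y - theta * ybar
  xstar <- x - theta * xbar
  s11 <- n * c0^2
  s12 <- c0 * sum(xstar)
  s22 <- sum(xstar^2)
  t1 <- c0 * sum(ystar)
  t2 <- sum(xstar * ystar)
  det_re <- s11 * s22 - s12^2
  beta_re <- (s11 * t2 - s12 * t1) / det_re
  a_re <- (s22 * t1 - s12 * t2) / det_re
  # FGLS covariance at the estimated components (not transformed-SSR based)
  se2_re <- sigma2_eps * s11 / det_re
  rmse_re <- sqrt(mean((y - a_re - beta_re * x)^2))

  # WB. Empirical demeaning: the deviation column is orthogonal to the
  # group-level columns, so the within coefficient is exactly the FE slope
  # and the (const, xbar) block solves separately. Latent components: full
  # 3x3 GLS solve on (const, w, xbar_latent).
  if (is.null(w)) {
    beta_wb <- sxy_w / sxx_w
    u3 <- c0 * xbar
    v11 <- s11
    v13 <- c0 * sum(u3)
    v33 <- sum(u3^2)
    w1 <- c0 * sum(ystar)
    w3 <- sum(u3 * ystar)
    det_wb <- v11 * v33 - v13^2
    a_wb <- (v33 * w1 - v13 * w3) / det_wb
    g_wb <- (v11 * w3 - v13 * w1) / det_wb
    se2_beta_wb <- sigma2_eps / sxx_w
    fit_wb_vals <- a_wb + beta_wb * xd + g_wb * xbar
  } else {
    wbar <- rep(.colMeans(matrix(w, nrow = N), N, J), each = N)
    xbl <- rep(xbar_latent, each = N)
    X <- cbind(c0, w - theta * wbar, c0 * xbl)
    XtX <- crossprod(X)
    bvec <- solve(XtX, crossprod(X, ystar))
    a_wb <- bvec[1L]
    beta_wb <- bvec[2L]
    g_wb <- bvec[3L]
    se2_beta_wb <- sigma2_eps * solve(XtX)[2L, 2L]
    fit_wb_vals <- a_wb + beta_wb * w + g_wb * xbl
  }
  rmse_wb <- sqrt(mean((y - fit_wb_vals)^2))

  # pooled OLS
  mx <- mean(x)
  my <- mean(y)
  sxx_p <- sum((x - mx)^2)
  beta_po <- sum((x - mx) * (y - my)) / sxx_p
  a_po <- my - beta_po * mx
  res_po <- y - a_po - beta_po * x
  rmse_po <- sqrt(mean(res_po^2))

  # Hausman (scalar form)
  vdiff <- se2_fe - se2_re
  if (vdiff <= 0) {
    h_stat <- 0
    h_p <- 1
    h_degenerate <- TRUE
    recommend_re <- TRUE
  } else {
    h_stat <- (beta_fe - beta_re)^2 / vdiff
    h_p <- stats::pchisq(h_stat, df = 1, lower.tail = FALSE)
    h_degenerate <- FALSE
    recommend_re <- h_p > alpha
  }

  tss_y <- sum((y - my)^2)
  list(
    beta_re = beta_re, beta_fe = beta_fe, beta_wb = beta_wb,
    beta_pooled = beta_po, gamma_wb = g_wb,
    se2_re = se2_re, se2_fe = se2_fe, se2_beta_wb = se2_beta_wb,
    theta = theta, sigma2_eps = sigma2_eps, sigma2_mu = sigma2_mu,
    rmse_re = rmse_re, rmse_fe = rmse_fe, rmse_wb = rmse_wb,
    rmse_pooled = rmse_po,
    hausman_stat = h_stat, hausman_p = h_p, recommend_re = recommend_re,
    hausman_degenerate = h_degenerate,
    lsdv_r2 = if (tss_y > 0) 1 - ssr_w / tss_y else NA_real_
  )
}
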