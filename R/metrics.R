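#' Coefficient error of a fitted estimator
#'
#' @param result A `panel_fit` (or anything with `beta_hat`).
#' @param beta_true True marginal effect.
#' @return \eqn{\hat\beta - \beta}.
#' @export
coefficient_error <- function(result, beta_true) {
  result$beta_hat - beta_true
}

#' Root mean squared error of predicted outcomes
#'
#' @param fitted,y Numeric vectors of equal length.
#' @return \eqn{\sqrt{\mathrm{mean}((\hat y - y)^2)}}.
#' @export
prediction_rmse <- function(fitted, y) {
  if (length(fitted) != length(y)) {
    stop("fitted and y must have equal length", call. = FALSE)
  }
  sqrt(mean((fitted - y)^2))
}

#' Mean squared error of a vector of coefficient errors
#'
#' Uses the population form, so the decomposition
#' `mse == mean(errors)^2 + uncorrected variance` holds exactly: the MSE
#' penalises bias and imprecision jointly.
#'
#' @param errors Nonempty numeric vector.
#' @return Mean of the squared errors.
#' @export
mse <- function(errors) {
  if (length(errors) == 0L) stop("empty error vector", call. = FALSE)
  mean(errors^2)
}

#' MSE-based preference between the RE and FE estimators
#'
#' Differences of at most `trivial_threshold` (default 0.005) are declared
#' trivial; otherwise the estimator with the smaller MSE is preferred.
#'
#' @param mse_re,mse_fe Scenario-level MSEs.
#' @param trivial_threshold Absolute MSE difference below which the choice
#'   is immaterial.
#' @return `"RE"`, `"FE"`, or `"trivial"`.
#' @export
#' @examples
#' mse_preference(0.010, 0.013) # "trivial"
mse_preference <- function(mse_re, mse_fe, trivial_threshold = 0.005) {
  dplyr::case_when(
    abs(mse_re - mse_fe) <= trivial_threshold ~ "trivial",
    mse_re < mse_fe ~ "RE",
    .default = "FE"
  )
}

#' Share of replicates where the Hausman test picks the better estimator
#'
#' "Better" means the smaller absolute coefficient error between the
#' traditional RE and FE fits of the same replicate; ties count as
#' agreement (they are probability-zero events, the rule only fixes
#' determinism).
#'
#' @param records A data frame of replicate records with columns
#'   `abs_err_re`, `abs_err_fe`, and logical `recommend_re`.
#' @return The agreement share in `[0, 1]`.
#' @export
hausman_agreement <- function(records) {
  if (nrow(records) == 0L) stop("no replicate records", call. = FALSE)
  agree <- ifelse(records$recommend_re,
                  records$abs_err_re <= records$abs_err_fe,
                  records$abs_err_fe <= records$abs_err_re)
  mean(agree)
}

#' Finite-sample MSE gap between the WB and FE estimators
#'
#' @param mse_wb,mse_fe Scenario-level MSEs.
#' @param threshold Gap beyond which one estimator is called worse
#'   (default 0.01).
#' @return A one-row tibble with `gap` (`mse_wb - mse_fe`), `fe_worse`, and
#'   `wb_worse`.
#' @export
wb_fe_mse_gap <- function(mse_wb, mse_fe, threshold = 0.01) {
  tibble::tibble(
    gap = mse_wb - mse_fe,
    fe_worse = (mse_fe - mse_wb) > threshold,
    wb_worse = (mse_wb - mse_fe) > threshold
  )
}

#' Correlation between the WB-FE MSE gap and the design dimensions
#'
#' Pearson pairwise correlations between the per-scenario gap
#' `mse_wb - mse_fe` and each design dimension, over scenarios with fewer
#' than `obs_cap` observations (`J * N < obs_cap`). Dimensions that are
#' constant in the qualifying subset are flagged `computable = FALSE`.
#'
#' @param summaries A scenario-summary tibble (see [run_grid()]) with
#'   columns `J`, `N`, `rho`, `sigma2_x`, `tau`, `psi`, `pi`, `mse_wb`,
#'   `mse_fe`.
#' @param obs_cap Only scenarios with `J * N` strictly below this enter.
#' @return A tibble with one row per dimension: `dimension`, `correlation`,
#'   `p_value`, `significant_at_99`, `computable`, `n_scenarios`.
#' @export
mse_gap_correlations <- function(summaries, obs_cap = 500L) {
  sub <- dplyr::filter(summaries, .data$J * .data$N < obs_cap)
  if (nrow(sub) < 3L) {
    stop("fewer than 3 scenarios with J*N < obs_cap", call. = FALSE)
  }
  gap <- sub$mse_wb - sub$mse_fe
  dims <- c("J", "N", "rho", "sigma2_x", "tau", "psi", "pi")
  purrr::map_dfr(dims, function(d) {
    v <- sub[[d]]
    if (stats::sd(v) == 0 || stats::sd(gap) == 0) {
      return(tibble::tibble(dimension = d, correlation = NA_real_,
                            p_value = NA_real_, significant_at_99 = NA,
                            computable = FALSE, n_scenarios = nrow(sub)))
    }
    ct <- stats::cor.test(gap, v, method = "pearson")
    tibble::tibble(dimension = d,
                   correlation = unname(ct$estimate),
                   p_value = ct$p.value,
                   significant_at_99 = ct$p.value < 0.01,
                   computable = TRUE, n_scenarios = nrow(sub))
  })
}
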