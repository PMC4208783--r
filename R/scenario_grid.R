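#' Dimension specification for the simulation grid
#'
#' Defines the values each design dimension of the clustered-data simulation
#' takes. The default values reproduce the full factorial experiment: three
#' group counts, three group sizes, eight correlations between the group
#' effect and the covariate, three covariate variances, five within-group
#' variance shares, five residual variance shares, and three model
#' (mis)specification conditions (correct, endogenous covariate with
#' \eqn{\psi = 0.2}, AR(1) residual with \eqn{\upsilon = 0.2}), for a total of
#' 16,200 scenarios.
#'
#' The endogeneity and autocorrelation dimensions are deliberately *not*
#' fully crossed with each other: misspecification is introduced one at a
#' time, so the conditions are \eqn{(\psi, \upsilon) \in \{(0,0), (0.2,0),
#' (0,0.2)\}} (optionally extended via `psi_values` / `upsilon_values`).
#'
#' @param J_values Positive integers; number of groups.
#' @param N_values Positive integers; observations per group (balanced).
#' @param rho_values Reals in `[0, 1)`; correlation between the group effect
#'   \eqn{\mu_j} and the covariate \eqn{x}.
#' @param sigma2_x_values Positive reals; total covariate variance
#'   \eqn{\sigma^2_x}.
#' @param tau_values Reals in `(0, 1)`; share of \eqn{\sigma^2_x} that lies
#'   within groups.
#' @param pi_values Reals in `(0, 1)`; share of the outcome variance due to
#'   the residual.
#' @param psi_values Reals in `[0, 1)`; contemporaneous correlation between
#'   the within-group covariate deviation and the residual (endogeneity).
#'   Nonzero values each define one misspecification condition.
#' @param upsilon_values Reals in `[0, 1)`; AR(1) coefficient of the
#'   within-group residual. Nonzero values each define one misspecification
#'   condition.
#' @param beta True marginal effect of `x` on `y` (default 1).
#'
#' @return An object of class `dimension_spec` (a named list).
#' @seealso [enumerate_scenarios()], [read_dimension_spec()]
#' @export
#' @examples
#' spec <- dimension_spec()
#' nrow(enumerate_scenarios(spec)) # 16200
dimension_spec <- function(J_values = c(10L, 50L, 100L),
                           N_values = c(5L, 10L, 50L),
                           rho_values = (0:7) / 10,
                           sigma2_x_values = c(0.5, 1, 2),
                           tau_values = c(0.10, 0.25, 0.50, 0.75, 0.90),
                           pi_values = c(0.10, 0.25, 0.50, 0.75, 0.90),
                           psi_values = c(0, 0.2),
                           upsilon_values = c(0, 0.2),
                           beta = 1) {
  spec <- list(
    J_values = as.integer(J_values),
    N_values = as.integer(N_values),
    rho_values = as.numeric(rho_values),
    sigma2_x_values = as.numeric(sigma2_x_values),
    tau_values = as.numeric(tau_values),
    pi_values = as.numeric(pi_values),
    psi_values = as.numeric(psi_values),
    upsilon_values = as.numeric(upsilon_values),
    beta = as.numeric(beta)
  )
  validate_dimension_spec(spec)
  structure(spec, class = "dimension_spec")
}

validate_dimension_spec <- function(spec) {
  chk <- function(ok, what) {
    if (!ok) stop("invalid dimension spec: ", what, call. = FALSE)
  }
  for (f in c("J_values", "N_values", "rho_values", "sigma2_x_values",
              "tau_values", "pi_values", "psi_values", "upsilon_values")) {
    chk(length(spec[[f]]) >= 1L, paste0(f, " is empty"))
    chk(!anyNA(spec[[f]]), paste0(f, " contains NA"))
  }
  chk(all(spec$J_values >= 1L), "J_values must be positive integers")
  chk(all(spec$N_values >= 1L), "N_values must be positive integers")
  chk(all(spec$rho_values >= 0 & spec$rho_values < 1),
      "rho_values must lie in [0, 1)")
  chk(all(spec$sigma2_x_values > 0), "sigma2_x_values must be positive")
  chk(all(spec$tau_values > 0 & spec$tau_values < 1),
      "tau_values must lie in (0, 1)")
  chk(all(spec$pi_values > 0 & spec$pi_values < 1),
      "pi_values must lie in (0, 1)")
  chk(all(spec$psi_values >= 0 & spec$psi_values < 1),
      "psi_values must lie in [0, 1)")
  chk(all(spec$upsilon_values >= 0 & spec$upsilon_values < 1),
      "upsilon_values must lie in [0, 1)")
  chk(length(spec$beta) == 1L && is.finite(spec$beta), "beta must be scalar")
  invisible(spec)
}

#' Read a dimension specification from a YAML file
#'
#' The file holds one entry per dimension, named exactly as the arguments of
#' [dimension_spec()] (e.g. `J_values: [10, 50]`). Omitted entries fall back
#' to the full-grid defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A `dimension_spec` object.
#' @export
read_dimension_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(dimension_spec))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad) > 0) {
    stop("unknown dimension spec fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(dimension_spec, cfg)
}

#' Enumerate the scenario grid
#'
#' Expands a [dimension_spec()] into the full table of simulation scenarios.
#' Misspecification is one-at-a-time: the baseline condition
#' (\eqn{\psi = \upsilon = 0}) is crossed with every combination of the other
#' dimensions, and each nonzero \eqn{\psi} or \eqn{\upsilon} value defines a
#' further condition, again crossed with the other dimensions. Enumeration
#' order is deterministic: the misspecification condition varies slowest,
#' then `J`, `N`, `rho`, `sigma2_x`, `tau`, and `pi` fastest; `scenario_id`
#' is the row number in this order.
#'
#' Scenarios for which no data-generating process exists (the group-level
#' covariance of \eqn{(\mu_j, \bar x_j)} would not be positive semi-definite,
#' i.e. \eqn{\rho > \sqrt{1 - \tau}}) are included but flagged via the
#' `feasible` column so that grid-level counts and feasibility coverage can
#' be reported.
#'
#' @param spec A `dimension_spec`.
#' @return A tibble with one row per scenario: `scenario_id`, `condition`
#'   (`"baseline"`, `"psi"`, or `"upsilon"`), `J`, `N`, `rho`, `sigma2_x`,
#'   `tau`, `pi`, `psi`, `upsilon`, `beta`, `feasible`, `rho_max`.
#' @export
#' @examples
#' enumerate_scenarios(dimension_spec(J_values = 10, N_values = 5,
#'   rho_values = c(0, 0.3), sigma2_x_values = 1, tau_values = 0.5,
#'   pi_values = 0.5))
enumerate_scenarios <- function(spec) {
  if (!inherits(spec, "dimension_spec")) {
    spec <- do.call(dimension_spec, as.list(spec))
  }
  validate_dimension_spec(spec)

  psi_on <- setdiff(unique(spec$psi_values), 0)
  ups_on <- setdiff(unique(spec$upsilon_values), 0)
  conditions <- dplyr::bind_rows(
    tibble::tibble(condition = "baseline", psi = 0, upsilon = 0),
    tibble::tibble(condition = "psi", psi = psi_on,
                   upsilon = rep(0, length(psi_on))),
    tibble::tibble(condition = "upsilon", psi = rep(0, length(ups_on)),
                   upsilon = ups_on)
  )

  grid <- tidyr::expand_grid(
    conditions,
    J = spec$J_values,
    N = spec$N_values,
    rho = spec$rho_values,
    sigma2_x = spec$sigma2_x_values,
    tau = spec$tau_values,
    pi = spec$pi_values
  )
  grid |>
    dplyr::mutate(
      beta = spec$beta,
      scenario_id = dplyr::row_number(),
      rho_max = sqrt(1 - .data$tau),
      feasible = .data$rho <= .data$rho_max + 1e-12
    ) |>
    dplyr::select("scenario_id", "condition", "J", "N", "rho", "sigma2_x",
                  "tau", "pi", "psi", "upsilon", "beta", "feasible",
                  "rho_max")
}

#' Feasibility of one scenario
#'
#' A scenario is feasible when the 2x2 covariance matrix of the group effect
#' and the group-mean covariate, `[[1, rho * sigma_x], [rho * sigma_x,
#' (1 - tau) * sigma2_x]]`, is positive semi-definite. This reduces to
#' \eqn{\rho \le \sqrt{1 - \tau}}, independently of `J`, `N`, `sigma2_x`,
#' `pi`, `psi` and `upsilon`.
#'
#' @param cfg A scenario: a one-row data frame (or list) with at least `rho`
#'   and `tau`.
#' @return A tibble with columns `feasible` (logical) and `rho_max`
#'   (\eqn{\sqrt{1-\tau}}).
#' @export
#' @examples
#' check_feasibility(list(rho = 0.7, tau = 0.9)) # infeasible, rho_max 0.316
check_feasibility <- function(cfg) {
  cfg <- as.list(cfg)
  rho_max <- sqrt(1 - cfg$tau)
  tibble::tibble(feasible = cfg$rho <= rho_max + 1e-12, rho_max = rho_max)
}

# Coerce a one-row scenario (tibble row, list, ...) to a validated plain list.
as_scenario <- function(cfg) {
  cfg <- as.list(cfg)
  needed <- c("J", "N", "rho", "sigma2_x", "tau", "pi", "psi", "upsilon",
              "beta")
  missing <- setdiff(needed, names(cfg))
  if (length(missing) > 0) {
    stop("scenario is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$scenario_id)) cfg$scenario_id <- NA_integer_
  if (cfg$psi != 0 && cfg$upsilon != 0) {
    stop("at most one of psi and upsilon may be nonzero", call. = FALSE)
  }
  cfg
}
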