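# Deterministic per-scenario substream seed. Lehmer-style hash of the master
# seed and the scenario id, kept inside the 32-bit range set.seed() accepts.
scenario_seed <- function(master_seed, scenario_id) {
  m <- 2147483647 # 2^31 - 1
  s <- ((master_seed %% m) * 48271 + (scenario_id %% m) * 16807) %% m
  as.integer(if (s == 0) 1 else s)
}

#' Run all replicates of one scenario
#'
#' Generates `replicates` datasets for the scenario, fits the RE (FGLS),
#' FE (within), WB and pooled estimators to each, runs the Hausman test at
#' level `alpha`, and aggregates coefficient-error distributions, MSEs,
#' prediction RMSEs, Hausman shares and the RE-vs-FE preference label.
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' The per-replicate LSDV goodness of fit is computed from the within
#' regression via the residual identity (LSDV and within residuals
#' coincide), avoiding a dummy-variable refit per replicate.
#'
#' The WB columns track the latent-means variant of [fit_wb()]: with
#' empirical demeaning the WB within slope coincides with the FE slope
#' exactly on these balanced panels, so only the latent variant exhibits
#' the finite-sample WB-FE differences the experiment is designed to
#' measure (see the methods vignette).
#'
#' @param cfg A feasible scenario row (see [enumerate_scenarios()]).
#' @param replicates Number of simulated datasets.
#' @param seed Optional integer seed for this scenario's substream.
#' @param alpha Hausman test level.
#' @param keep_records Attach the replicate-level table as attribute
#'   `"records"`.
#' @return A one-row tibble (the scenario summary).
#' @export
run_scenario <- function(cfg, replicates = 1000L, seed = NULL, alpha = 0.1,
                         keep_records = FALSE) {
  cfg <- as_scenario(cfg)
  stopifnot(replicates >= 1L)
  feas <- check_feasibility(cfg)
  if (!feas$feasible) {
    stop(sprintf("infeasible scenario: rho = %.3f > rho_max = %.4f",
                 cfg$rho, feas$rho_max), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  ests <- c("re", "fe", "wb", "pooled")
  err <- matrix(NA_real_, replicates, 4L, dimnames = list(NULL, ests))
  rmse <- err
  recommend_re <- logical(replicates)
  degenerate <- logical(replicates)
  lsdv_r2 <- numeric(replicates)

  sigma2_eps <- residual_scale(cfg)
  for (r in seq_len(replicates)) {
    core <- generate_panel_core(cfg, sigma2_eps)
    f <- fit_replicate(core$x, core$y, cfg$J, cfg$N, alpha = alpha,
                       w = core$w, xbar_latent = core$xbar_g)
    err[r, ] <- c(f$beta_re, f$beta_fe, f$beta_wb, f$beta_pooled) - cfg$beta
    rmse[r, ] <- c(f$rmse_re, f$rmse_fe, f$rmse_wb, f$rmse_pooled)
    recommend_re[r] <- f$recommend_re
    degenerate[r] <- f$hausman_degenerate
    lsdv_r2[r] <- f$lsdv_r2
  }

  q <- function(v, p) unname(stats::quantile(v, p, type = 7))
  per_est <- purrr::map(ests, function(e) {
    stats::setNames(
      list(mean(err[, e]), q(err[, e], 0.025), q(err[, e], 0.975),
           mse(err[, e]), mean(rmse[, e]), q(rmse[, e], 0.025),
           q(rmse[, e], 0.975)),
      paste0(c("mean_err_", "err_p025_", "err_p975_", "mse_", "mean_rmse_",
               "rmse_p025_", "rmse_p975_"), e)
    )
  })
  abs_re <- abs(err[, "re"])
  abs_fe <- abs(err[, "fe"])
  agree <- ifelse(recommend_re, abs_re <= abs_fe, abs_fe <= abs_re)
  mse_re <- mse(err[, "re"])
  mse_fe <- mse(err[, "fe"])
  mse_wb <- mse(err[, "wb"])

  out <- tibble::as_tibble(c(
    list(scenario_id = cfg$scenario_id, n_replicates = replicates),
    purrr::flatten(per_est),
    list(
      hausman_fail_to_reject_share = mean(recommend_re),
      hausman_better_share = mean(agree),
      hausman_degenerate_share = mean(degenerate),
      re_smaller_abs_err_share = mean(abs_re < abs_fe),
      preference_label = mse_preference(mse_re, mse_fe),
      wb_fe_mse_diff = mse_wb - mse_fe,
      mean_lsdv_r2 = mean(lsdv_r2)
    )
  ))
  if (keep_records) {
    attr(out, "records") <- tibble::tibble(
      scenario_id = cfg$scenario_id,
      replicate = seq_len(replicates),
      err_re = err[, "re"], err_fe = err[, "fe"], err_wb = err[, "wb"],
      err_pooled = err[, "pooled"],
      abs_err_re = abs_re, abs_err_fe = abs_fe,
      rmse_re = rmse[, "re"], rmse_fe = rmse[, "fe"],
      rmse_wb = rmse[, "wb"],
      recommend_re = recommend_re, degenerate = degenerate,
      lsdv_r2 = lsdv_r2
    )
  }
  out
}

#' Run replicated simulations over a scenario grid
#'
#' Executes [run_scenario()] for every feasible scenario in `scenarios`,
#' each on its own RNG substream derived from `master_seed` and the
#' scenario id, so results are deterministic regardless of worker count or
#' execution order, and any single cell can be reproduced in isolation.
#' Infeasible scenarios are recorded under `$skipped`, never raised
#' mid-grid; a scenario whose fit fails is likewise recorded with its error
#' message.
#'
#' With `checkpoint_dir` set, each completed scenario summary is written to
#' disk and re-running the same plan skips completed cells.
#'
#' @param scenarios A scenario tibble from [enumerate_scenarios()]
#'   (optionally pre-filtered), or a `dimension_spec` to enumerate.
#' @param replicates Replicates per scenario.
#' @param master_seed Integer master seed.
#' @param scenario_filter Optional predicate taking the scenario tibble and
#'   returning a logical vector (applied before running).
#' @param workers Parallel workers (forked via the parallel package when
#'   available; results are identical for any value).
#' @param keep_records Keep the replicate-level table (needed for pooled
#'   medians in [summarize_rules_of_thumb()]).
#' @param alpha Hausman test level.
#' @param checkpoint_dir Optional directory for per-scenario checkpoints.
#' @param verbose Emit a progress line per completed scenario.
#' @return A list of class `grid_results`: `summaries` (scenario summaries
#'   joined to the design columns), `records` (replicate-level tibble or
#'   `NULL`), `skipped` (scenario ids with reasons), `provenance`.
#' @export
run_grid <- function(scenarios, replicates = 1000L, master_seed = 1L,
                     scenario_filter = NULL, workers = 1L,
                     keep_records = TRUE, alpha = 0.1,
                     checkpoint_dir = NULL, verbose = FALSE) {
  if (inherits(scenarios, "dimension_spec")) {
    scenarios <- enumerate_scenarios(scenarios)
  }
  if (!is.null(scenario_filter)) {
    scenarios <- scenarios[scenario_filter(scenarios), , drop = FALSE]
  }
  if (nrow(scenarios) == 0L) stop("empty scenario set", call. = FALSE)

  skipped <- scenarios |>
    dplyr::filter(!.data$feasible) |>
    dplyr::transmute(.data$scenario_id,
                     reason = sprintf("infeasible: rho %.2f > rho_max %.4f",
                                      .data$rho, .data$rho_max))
  todo <- dplyr::filter(scenarios, .data$feasible)

  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE)
  }
  ckpt_path <- function(id) {
    file.path(checkpoint_dir, sprintf("scenario_%06d.csv", id))
  }

  run_one <- function(i) {
    row <- todo[i, ]
    if (!is.null(checkpoint_dir) && file.exists(ckpt_path(row$scenario_id))) {
      s <- tibble::as_tibble(utils::read.csv(ckpt_path(row$scenario_id)))
      return(list(summary = s, records = NULL, error = NULL))
    }
    res <- tryCatch(
      run_scenario(row, replicates = replicates,
                   seed = scenario_seed(master_seed, row$scenario_id),
                   alpha = alpha, keep_records = keep_records),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      if (verbose) {
        message(sprintf("scenario %d: skipped (%s)", row$scenario_id,
                        conditionMessage(res)))
      }
      return(list(summary = NULL, records = NULL,
                  error = conditionMessage(res)))
    }
    if (verbose) {
      message(sprintf("scenario %d: %d replicates done", row$scenario_id,
                      replicates))
    }
    if (!is.null(checkpoint_dir)) {
      utils::write.csv(as.data.frame(res), ckpt_path(row$scenario_id),
                       row.names = FALSE)
    }
    list(summary = res, records = attr(res, "records"), error = NULL)
  }

  use_fork <- workers > 1L &&
    requireNamespace("parallel", quietly = TRUE) &&
    .Platform$OS.type == "unix"
  results <- if (use_fork) {
    parallel::mclapply(seq_len(nrow(todo)), run_one, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(todo)), run_one)
  }

  failed <- purrr::imap_dfr(results, function(r, i) {
    if (is.null(r$error)) return(tibble::tibble())
    tibble::tibble(scenario_id = todo$scenario_id[i], reason = r$error)
  })
  summaries <- purrr::map_dfr(results, function(r) {
    if (is.null(r$summary)) tibble::tibble() else {
      s <- r$summary
      attr(s, "records") <- NULL
      s
    }
  })
  records <- if (keep_records) {
    purrr::map_dfr(results, ~ .x$records %||% tibble::tibble())
  }
  if (nrow(summaries) > 0L) {
    summaries <- dplyr::inner_join(
      dplyr::select(scenarios, -"feasible", -"rho_max"),
      summaries, by = "scenario_id"
    )
  }
  structure(
    list(
      summaries = summaries,
      records = records,
      skipped = dplyr::bind_rows(skipped, failed),
      provenance = list(master_seed = master_seed, replicates = replicates,
                        alpha = alpha,
                        package_version = as.character(
                          utils::packageVersion("panelmc")))
    ),
    class = "grid_results"
  )
}

#' @export
print.grid_results <- function(x, ...) {
  cat("<grid_results>\n")
  cat(sprintf("  scenarios run: %d (skipped: %d)\n", nrow(x$summaries),
              nrow(x$skipped)))
  cat(sprintf("  replicates per scenario: %d, master seed: %s\n",
              x$provenance$replicates, format(x$provenance$master_seed)))
  if (!is.null(x$records)) {
    cat(sprintf("  replicate records kept: %d rows\n", nrow(x$records)))
  }
  invisible(x)
}

#' Write grid results to CSV
#'
#' One CSV of scenario summaries; optionally a second, much larger CSV of
#' replicate-level records.
#'
#' @param grid A `grid_results`.
#' @param dir Output directory (created if needed).
#' @param replicate_level Also write the replicate records, if kept.
#' @return `dir`, invisibly.
#' @export
write_grid_results <- function(grid, dir, replicate_level = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(grid$summaries),
                   file.path(dir, "scenario_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(grid$skipped),
                   file.path(dir, "skipped_scenarios.csv"),
                   row.names = FALSE)
  if (replicate_level && !is.null(grid$records)) {
    utils::write.csv(as.data.frame(grid$records),
                     file.path(dir, "replicate_records.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Rule-of-thumb statistics over a completed grid
#'
#' Aggregates the grid into the practical estimator-selection statistics:
#'
#' * `median_abs_err_fe_gt500`, `median_abs_err_re_gt500`: median absolute
#'   coefficient error of FE and RE, pooled over all replicates of
#'   scenarios with more than 500 observations (`J*N > 500`).
#' * `hausman_agreement_ge1000`: share of replicates where the Hausman
#'   recommendation matches the smaller-absolute-error estimator, over
#'   scenarios with `J*N >= 1000`.
#' * `re_smaller_share_lowr2_lt500`: share of replicates with
#'   `|RE error| < |FE error|` among scenarios with mean LSDV R-squared
#'   below 0.5 and `J*N < 500`.
#' * `re_smaller_share_lowtau_lt500`: the same share among scenarios with
#'   `J*N < 500` and within-variance share `tau < 0.20`.
#' * `fe_worse_share_lt500`, `wb_worse_share_lt500`: shares of scenarios
#'   with `J*N < 500` whose FE MSE exceeds the WB MSE by more than 0.01,
#'   and vice versa.
#' * `hausman_agreement_overall`: the Hausman agreement share over all
#'   feasible scenarios.
#'
#' Replicate-pooled shares are computed as means of per-scenario shares,
#' which coincides with pooling because every scenario carries the same
#' number of replicates. Pooled medians require the replicate records
#' (`keep_records = TRUE` in [run_grid()]); without them those rows are
#' `NA`. Infeasible cells never enter any denominator.
#'
#' By default the endogenous-covariate condition (`psi != 0`) is excluded:
#' under endogeneity no estimator is consistent (the within-deviation bias
#' \eqn{\psi\sigma_\epsilon/\sigma_W} dwarfs everything else at small
#' \eqn{\tau}), so error-magnitude rules of thumb are computed over designs
#' where the estimators estimate what they claim to. Pass all three
#' condition labels to override.
#'
#' @param grid A `grid_results`.
#' @param conditions Misspecification conditions to include (default
#'   `c("baseline", "upsilon")`, i.e. correctly specified mean structure).
#' @return A tibble with columns `statistic`, `value`, `n_scenarios`; shares
#'   and medians are proportions on the original scale (multiply by 100 for
#'   percent).
#' @export
summarize_rules_of_thumb <- function(grid,
                                     conditions = c("baseline", "upsilon")) {
  s <- dplyr::filter(grid$summaries, .data$condition %in% conditions)
  if (nrow(s) == 0L) stop("no scenarios in the requested conditions",
                          call. = FALSE)
  obs <- s$J * s$N
  rec <- grid$records
  stat <- function(statistic, value, n) {
    tibble::tibble(statistic = statistic, value = value, n_scenarios = n)
  }
  share <- function(v, keep) {
    if (!any(keep)) NA_real_ else mean(v[keep])
  }

  big <- obs > 500
  med_fe <- med_re <- NA_real_
  if (!is.null(rec) && any(big)) {
    rec_big <- dplyr::semi_join(rec,
                                dplyr::filter(s, obs > 500)["scenario_id"],
                                by = "scenario_id")
    med_fe <- stats::median(rec_big$abs_err_fe)
    med_re <- stats::median(rec_big$abs_err_re)
  }
  lt500 <- obs < 500

  dplyr::bind_rows(
    stat("median_abs_err_fe_gt500", med_fe, sum(big)),
    stat("median_abs_err_re_gt500", med_re, sum(big)),
    stat("hausman_agreement_ge1000",
         share(s$hausman_better_share, obs >= 1000), sum(obs >= 1000)),
    stat("re_smaller_share_lowr2_lt500",
         share(s$re_smaller_abs_err_share, lt500 & s$mean_lsdv_r2 < 0.5),
         sum(lt500 & s$mean_lsdv_r2 < 0.5)),
    stat("re_smaller_share_lowtau_lt500",
         share(s$re_smaller_abs_err_share, lt500 & s$tau < 0.20),
         sum(lt500 & s$tau < 0.20)),
    stat("fe_worse_share_lt500",
         share(-s$wb_fe_mse_diff > 0.01, lt500), sum(lt500)),
    stat("wb_worse_share_lt500",
         share(s$wb_fe_mse_diff > 0.01, lt500), sum(lt500)),
    stat("hausman_agreement_overall",
         mean(s$hausman_better_share), nrow(s))
  )
}
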