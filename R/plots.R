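# Long format of per-estimator summary columns for plotting.
summaries_long <- function(summaries, prefix) {
  summaries |>
    tidyr::pivot_longer(
      cols = tidyr::matches(paste0("^(", paste(prefix, collapse = "|"),
                                   ")_(re|fe|wb|pooled)$")),
      names_to = c(".value", "estimator"),
      names_pattern = "^(.*)_(re|fe|wb|pooled)$"
    ) |>
    dplyr::filter(.data$estimator %in% c("re", "fe", "wb")) |>
    dplyr::mutate(estimator = factor(toupper(.data$estimator),
                                     levels = c("RE", "FE", "WB")))
}

panel_facets <- function() {
  ggplot2::facet_grid(
    rows = ggplot2::vars(.data$J), cols = ggplot2::vars(.data$N),
    labeller = ggplot2::labeller(
      J = function(v) paste0("J = ", v), N = function(v) paste0("N = ", v)
    )
  )
}

est_colours <- c(RE = "#c23b22", FE = "#2b6ca3", WB = "#2e8b57")

#' Coefficient-error distributions across rho
#'
#' Mean coefficient error (solid) with the 2.5th-97.5th percentile band
#' (ribbon) for each estimator, against the effect-covariate correlation
#' `rho`, faceted by group count `J` and group size `N`.
#'
#' @param summaries A scenario-summary tibble from [run_grid()].
#' @return A ggplot object.
#' @export
plot_error_distribution <- function(summaries) {
  summaries_long(summaries, c("mean_err", "err_p025", "err_p975")) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$rho, colour = .data$estimator,
                                 fill = .data$estimator)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$err_p025,
                                      ymax = .data$err_p975),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_err)) +
    panel_facets() +
    ggplot2::scale_colour_manual(values = est_colours) +
    ggplot2::scale_fill_manual(values = est_colours) +
    ggplot2::labs(x = expression(rho), y = "coefficient error",
                  colour = "estimator", fill = "estimator") +
    ggplot2::theme_minimal()
}

#' Scenario MSE of the slope estimate across rho
#'
#' @inheritParams plot_error_distribution
#' @return A ggplot object.
#' @export
plot_mse <- function(summaries) {
  summaries_long(summaries, "mse") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$rho, y = .data$mse,
                                 colour = .data$estimator)) +
    ggplot2::geom_line() +
    panel_facets() +
    ggplot2::scale_colour_manual(values = est_colours) +
    ggplot2::labs(x = expression(rho), y = "MSE of slope estimate",
                  colour = "estimator") +
    ggplot2::theme_minimal()
}

#' Hausman test behaviour across rho
#'
#' Share of replicates where the test fails to reject (solid; the
#' conventional recommendation of RE) and the share where its
#' recommendation matches the smaller-absolute-error estimator (dashed),
#' with the facet background tinted by the RE-vs-FE MSE preference.
#'
#' @inheritParams plot_error_distribution
#' @return A ggplot object.
#' @export
plot_hausman <- function(summaries) {
  long <- summaries |>
    tidyr::pivot_longer(
      cols = c("hausman_fail_to_reject_share", "hausman_better_share"),
      names_to = "measure", values_to = "share"
    ) |>
    dplyr::mutate(measure = dplyr::recode(.data$measure,
      hausman_fail_to_reject_share = "fail to reject (choose RE)",
      hausman_better_share = "recommends better estimator"))
  ggplot2::ggplot(long) +
    ggplot2::geom_rect(
      data = summaries,
      ggplot2::aes(fill = .data$preference_label),
      xmin = -Inf, xmax = Inf, ymin = -Inf, ymax = Inf, alpha = 0.15
    ) +
    ggplot2::geom_line(ggplot2::aes(x = .data$rho, y = .data$share,
                                    linetype = .data$measure),
                       colour = "#d2691e") +
    panel_facets() +
    ggplot2::scale_fill_manual(
      values = c(RE = "#c23b22", FE = "#2b6ca3", trivial = "white")) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = expression(rho), y = "share of replicates",
                  fill = "MSE-preferred", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Prediction RMSE distributions across rho
#'
#' @inheritParams plot_error_distribution
#' @return A ggplot object.
#' @export
plot_prediction_rmse <- function(summaries) {
  summaries_long(summaries, c("mean_rmse", "rmse_p025", "rmse_p975")) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$rho, colour = .data$estimator,
                                 fill = .data$estimator)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rmse_p025,
                                      ymax = .data$rmse_p975),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_rmse)) +
    panel_facets() +
    ggplot2::scale_colour_manual(values = est_colours) +
    ggplot2::scale_fill_manual(values = est_colours) +
    ggplot2::labs(x = expression(rho), y = "prediction RMSE",
                  colour = "estimator", fill = "estimator") +
    ggplot2::theme_minimal()
}

#' Autoplot a grid of simulation results
#'
#' @param object A `grid_results` from [run_grid()].
#' @param type One of `"error"`, `"mse"`, `"hausman"`, `"rmse"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grid_results
#' @export
autoplot.grid_results <- function(object,
                                  type = c("error", "mse", "hausman",
                                           "rmse"),
                                  ...) {
  type <- match.arg(type)
  switch(type,
    error = plot_error_distribution(object$summaries),
    mse = plot_mse(object$summaries),
    hausman = plot_hausman(object$summaries),
    rmse = plot_prediction_rmse(object$summaries)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
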