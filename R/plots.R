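# ggplot2 views of the fitted objects and simulation output.

#' Plot propensity-score overlap by treatment group
#'
#' Density of the true (or supplied) propensity scores in each group, with
#' the `[0.1, 0.9]` overlap band marked.
#'
#' @param data A simulated dataset (see [simulate_scenario()]).
#' @param ps Propensity scores; defaults to the true scores attached to
#'   `data`.
#' @return A ggplot object.
#' @export
plot_ps_overlap <- function(data, ps = NULL) {
  ps <- ps %||% true_ps(data)
  df <- tibble::tibble(ps = ps, group = factor(data$Z, c(0, 1),
                                               c("control", "treated")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ps, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = c(0.1, 0.9), linetype = "dashed") +
    ggplot2::labs(x = "propensity score", y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn estimate_oal Plot the wAMD profile over the lambda grid with
#'   the selected penalty highlighted.
#' @param object An `oal_fit`.
#' @param ... Unused.
#' @export
autoplot.oal_fit <- function(object, ...) {
  df <- object$path
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda_exponent,
                                   y = .data$wamd)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$lambda_exponent ==
                                       object$selected_exponent),
                        size = 2, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "lambda exponent (lambda = n^a)",
                  y = "weighted absolute mean difference") +
    ggplot2::theme_minimal()
}

#' @describeIn estimate_sbw Plot the bootstrap-averaged imbalance against the
#'   candidate tolerances (log scale), marking infeasible candidates and the
#'   selection.
#' @param object An `sbw_fit`.
#' @param ... Unused.
#' @export
autoplot.sbw_fit <- function(object, ...) {
  df <- object$delta_table
  df$status <- ifelse(!df$feasible_control | !df$feasible_treated,
                      "infeasible", ifelse(df$selected, "selected",
                                           "candidate"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$multiplier,
                                   y = .data$mean_bootstrap_asd,
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = df[!is.na(df$mean_bootstrap_asd), ],
                       colour = "grey60") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "balance tolerance multiplier (delta)",
                  y = "mean bootstrap ASD", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn estimate_scs Plot the nested estimates with Wald intervals,
#'   the moving average, and the selected set size.
#' @param object An `scs_fit`.
#' @param ... Unused.
#' @export
autoplot.scs_fit <- function(object, ...) {
  df <- object$path
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$tau_hat)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$tau_hat -
                                            1.959964 * .data$se,
                                          ymax = .data$tau_hat +
                                            1.959964 * .data$se),
                             fatten = 1.5, colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$moving_average),
                       colour = "steelblue", na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = object$selected_k, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "number of top-ranked covariates (k)",
                  y = "AIPTW estimate") +
    ggplot2::theme_minimal()
}

#' Plot a performance table
#'
#' Relative MSE by method (bars) with coverage printed above each bar.
#'
#' @param perf Output of [summarize_performance()].
#' @return A ggplot object.
#' @export
plot_performance <- function(perf) {
  y <- if ("rmse" %in% names(perf)) "rmse" else "mse"
  ggplot2::ggplot(perf, ggplot2::aes(x = factor(.data$method,
                                                method_labels),
                                     y = .data[[y]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$covrate)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = if (y == "rmse") "relative MSE" else "MSE") +
    ggplot2::theme_minimal()
}
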