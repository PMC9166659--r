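#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic graphics: odds-ratio forest
#' plots for fitted models, estimate distributions for the recovery
#' experiment, and duplicate-rate bars for the descriptive table.
#'
#' @param object A fitted or summary object from this package.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @export
autoplot.dupfit <- function(object, ...) {
  cf <- filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(cf, ggplot2::aes(x = exp(.data$estimate),
                                   y = stats::reorder(.data$term,
                                                      .data$estimate))) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = exp(.data$conf.low),
                                          xmax = exp(.data$conf.high))) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL,
                  title = "Logistic model: odds ratios with Wald 95% CIs") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.dup2sri <- function(object, ...) {
  p <- autoplot(object$second_stage) +
    ggplot2::labs(title = "2SRI second stage: odds ratios with Wald 95% CIs",
                  subtitle = sprintf("Cragg-Donald F = %.1f; AIE = %.3f",
                                     object$cragg_donald$statistic,
                                     object$aie))
  p
}

#' @rdname plots
#' @export
autoplot.recovery_experiment <- function(object, ...) {
  truth <- attr(object, "truth")
  long <- tidyr::pivot_longer(
    select(object, "replicate", "naive_estimate", "tsri_estimate"),
    cols = c("naive_estimate", "tsri_estimate"),
    names_to = "estimator", values_to = "estimate"
  ) |>
    mutate(estimator = dplyr::recode(.data$estimator,
                                     naive_estimate = "naive logistic",
                                     tsri_estimate = "2SRI"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$estimate,
                                     fill = .data$estimator)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 20) +
    ggplot2::geom_vline(xintercept = truth, linetype = 2) +
    ggplot2::labs(x = "estimated exposure coefficient (log-odds)",
                  y = "replicates",
                  title = "Parameter recovery under unobserved confounding",
                  subtitle = sprintf("dashed line: generative value %.3f",
                                     truth)) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.descriptive_table <- function(object, ...) {
  rates <- filter(object, .data$variable == "duplicate_image")
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$stratum, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$pct)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "duplicate imaging rate (%)",
                  title = "Duplicate imaging by viewer-use stratum") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}
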