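#' Forest plot of structural estimates
#'
#' @param object A [sem_fit()] result.
#' @param types Parameter types to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.semloop_fit <- function(object, types = "structural", ...) {
  d <- tidy(object, conf.int = TRUE)
  d <- d[d$type %in% types & !is.na(d$estimate), ]
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Direct vs indirect effect decomposition plot
#'
#' @param object An effect table from [effect_decomposition()] (class
#'   `semloop_effects`).
#' @param outcome Restrict to one outcome variable.
#' @param ... Unused.
#' @return A ggplot with one bar pair per cause.
#' @export
autoplot.semloop_effects <- function(object, outcome = NULL, ...) {
  d <- tibble::as_tibble(object)
  if (!is.null(outcome)) d <- d[d$outcome == outcome, ]
  long <- tidyr::pivot_longer(d, c("direct", "indirect"),
                              names_to = "component", values_to = "effect")
  long <- long[abs(long$effect) > 1e-12, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$effect, y = .data$cause,
                                     fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = "effect on outcome", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Prevalence estimates with Wilson intervals
#'
#' @param prevalence A tibble from [prevalence_report()] (or [prevalence()]
#'   rows with an `outcome` column).
#' @return A ggplot.
#' @export
plot_prevalence <- function(prevalence) {
  ggplot2::ggplot(prevalence,
                  ggplot2::aes(x = .data$proportion, y = .data$outcome)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "screening prevalence (Wilson 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Candidate model comparison plot
#'
#' @param comparison A [compare_models()] table.
#' @return A ggplot of BIC against RMSEA, cutoff lines marked.
#' @export
plot_model_comparison <- function(comparison) {
  d <- tibble::as_tibble(comparison)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rmsea, y = .data$bic,
                                  shape = .data$selected)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_vline(xintercept = 0.05, linetype = 2, colour = "grey50") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), hjust = -0.08,
                       size = 3, check_overlap = TRUE) +
    ggplot2::labs(x = "RMSEA", y = "BIC (chi-square convention)") +
    ggplot2::theme_minimal()
}
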