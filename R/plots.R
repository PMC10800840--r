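#' Plot a Sloan NCM fit
#'
#' Occurrence frequency against log10 mean relative abundance, with the
#' fitted curve and the 95% prediction band; taxa colored by band position.
#'
#' @param object An `ncm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ncm_fit <- function(object, ...) {
  df <- dplyr::arrange(object$taxa, .data$mean_relative_abundance)
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$mean_relative_abundance))) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed_frequency,
                                     colour = .data$band), size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted_frequency),
                       colour = "blue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower), colour = "blue",
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), colour = "blue",
                       linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(above = "darkgreen",
                                            within = "grey40",
                                            below = "firebrick")) +
    ggplot2::labs(x = "log10 mean relative abundance",
                  y = "occurrence frequency",
                  title = sprintf("Sloan NCM: Nm = %.1f, R2 = %.3f",
                                  object$Nm, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a distance-decay fit
#'
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decay_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$distance, y = .data$dissimilarity)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "blue") +
    ggplot2::labs(x = "geographic distance (m)", y = "community dissimilarity",
                  title = sprintf("slope = %.3g, r = %.3f, p = %.3g",
                                  object$slope, object$r, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot process-classification fractions
#'
#' Stacked percentage bars of the five assembly processes per group.
#'
#' @param object A `process_classification`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.process_classification <- function(object, ...) {
  ggplot2::ggplot(object$fractions,
                  ggplot2::aes(x = .data$group, y = .data$percent,
                               fill = .data$process)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of sample pairs") +
    ggplot2::theme_minimal()
}

#' Plot node roles in the Zi-Pi plane
#'
#' @param object A tibble from [zi_pi()].
#' @param zi_cut,pi_cut Thresholds to draw (defaults 2.5 and 0.62).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_zi_pi <- function(object, zi_cut = 2.5, pi_cut = 0.62, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pi, y = .data$zi,
                                       colour = .data$role)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = zi_cut, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = pi_cut, linetype = "dashed") +
    ggplot2::labs(x = "participation coefficient (Pi)",
                  y = "within-module degree (Zi)") +
    ggplot2::theme_minimal()
}
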