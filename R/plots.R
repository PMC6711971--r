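#' Volcano plot of a transition fit
#'
#' Slope (expression change, matrix units) against -log10 empirical P,
#' colored by significance call.
#'
#' @param object A `transition_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot transition_fit
#' @export
autoplot.transition_fit <- function(object, ...) {
  d <- object$results
  ggplot2::ggplot(d, ggplot2::aes(x = .data$slope,
                                  y = -log10(.data$empirical_p),
                                  colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$spec$slope_threshold,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(object$spec$alpha),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(up = "#b2182b", down = "#2166ac",
                                            ns = "grey70")) +
    ggplot2::labs(x = sprintf("slope (%s)", object$unit),
                  y = "-log10 empirical P",
                  title = sprintf("%s arm: %s", object$arm, object$label)) +
    ggplot2::theme_minimal()
}

#' Bar chart of pattern counts
#'
#' @param summary_tab Output of [summarize_patterns()].
#' @return A ggplot object.
#' @export
plot_pattern_summary <- function(summary_tab) {
  long <- summary_tab |>
    select(-"total") |>
    tidyr::pivot_longer(-"response_class", names_to = "re_class",
                        values_to = "n") |>
    filter(.data$response_class != "none") |>
    mutate(response_class = factor(.data$response_class,
                                   levels = setdiff(RESPONSE_CLASSES, "none")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$response_class, y = .data$n,
                                     fill = .data$re_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "REs", fill = "RE class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Repeat enrichment per arm and visit
#'
#' Delta-ratio per repeat, faceted by arm x visit; significant cells
#' (BH-adjusted hypergeometric P < `alpha`) are outlined.
#'
#' @param enrichment Output of [enrichment_by_visit()].
#' @param alpha Significance level for highlighting.
#' @return A ggplot object.
#' @export
plot_repeat_enrichment <- function(enrichment, alpha = 0.05) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = .data$repeat_name, y = .data$delta_ratio,
                               fill = .data$bh_p < alpha)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(ggplot2::vars(.data$arm), ggplot2::vars(.data$visit)) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey60"),
                               name = sprintf("BH P < %g", alpha)) +
    ggplot2::labs(x = NULL, y = "delta-ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
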