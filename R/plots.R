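# ggplot2 autoplot methods for the package's result types.

#' @method autoplot generalization_curve
#' @export
autoplot.generalization_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$direction, y = .data$prop_rightward,
                               linetype = .data$stimulus_kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = seq(0, 360, 60)) +
    ggplot2::labs(x = "stimulus direction (deg)",
                  y = "fraction classified rightward",
                  linetype = "stimulus") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @method autoplot priming_curve
#' @export
autoplot.priming_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$distance, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = 90, linetype = "dotted") +
    ggplot2::scale_x_continuous(breaks = seq(0, 180, 30)) +
    ggplot2::labs(x = "prime-target distance (deg)", y = "accuracy") +
    ggplot2::theme_minimal()
}

#' @method autoplot pruning_profile
#' @export
autoplot.pruning_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              c("fraction_component", "fraction_pattern"),
                              names_to = "cell_class",
                              names_prefix = "fraction_",
                              values_to = "fraction")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$quantile, y = .data$fraction,
                               color = .data$cell_class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_color_manual(values = c(component = "#2e7d32",
                                           pattern = "#ef6c00")) +
    ggplot2::labs(x = "pruned quantile of |weight|",
                  y = "fraction of decoding pool", color = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @method autoplot evidence_curve
#' @export
autoplot.evidence_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$direction, y = .data$evidence,
                               linetype = .data$test_kind,
                               color = .data$train_kind)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = seq(0, 360, 60)) +
    ggplot2::labs(x = "stimulus direction (deg)",
                  y = "weighted input (evidence)",
                  color = "trained on", linetype = "tested on") +
    ggplot2::theme_minimal()
}

#' Plot the decision neuron's weights over preferred direction
#'
#' @param model A `plaid_readout`.
#' @return A ggplot object: weight against the cell's preferred direction,
#'   colored by cell class.
#' @export
plot_weights <- function(model) {
  ggplot2::ggplot(tidy(model),
                  ggplot2::aes(x = .data$pref_direction, y = .data$weight,
                               color = .data$cell_class)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_color_manual(values = c(component = "#2e7d32",
                                           pattern = "#ef6c00")) +
    ggplot2::scale_x_continuous(breaks = seq(0, 360, 60)) +
    ggplot2::labs(x = "preferred direction (deg)", y = "weight",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot group priming curves with bootstrap confidence bands
#'
#' @param boot A `priming_bootstrap` from [bootstrap_group_curves()].
#' @return A ggplot object, one panel per group, identity and cross
#'   conditions overlaid with their Bonferroni-adjusted normal CI bands.
#' @export
plot_priming_curves <- function(boot) {
  stopifnot(inherits(boot, "priming_bootstrap"))
  ggplot2::ggplot(boot$curves,
                  ggplot2::aes(x = .data$distance, y = .data$accuracy,
                               color = .data$condition,
                               fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_color_manual(values = c(identity = "black",
                                           cross = "grey55")) +
    ggplot2::scale_fill_manual(values = c(identity = "black",
                                          cross = "grey55")) +
    ggplot2::scale_x_continuous(breaks = seq(0, 180, 30)) +
    ggplot2::labs(x = "prime-target distance (deg)", y = "accuracy",
                  color = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
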