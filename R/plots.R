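#' Plot global metric curves by group
#'
#' Group mean (ribbon: +/- 1 SE) of each global metric over the sparsity
#' grid.
#'
#' @param object A `wm_metric_curves` tibble from
#'   [cohort_global_curves()].
#' @param metrics Metrics to facet (default all seven).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wm_metric_curves <- function(object, metrics = global_metric_names,
                                      ...) {
  long <- object |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$group, .data$metric, .data$S) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$S, .data$mean,
                                     colour = .data$group,
                                     fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "sparsity S", y = NULL, colour = NULL, fill = NULL)
}

#' Plot an NBS result
#'
#' Supra-threshold edges of each component, labelled by region, with the
#' component-level FWER p in the strip.
#'
#' @param object A `wm_nbs` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wm_nbs <- function(object, ...) {
  edges <- tidy(object)
  if (!nrow(edges)) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0,
                               label = "no supra-threshold components") +
             ggplot2::theme_void())
  }
  edges <- dplyr::mutate(
    edges,
    pair = paste(.data$region_i, .data$region_j, sep = " - "),
    label = sprintf("%s component %d (p = %.3g)", .data$direction,
                    .data$component, .data$p_fwer))
  ggplot2::ggplot(edges, ggplot2::aes(abs(.data$t),
                                      stats::reorder(.data$pair,
                                                     abs(.data$t)))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = "|t|", y = NULL)
}

#' Plot classifier performance and top connections
#'
#' @param object A `wm_progression` object.
#' @param type `"accuracy"` (per-fold balanced accuracy with the
#'   permutation null, when available) or `"importance"` (top
#'   connections).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wm_progression <- function(object,
                                    type = c("accuracy", "importance"),
                                    ...) {
  type <- match.arg(type)
  if (type == "accuracy") {
    df <- tibble(fold = seq_along(object$fold_accuracies),
                 accuracy = object$fold_accuracies)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$fold, .data$accuracy)) +
      ggplot2::geom_col() +
      ggplot2::geom_hline(yintercept = object$mean_balanced_accuracy,
                          linetype = 2) +
      ggplot2::labs(x = "outer fold", y = "balanced accuracy")
    if (!is.null(object$perm_accuracies)) {
      p <- p + ggplot2::geom_hline(
        yintercept = quantile(object$perm_accuracies, 0.95),
        linetype = 3)
    }
    p
  } else {
    imp <- dplyr::mutate(object$importance,
                         pair = paste(.data$region_i, .data$region_j,
                                      sep = " - "))
    ggplot2::ggplot(imp, ggplot2::aes(.data$importance,
                                      stats::reorder(.data$pair,
                                                     .data$importance))) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "predictive importance", y = NULL)
  }
}
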