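#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom dplyr .data
NULL

#' Plot methods
#'
#' `autoplot()` methods for the package's result objects: ordination
#' score plots, per-iteration performance traces, pooled SHAP
#' distributions, screening traces, and group contrasts, plus an
#' UpSet-style bar chart of intersection counts.
#'
#' @param object A result object.
#' @param labels Optional named vector (by sample) used to colour
#'   ordination scores.
#' @param ... Unused.
#' @return A ggplot object.
#' @name pmiscreen-plots
NULL

#' @rdname pmiscreen-plots
#' @export
autoplot.pmi_ordination <- function(object, labels = NULL, ...) {
  sc <- object$scores
  dims <- setdiff(names(sc), "sample")[1:2]
  expl <- object$explained
  lab <- function(d) {
    i <- match(d, expl$component)
    if (is.na(i)) d else sprintf("%s (%.1f%%)", d, 100 * expl$variance_ratio[i])
  }
  if (!is.null(labels)) sc$group <- labels[sc$sample]
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data[[dims[1]]], .data[[dims[2]]]))
  p <- if (is.null(labels)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  }
  p + ggplot2::labs(x = lab(dims[1]), y = lab(dims[2]),
                    title = toupper(object$method)) +
    ggplot2::theme_minimal()
}

#' @rdname pmiscreen-plots
#' @export
autoplot.rf_evaluation <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object), c("accuracy", "f1"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(y = "test-set metric",
                  title = "Resampled evaluation") +
    ggplot2::theme_minimal()
}

#' @rdname pmiscreen-plots
#' @export
autoplot.screening_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object),
                              c("mean_accuracy", "min_accuracy",
                                "mean_f1", "min_f1"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$round, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(long$round)) +
    ggplot2::labs(y = "pooled metric", title = "Variable screening trace") +
    ggplot2::theme_minimal()
}

#' @rdname pmiscreen-plots
#' @export
autoplot.pmi_contrast <- function(object, ...) {
  long <- tidyr::pivot_longer(object$profiles,
                              c("molecular_weight", "acidic_pct",
                                "basic_pct"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Early-exclusive vs late biochemical profiles") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Pooled SHAP distribution plot
#'
#' Violin plot of pooled per-class SHAP values per protein, mirroring the
#' usual presentation of per-class attribution distributions.
#'
#' @param evaluation An `rf_evaluation` with SHAP values.
#' @return A ggplot object.
#' @export
plot_shap_distributions <- function(evaluation) {
  stopifnot(inherits(evaluation, "rf_evaluation"))
  if (is.null(evaluation$shap)) abort("No SHAP values in this evaluation.")
  ggplot2::ggplot(evaluation$shap,
                  ggplot2::aes(.data$protein, .data$value,
                               fill = .data$protein)) +
    ggplot2::geom_violin(scale = "width", alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(~class) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "SHAP value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' UpSet-style intersection bar chart
#'
#' @param counts Tibble from [intersection_counts()].
#' @return A ggplot object.
#' @export
plot_intersection_counts <- function(counts) {
  counts <- dplyr::filter(counts, .data$n > 0)
  counts$signature <- factor(counts$signature,
                             levels = counts$signature[order(-counts$n)])
  ggplot2::ggplot(counts, ggplot2::aes(.data$signature, .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = "membership signature", y = "proteins") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
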