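#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-fold performance of a cross-validation report
#'
#' Boxplots of the per-fold F1, MCC and iAUC values with the across-fold
#' mean overlaid.
#'
#' @param object a `ddi_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ddi_eval
#' @export
autoplot.ddi_eval <- function(object, ...) {
  long <- tidy(object)
  means <- dplyr::summarise(dplyr::group_by(long, .data$metric),
                            value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 1) +
    ggplot2::geom_point(data = means, colour = "red", shape = 18, size = 3) +
    ggplot2::labs(x = NULL, y = "per-fold value",
                  title = attr(object, "config")$label) +
    ggplot2::theme_minimal()
}

#' Plot a rank table
#'
#' Configurations ordered by RP3 (best first), showing the per-measure
#' competition ranks.
#'
#' @param object a `ddi_rank_table` from [rank_product_rp3()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ddi_rank_table
#' @export
autoplot.ddi_rank_table <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::mutate(configuration = factor(.data$configuration,
                                         levels = rev(.data$configuration))) |>
    tidyr::pivot_longer(c("rank_f1", "rank_mcc", "rank_iauc"),
                        names_to = "measure", values_to = "rank") |>
    dplyr::mutate(measure = sub("rank_", "", .data$measure))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$configuration,
                                     colour = .data$measure)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "competition rank (1 = best)", y = NULL,
                  colour = "measure") +
    ggplot2::theme_minimal()
}

#' Plot the most discriminative features of a model
#'
#' @param model a `ddi_model`.
#' @param k features per direction.
#' @param standardized,train passed to [top_features()].
#' @return a ggplot object.
#' @export
plot_top_features <- function(model, k = 20, standardized = FALSE, train = NULL) {
  tf <- top_features(model, k = k, standardized = standardized, train = train)
  tf <- dplyr::mutate(tf, feature = factor(.data$feature,
                                           levels = rev(unique(.data$feature))))
  ggplot2::ggplot(tf, ggplot2::aes(x = .data$weight, y = .data$feature,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "hyperplane coefficient", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
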