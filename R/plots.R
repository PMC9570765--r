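#' Histogram of gene-silencing potencies
#'
#' @param records Tibble with a `potency` column.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_potency_distribution <- function(records, bins = 30) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$potency)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", color = "white") +
    ggplot2::labs(x = "potency", y = "siRNA count") +
    ggplot2::theme_minimal()
}

#' Predicted-versus-actual scatter plot
#'
#' @param y Actual potencies.
#' @param p Predicted potencies.
#' @return A ggplot object annotated with Pearson r.
#' @export
plot_predictions <- function(y, p) {
  df <- tibble(actual = y, predicted = p)
  r <- pearson_r(y, p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$actual, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::labs(title = sprintf("Pearson r = %.2f", r),
                  x = "actual potency", y = "predicted potency") +
    ggplot2::theme_minimal()
}

#' @method autoplot sibcut_pc_scan
#' @export
autoplot.sibcut_pc_scan <- function(object, ...) {
  df <- as_tibble(object)
  df$n_components <- factor(df$n_components, levels = unique(df$n_components))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_components, y = .data$r,
                                   group = .data$set, color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of PLS components", y = "Pearson r",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot sibcut_importance
#' @export
autoplot.sibcut_importance <- function(object, which = c("position", "bcut"),
                                       ...) {
  which <- match.arg(which)
  if (which == "position") {
    df <- object$per_position
    df$label <- factor(paste0("nt", df$position),
                       levels = paste0("nt", sort(df$position)))
  } else {
    df <- object$per_bcut
    df$label <- factor(df$descriptor, levels = BCUT_NAMES)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$importance)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "relative importance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
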