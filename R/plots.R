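#' @importFrom ggplot2 ggplot aes geom_line geom_col geom_histogram labs
#'   autoplot facet_wrap theme_minimal
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Training-loss curve of a demo fit
#'
#' @param object A `dnalm_demo_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dnalm_demo_fit <- function(object, ...) {
  lh <- object$loss_history
  xvar <- if ("step" %in% names(lh)) "step" else "epoch"
  ggplot(lh, aes(x = .data[[xvar]], y = .data$loss)) +
    geom_line(colour = "steelblue") +
    labs(
      x = xvar, y = "mean loss",
      title = sprintf("Training loss (%s task)", object$task)
    ) +
    theme_minimal()
}

#' Reference-rank distribution of a restoration evaluation
#'
#' @param object A `masking_eval_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.masking_eval_result <- function(object, ...) {
  ggplot(object$per_position, aes(x = .data$rank)) +
    geom_histogram(bins = 30, fill = "steelblue") +
    labs(x = "reference rank of the true token (0 = best)", y = "positions",
         title = "Masked-token restoration ranks") +
    theme_minimal()
}

#' Composition of a labeled benchmark dataset
#'
#' Record counts per source class and split.
#'
#' @param records Labeled-records tibble with `source_class` and `split`.
#' @return A ggplot object.
#' @export
plot_dataset_composition <- function(records) {
  df <- records %>%
    dplyr::count(.data$split, .data$source_class)
  ggplot(df, aes(x = .data$source_class, y = .data$n, fill = .data$split)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "records", title = "Dataset composition") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
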