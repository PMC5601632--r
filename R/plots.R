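# ggplot2 views of the result types

#' @exportS3Method ggplot2::autoplot
autoplot.dcg_result <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(as.data.frame(object)),
    ggplot2::aes(
      x = .data$dC, y = -log10(.data$p_value), colour = .data$is_dcg
    )
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "DCp (RMS change in link correlation)",
      y = expression(-log[10] ~ "permutation p"),
      colour = "DCG"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.driver_table <- function(object, top_n = 30, ...) {
  df <- as_tibble(as.data.frame(object)) |>
    filter(.data$rank <= top_n) |>
    mutate(gene = stats::reorder(.data$gene, -.data$rank))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$driver_score, y = .data$gene, fill = .data$is_candidate
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(
      xintercept = attr(object, "score_threshold") %||% 2, linetype = 2
    ) +
    ggplot2::labs(x = "driver gene score (z_dcg + z_mut)", y = NULL, fill = "candidate") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.evaluation_curve <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$k, y = .data$value, colour = .data$metric)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "top-k genes", y = "score", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a benchmark evaluation curve
#'
#' Convenience wrapper around [autoplot()] for `evaluation_curve` objects.
#'
#' @param curve An `evaluation_curve` from [evaluation_curve()].
#' @param ... Passed to the autoplot method.
#' @return A ggplot object.
#' @export
plot_evaluation_curve <- function(curve, ...) autoplot(curve, ...)
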