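# ggplot2 visualisations for the main result types.

#' @export
autoplot.score_map_result <- function(object, ...) {
  df <- tibble::tibble(
    component = seq_along(object$variance_explained),
    variance_explained = object$variance_explained
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$variance_explained)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "principal component", y = "variance explained",
                  title = "Perfusion score map: variance explained") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.enrichment_table <- function(object, top_n = 20, ...) {
  df <- utils::head(object, top_n)
  df$category <- factor(df$category, levels = rev(df$category))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$category,
                                   fill = .data$rejected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey70"),
                               name = "FDR < 0.05") +
    ggplot2::labs(x = "category score (mean Fisher-z r)", y = NULL,
                  title = "Category enrichment against the spatial null") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gradient_result <- function(object, ...) {
  df <- tibble::tibble(g1 = object$gradients[, 1],
                       g2 = object$gradients[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$g1, y = .data$g2,
                                   colour = .data$g1 > 0)) +
    ggplot2::geom_point(alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = sprintf("gradient 1 (lambda = %.3f)", object$lambdas[1]),
                  y = sprintf("gradient 2 (lambda = %.3f)", object$lambdas[2]),
                  title = "Covariance gradients") +
    ggplot2::theme_minimal()
}

#' Plot fitted normative centile curves over the raw data
#'
#' @param fit a `trajectory_fit`.
#' @param age,y optional raw observations to underlay.
#' @param centiles probabilities for the curves.
#' @return A ggplot object.
#' @export
plot_centiles <- function(fit, age = NULL, y = NULL,
                          centiles = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  grid <- seq(fit$age_range[1], fit$age_range[2], length.out = 200)
  curves <- centile_curves(fit, grid, centiles)
  p <- ggplot2::ggplot()
  if (!is.null(age) && !is.null(y)) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(age = age, y = y),
      ggplot2::aes(x = .data$age, y = .data$y),
      alpha = 0.2, size = 0.6
    )
  }
  p +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$age, y = .data$value,
                   group = .data$centile, colour = factor(.data$centile))
    ) +
    ggplot2::scale_colour_viridis_d(name = "centile") +
    ggplot2::labs(x = "age (years)", y = "perfusion",
                  title = "Normative generalized-gamma trajectory") +
    ggplot2::theme_minimal()
}
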