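#' Eigen-gap diagnostic plot
#'
#' Plots the ascending normalized-Laplacian eigenvalues of a clustering and
#' marks the selected cluster count; a clean gap after position `n`
#' supports the eigen-gap choice.
#'
#' @param x an `interface_clustering` object.
#' @param n_show how many leading eigenvalues to display.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.interface_clustering <- function(x, n_show = 20, ...) {
  df <- tibble::tibble(
    index = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues
  )
  df <- df[df$index <= n_show, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$eigenvalue)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = x$n + 0.5, linetype = "dashed") +
    ggplot2::labs(
      x = "eigenvalue index (ascending)",
      y = "normalized Laplacian eigenvalue",
      title = sprintf("Eigen-gap selection: n = %d clusters (k = %d)", x$n, x$k)
    ) +
    ggplot2::theme_minimal()
}

#' Support sweep plot
#'
#' Shows how the number of frequent and maximal patterns and the largest
#' pattern size vary with the minimum-support threshold.
#'
#' @param x a `support_sweep` tibble from [support_sweep()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.support_sweep <- function(x, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(x),
    cols = c("n_patterns", "n_maximal", "max_nodes"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$support, y = .data$value, colour = .data$metric
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "minimum support", y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-rank parameter selection plot
#'
#' Visualizes the joint selection table of [select_parameters()]: the
#' eigen-gap cluster count and the minimal connected neighbor count per
#' retained SVD rank.
#'
#' @param report the `report` tibble of a [select_parameters()] result.
#' @return A ggplot object.
#' @export
plot_parameter_selection <- function(report) {
  long <- tidyr::pivot_longer(
    report,
    cols = c("n", "k"),
    names_to = "parameter", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$d, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = "retained SVD rank d",
      y = NULL,
      title = "Cluster count (eigen-gap) and neighbor count per rank"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
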