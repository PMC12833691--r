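#' Plot a Shapley contribution table
#'
#' Horizontal bar chart of the per-variable percentage contributions to
#' absolute opportunity inequality.
#'
#' @param object a `opineq_contrib` table.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.opineq_contrib <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$share,
                                   y = stats::reorder(.data$variable,
                                                      .data$share))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "contribution to absolute IOp (%)", y = NULL,
                  title = sprintf("Shapley decomposition (%s, %s)",
                                  attr(object, "family"),
                                  attr(object, "method"))) +
    ggplot2::theme_minimal()
}

#' Plot per-quantile opportunity inequality
#'
#' Relative opportunity inequality across the requested quantile levels; a
#' declining profile indicates a tail effect (environment matters more for
#' patients in poorer health).
#'
#' @param object a [quantile_iop()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.opineq_quantile <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$tau, y = .data$theta_r)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = object$summary$tau) +
    ggplot2::labs(x = expression(tau),
                  y = expression(theta[r](tau)),
                  title = "Relative opportunity inequality by quantile") +
    ggplot2::theme_minimal()
}
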