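# ggplot2 displays for fitted objects.

#' Plot a single-group CNI fit
#'
#' Point estimates of C, N and I with Wald intervals.
#'
#' @param object A `cni_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cni_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high)
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "Estimate",
      title = "CNI parameter estimates",
      subtitle = sprintf("G²(%d) = %.3f, p = %.3f", object$df,
                         object$g2, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a joint multi-group CNI fit
#'
#' Per-group parameter estimates side by side (the standard display for
#' extreme-group comparisons), with Wald intervals where available.
#'
#' @param object A `cni_fit_joint`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cni_fit_joint <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$estimate,
                                   colour = .data$group)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Estimate", colour = "Group",
                  title = "CNI parameter estimates by group") +
    ggplot2::theme_minimal()
}

#' Plot observed vs model-implied action proportions
#'
#' @param counts Counts tibble for one group.
#' @param fit Optional `cni_fit`; when given, model-implied probabilities are
#'   overlaid.
#' @return A ggplot object.
#' @export
plot_action_proportions <- function(counts, fit = NULL) {
  x <- single_group_counts(counts)
  df <- dilemma_types()
  df$observed <- x$n_action / pmax(x$n_total, 1)
  df$type <- paste(substr(df$norm, 1, 3), df$benefits, sep = "/")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = .data$observed)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Dilemma type (norm/benefits)",
                  y = "Action proportion") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    df$model <- cni_p_action(fit$estimates)
    p <- p + ggplot2::geom_point(
      data = df, ggplot2::aes(y = .data$model), shape = 4, size = 3
    )
  }
  p
}
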