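#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of each result type:
#' selection tables as ratio-with-interval dot plots on a log-friendly
#' scale with the neutral line at 1, activity profiles as stacked
#' hourly bars, activity kernels as density curves, and NMDS results
#' as ordination scatter plots annotated with the stress.
#'
#' @param object A result object from this package.
#' @param ... Unused.
#' @return A ggplot object.
#' @name herpeco-autoplot
NULL

#' @rdname herpeco-autoplot
#' @export
autoplot.selection_table <- function(object, ...) {
  df <- tidy(object)
  df$category <- factor(df$category,
                        levels = df$category[order(df$wi)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wi, y = .data$category)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "red3") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
      height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$classification),
                        size = 2) +
    ggplot2::labs(x = "selection ratio (Wi)", y = NULL,
                  colour = "selection") +
    ggplot2::theme_minimal()
}

#' @rdname herpeco-autoplot
#' @export
autoplot.activity_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("active", "inactive"),
                            names_to = "state", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$count,
                                   fill = .data$state)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "hour of day", y = "encounters") +
    ggplot2::theme_minimal()
}

#' @rdname herpeco-autoplot
#' @export
autoplot.activity_kde <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_h, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "hour of day", y = "density") +
    ggplot2::theme_minimal()
}

#' @rdname herpeco-autoplot
#' @export
autoplot.herpeco_nmds <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = "NMDS1", y = "NMDS2",
      subtitle = paste0("stress = ", signif(object$stress, 3))) +
    ggplot2::theme_minimal()
}
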