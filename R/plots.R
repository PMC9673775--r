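#' Plot the SATR-Bolton association
#'
#' Scatter of per-subject SATR against anterior Bolton ratio (percent) with
#' the fitted regression line.
#'
#' @param object A `satr_fit` from [fit_satr_abr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.satr_fit <- function(object, ...) {
  d <- object$model$model |>
    as_tibble() |>
    mutate(satr_pct = 100 * .data$satr, abr_pct = 100 * .data$abr)
  ggplot(d, aes(x = .data$satr_pct, y = .data$abr_pct)) +
    geom_point(alpha = 0.6) +
    geom_abline(intercept = 100 * object$intercept, slope = object$slope,
                colour = "steelblue", linewidth = 0.8) +
    labs(
      x = "SATR (%)", y = "Anterior Bolton ratio (%)",
      title = sprintf("abr = %.3f + %.3f satr   (r = %.3f, n = %d)",
                      object$intercept, object$slope, object$r, object$n)
    ) +
    theme_minimal()
}

#' Plot ratio values against a normative standard
#'
#' Histogram of ratio values with the normal band of a standard marked.
#'
#' @param object A [norm_standard()].
#' @param values_pct Ratio values to display, percent.
#' @param binwidth Histogram bin width in percentage points.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.norm_standard <- function(object, values_pct, binwidth = 1, ...) {
  ggplot(tibble(value = values_pct), aes(x = .data$value)) +
    geom_histogram(binwidth = binwidth, fill = "grey75", colour = "white") +
    geom_vline(xintercept = c(object$lower, object$mean, object$upper),
               linetype = c("dashed", "solid", "dashed"),
               colour = "steelblue") +
    labs(x = "Ratio (%)", y = "Subjects",
         title = sprintf("Normal band %.2f-%.2f%% (mean %.2f%%, k = %g)",
                         object$lower, object$upper, object$mean, object$k)) +
    theme_minimal()
}

#' Plot a diagnosis cross-table
#'
#' Tile plot of the 3x3 (or collapsed 2x2) screening-vs-gold table with
#' counts printed in each cell.
#'
#' @param object A [cross_table()] or [collapse_to_binary()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cross_table <- function(object, ...) {
  d <- as.data.frame(as.table(unclass(object))) |>
    setNames(c("test", "gold", "count"))
  ggplot(d, aes(x = .data$gold, y = .data$test, fill = .data$count)) +
    geom_tile(colour = "white") +
    geom_text(aes(label = .data$count)) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "Gold standard (anterior Bolton)", y = "Screening test (SATR)",
         fill = "n") +
    theme_minimal()
}

#' @rdname autoplot.cross_table
#' @exportS3Method ggplot2::autoplot
autoplot.cross_table2 <- autoplot.cross_table
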