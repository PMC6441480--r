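#' Box plot of per-sample expression distributions
#'
#' The comparability diagnostic run before differential expression: after
#' median centering, all boxes should sit on a common median line.
#'
#' @param matrix An [expr_matrix].
#' @param ... Passed to [graphics::boxplot()].
#' @return The boxplot statistics, invisibly.
#' @export
plot_sample_boxes <- function(matrix, ...) {
  stopifnot(inherits(matrix, "expr_matrix"))
  invisible(graphics::boxplot(matrix$values, las = 2,
                              ylab = "log2 intensity", ...))
}

#' Log-log degree distribution with its power-law fit
#'
#' @param dist Data frame from [degree_distribution_table()].
#' @param fit Optional [fit_power_law()] result to overlay.
#' @return `NULL`, invisibly.
#' @export
plot_degree_distribution <- function(dist, fit = NULL) {
  graphics::plot(dist$k, dist$count, log = "xy", pch = 16,
                 xlab = "degree k", ylab = "node count")
  if (!is.null(fit))
    graphics::curve(fit$a * x^fit$b, add = TRUE, col = "red")
  invisible(NULL)
}
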