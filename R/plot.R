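#' Forest plot of association results
#'
#' Draws odds ratios and 95% confidence intervals (log scale) for a stack
#' of fitted models — primary, stratified, and sensitivity rows as produced
#' by [run_pipeline()] or the individual fitting functions. Rows that did
#' not converge are dropped with a message.
#'
#' @param results a data.table of result rows in the [fit_logistic()] layout
#' @param ref vertical reference line (default 1)
#' @return a ggplot object
#' @export
plot_forest <- function(results, ref = 1) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_forest needs the ggplot2 package", call. = FALSE)
  dd <- as.data.table(results)
  bad <- !dd$converged | is.na(dd$or_estimate)
  if (any(bad)) {
    message(sprintf("dropping %d non-converged row(s)", sum(bad)))
    dd <- dd[!bad]
  }
  dd[, label := ifelse(is.na(stratum), model, paste(model, stratum))]
  dd[, label := factor(label, levels = rev(unique(label)))]
  ggplot2::ggplot(dd, ggplot2::aes(x = or_estimate, y = label)) +
    ggplot2::geom_vline(xintercept = ref, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = ci_low, xmax = ci_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
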