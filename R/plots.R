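#' Manhattan-style plot of a per-site scan statistic
#'
#' @param scores a per-site tibble with a `pos` column (e.g. from
#'   [pbs_scan()], [nsl_scan()], [xpnsl_scan()]).
#' @param statistic column name to plot.
#' @param threshold optional horizontal significance line (e.g. from
#'   [empirical_threshold()]).
#' @return a ggplot.
#' @export
plot_scan <- function(scores, statistic, threshold = NULL) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$pos / 1e6,
                                            y = .data[[statistic]])) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9, na.rm = TRUE) +
    ggplot2::labs(x = "position (Mb)", y = statistic) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot composite-test results
#'
#' Shows `-log10(hmp)` along the region, with removed sites greyed out
#' and significant sites highlighted.
#'
#' @param records output of [composite_test()] / [composite_scan()] with a
#'   `pos` column.
#' @return a ggplot.
#' @export
plot_composite <- function(records) {
  records$status <- dplyr::case_when(
    records$removed ~ "removed",
    records$significant ~ "significant",
    TRUE ~ "tested"
  )
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$pos / 1e6,
                               y = -log10(.data$hmp),
                               colour = .data$status)) +
    ggplot2::geom_point(size = 1.2, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(removed = "grey70",
                                            tested = "grey30",
                                            significant = "firebrick")) +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](HMP)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Effect plot for an association fit
#'
#' Phenotype (model response scale) by genotype dosage with the fitted
#' dosage effect overlaid at covariate means.
#'
#' @param object an `assoc_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot assoc_fit
#' @export
autoplot.assoc_fit <- function(object, ...) {
  mf <- object$fit$model
  names(mf) <- gsub("`", "", names(mf))
  df <- tibble(y = mf[[gsub("`", "", object$phenotype)]],
               dosage = mf[[gsub("`", "", object$dosage)]])
  ## fitted line at covariate means
  co <- coef(object$fit)
  names(co) <- gsub("`", "", names(co))
  intercept_adj <- co[["(Intercept)"]]
  for (cv in object$covariates %||% character(0)) {
    intercept_adj <- intercept_adj + co[[cv]] * mean(mf[[cv]])
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dosage, y = .data$y)) +
    ggplot2::geom_jitter(width = 0.06, height = 0, alpha = 0.5) +
    ggplot2::geom_abline(intercept = intercept_adj, slope = object$beta,
                         colour = "firebrick") +
    ggplot2::labs(x = sprintf("%s dosage (%s)", object$dosage, object$model),
                  y = object$phenotype,
                  title = sprintf("beta = %.2f [%.2f, %.2f], p = %.3g",
                                  object$beta, object$ci_low, object$ci_high,
                                  object$p_value)) +
    ggplot2::theme_minimal()
}
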