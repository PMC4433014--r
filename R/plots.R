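#' Plot the permutation null of an OPTPDT fit
#'
#' Histogram of the permuted maximum standardized statistics `M_j` with the
#' observed statistic `M` marked; the permutation p-value is the fraction
#' of the histogram's mass at or beyond the line.
#'
#' @param object An `optpdt_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.optpdt_fit <- function(object, ...) {
  df <- tibble::tibble(m_j = object$null_statistics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m_j)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$statistic,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = "permuted max standardized statistic",
      y = "permutations",
      title = sprintf("M = %.3f, permutation p = %.4g (m = %d)",
                      object$statistic, object$p, object$m)
    ) +
    ggplot2::theme_minimal()
}

#' Plot rejection rates of an experiment
#'
#' Rejection-rate point estimates with exact 95% confidence intervals per
#' method, faceted by nominal level; the dashed line marks the nominal
#' level itself (type-I-error experiments should straddle it).
#'
#' @param object An `optpdt_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.optpdt_experiment <- function(object, ...) {
  df <- dplyr::mutate(object$summary,
                      level = paste0("alpha = ", .data$alpha))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$estimate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf_low,
                                        ymax = .data$conf_high),
                           width = 0.2) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$alpha),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~level, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "rejection rate", title = object$scenario) +
    ggplot2::theme_minimal()
}
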