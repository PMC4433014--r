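#' Tidy the per-threshold table of an OPTPDT fit
#'
#' @param x An `optpdt_fit` from [optpdt_test()].
#' @param ... Unused.
#' @return Tibble with one row per p-value threshold: `threshold`,
#'   `n_selected`, `y` (sum of selected PDT statistics), the permutation
#'   null moments `mu` and `sigma`, the standardized `z`, and `available`
#'   (`FALSE` when the null is degenerate at that threshold).
#' @export
tidy.optpdt_fit <- function(x, ...) {
  dplyr::select(x$thresholds, -"selected")
}

#' One-row summary of an OPTPDT fit
#'
#' @inheritParams tidy.optpdt_fit
#' @return One-row tibble: `set`, `n_markers`, `n_selected` and
#'   `best_threshold` for the threshold attaining the maximum `z`,
#'   `statistic` (M), `p`, `p_min`, `m`, and one `z_<threshold>` column per
#'   threshold.
#' @export
glance.optpdt_fit <- function(x, ...) {
  th <- x$thresholds
  best <- if (any(th$available)) {
    which.max(ifelse(th$available, th$z, -Inf))
  } else NA_integer_
  out <- tibble::tibble(
    set = x$set_name,
    n_markers = x$n_markers,
    n_selected = if (is.na(best)) NA_integer_ else th$n_selected[best],
    best_threshold = if (is.na(best)) NA_real_ else th$threshold[best],
    statistic = x$statistic,
    p = x$p,
    p_min = x$p_min,
    m = x$m
  )
  for (i in seq_len(nrow(th))) out[[z_col(th$threshold[i])]] <- th$z[i]
  out
}

#' Tidy an experiment result
#'
#' @param x An `optpdt_experiment` from [type1_error_experiment()] or
#'   [power_experiment()].
#' @param ... Unused.
#' @return The summary tibble: one row per method and nominal level with
#'   the rejection count, the point estimate and its exact (Clopper-Pearson)
#'   95\% confidence interval.
#' @export
tidy.optpdt_experiment <- function(x, ...) x$summary

#' One-row-per-method summary of an experiment
#'
#' @inheritParams tidy.optpdt_experiment
#' @return Tibble with one row per method: `scenario`, `method`,
#'   `n_replicates`, and the rejection rate at the first nominal level.
#' @export
glance.optpdt_experiment <- function(x, ...) {
  a1 <- x$summary$alpha[1]
  dplyr::filter(x$summary, .data$alpha == a1) |>
    dplyr::select("scenario", "method", "n_replicates", "estimate")
}
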