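#' Fixed-threshold SNP-set test
#'
#' The single-threshold special case of [optpdt_test()]: sum the PDT
#' statistics of the markers below one fixed p-value cutoff (0.05 by
#' default, the conventional choice in set-based testing) and assess the
#' sum by the same family sign-flip permutations.
#'
#' @inheritParams optpdt_test
#' @param threshold The single p-value cutoff (default 0.05).
#' @return An `optpdt_fit`.
#' @export
fixed_threshold_test <- function(x, threshold = 0.05, set = NULL, m = 2000,
                                 seed = NULL) {
  optpdt_test(x, set = set, thresholds = threshold, m = m, seed = seed)
}

#' Classical p-value combination tests
#'
#' Comparators for the set-level analysis, applied to the per-marker
#' single-SNP p-values of a set: Fisher's combination
#' (`-2 sum log p` against chi-square with `2n` df), the Simes test
#' (`min_i n p_(i) / i`), and the Bonferroni min-p test
#' (`min(1, n min p)`).
#'
#' @param p_values Numeric vector of per-marker p-values in (0, 1].
#' @return Tibble with columns `method` (`"fisher"`, `"simes"`, `"minp"`)
#'   and `p`.
#' @examples
#' pvalue_combination_tests(c(0.01, 0.04))
#' @export
pvalue_combination_tests <- function(p_values) {
  if (length(p_values) == 0L) stop("p_values must be non-empty")
  if (any(is.na(p_values) | p_values <= 0 | p_values > 1)) {
    stop("p_values must lie in (0, 1]")
  }
  n <- length(p_values)
  fisher <- stats::pchisq(-2 * sum(log(p_values)), df = 2 * n,
                          lower.tail = FALSE)
  ps <- sort(p_values)
  simes <- min(n * ps / seq_len(n))
  minp <- min(1, n * min(p_values))
  tibble::tibble(method = c("fisher", "simes", "minp"),
                 p = c(fisher, simes, minp))
}

summarize_rejections <- function(p_values, alphas, scenario, method,
                                 conf_level = 0.95) {
  purrr::map_dfr(alphas, function(a) {
    r <- sum(p_values <= a)
    n <- length(p_values)
    ci <- stats::binom.test(r, n, conf.level = conf_level)$conf.int
    tibble::tibble(scenario = scenario, method = method, alpha = a,
                   n_replicates = n, rejections = r, estimate = r / n,
                   conf_low = ci[1], conf_high = ci[2])
  })
}

new_experiment <- function(summary, p_values, scenario_label) {
  structure(list(summary = summary, p_values = p_values,
                 scenario = scenario_label),
            class = "optpdt_experiment")
}

#' @export
print.optpdt_experiment <- function(x, ...) {
  cat("<optpdt_experiment> ", x$scenario, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Type-I-error experiment under a null scenario
#'
#' Simulates replicate studies under a configuration with no associated
#' markers, runs the variable-threshold test on each, and reports the
#' rejection rate at each nominal level with an exact (Clopper-Pearson)
#' 95% confidence interval. A valid test keeps the nominal level inside
#' the interval.
#'
#' @param config A null [sim_config()] (all odds ratios 1).
#' @param n_replicates Number of replicate studies.
#' @param m Permutations per replicate (default 1000).
#' @param thresholds P-value thresholds for the test.
#' @param alphas Nominal significance levels (default 0.05 and 0.01).
#' @param seed Integer seed driving the pool, every replicate and every
#'   permutation stream.
#' @return An `optpdt_experiment`: `summary` tibble plus the per-replicate
#'   p-values.
#' @export
type1_error_experiment <- function(config, n_replicates, m = 1000,
                                   thresholds = default_thresholds(),
                                   alphas = c(0.05, 0.01), seed = 1) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (length(config$odds_ratio) > 0 && any(config$odds_ratio != 1)) {
    stop("type-I-error experiments need a null config (all odds ratios 1)")
  }
  scenario <- prepare_scenario(config, seed = derive_seed(seed, "pool"))
  p <- vapply(seq_len(n_replicates), function(i) {
    study <- simulate_families(scenario,
                               seed = derive_seed(seed, paste0("rep", i)))
    fit <- optpdt_test(d_matrix(study), thresholds = thresholds, m = m,
                       seed = derive_seed(seed, paste0("perm", i)))
    fit$p
  }, numeric(1))
  new_experiment(
    summarize_rejections(p, alphas, config$label, "optpdt"),
    tibble::tibble(replicate = seq_len(n_replicates), method = "optpdt",
                   p = p),
    config$label
  )
}

#' Power experiment with paired comparators
#'
#' Simulates replicate studies under an alternative configuration and feeds
#' the same replicate to every method (a paired design: power differences
#' are not simulation-noise artifacts). The permutation-based methods
#' (`optpdt`, `fixed_threshold`) share one permutation pass per replicate;
#' `fisher`, `simes` and `minp` combine the per-marker asymptotic PDT
#' p-values.
#'
#' @param config A [sim_config()].
#' @param methods Subset of
#'   `c("optpdt", "fixed_threshold", "fisher", "simes", "minp")`.
#' @param n_replicates Number of replicate studies.
#' @param m Permutations per replicate.
#' @param thresholds Thresholds for the variable-threshold test.
#' @param fixed_p_threshold Cutoff for the fixed-threshold comparator.
#' @param alphas Nominal significance levels.
#' @param seed Integer seed.
#' @return An `optpdt_experiment` with one summary row per method and
#'   level.
#' @export
power_experiment <- function(config,
                             methods = c("optpdt", "fixed_threshold",
                                         "fisher", "simes", "minp"),
                             n_replicates = 100, m = 1000,
                             thresholds = default_thresholds(),
                             fixed_p_threshold = 0.05,
                             alphas = c(0.05, 0.01), seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  scenario <- prepare_scenario(config, seed = derive_seed(seed, "pool"))
  perm_methods <- intersect(methods, c("optpdt", "fixed_threshold"))
  comb_methods <- intersect(methods, c("fisher", "simes", "minp"))
  rows <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    study <- simulate_families(scenario,
                               seed = derive_seed(seed, paste0("rep", i)))
    dmat <- d_matrix(study)
    obs <- marker_stats(dmat)
    out <- list()
    if (length(perm_methods) > 0) {
      old <- get_rng_state()
      set.seed(derive_seed(seed, paste0("perm", i)))
      perm <- permute_t2_matrix(dmat, m)
      restore_rng_state(old)
      if ("optpdt" %in% perm_methods) {
        fit <- optpdt_from_perm(obs, perm, check_thresholds(thresholds))
        out$optpdt <- fit$p
      }
      if ("fixed_threshold" %in% perm_methods) {
        fit <- optpdt_from_perm(obs, perm, fixed_p_threshold)
        out$fixed_threshold <- fit$p
      }
    }
    if (length(comb_methods) > 0) {
      comb <- pvalue_combination_tests(obs$p)
      for (mth in comb_methods) out[[mth]] <- comb$p[comb$method == mth]
    }
    tibble::tibble(replicate = i, method = names(out),
                   p = unlist(out, use.names = FALSE))
  })
  summary <- purrr::map_dfr(methods, function(mth) {
    summarize_rejections(rows$p[rows$method == mth], alphas,
                         config$label, mth)
  })
  new_experiment(summary, rows, config$label)
}
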