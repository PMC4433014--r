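#' Threshold selection and set statistic
#'
#' Selects the markers whose single-SNP p-values fall strictly below a
#' p-value threshold and sums their PDT statistics. An empty selection
#' yields the empty-sum statistic `y = 0`.
#'
#' @param t2_values,p_values Aligned numeric vectors of per-marker PDT
#'   statistics and p-values.
#' @param threshold A p-value cutoff in (0, 1].
#' @return List with `selected` (integer indices) and `y` (sum of selected
#'   `t2_values`).
#' @export
select_and_sum <- function(t2_values, p_values, threshold) {
  stopifnot(length(t2_values) == length(p_values))
  sel <- which(p_values < threshold)
  list(selected = sel, y = sum(t2_values[sel]))
}

check_thresholds <- function(thresholds) {
  thresholds <- sort(unique(as.numeric(thresholds)), decreasing = TRUE)
  if (length(thresholds) == 0L || any(thresholds <= 0 | thresholds > 1)) {
    stop("thresholds must lie in (0, 1]")
  }
  thresholds
}

#' Default p-value thresholds for the variable-threshold statistic
#' @return Numeric vector `c(0.05, 0.03, 0.01, 0.005)`.
#' @export
default_thresholds <- function() c(0.05, 0.03, 0.01, 0.005)

# One pass of m family sign-flips: returns list(t2 = m x n matrix of
# permuted PDT statistics, p = matching p-values). The sum of squares is
# sign-invariant, so only column sums need recomputing.
permute_t2_matrix <- function(dmat, m) {
  n_fam <- nrow(dmat$values)
  signs <- matrix(sample(c(-1, 1), m * n_fam, replace = TRUE), m, n_fam)
  cs <- signs %*% dmat$values
  ss <- colSums(dmat$values^2)
  testable <- ss > 0
  t2 <- sweep(cs^2, 2, ifelse(testable, ss, 1), "/")
  t2[, !testable] <- 0
  p <- stats::pchisq(t2, df = 1, lower.tail = FALSE)
  p[, !testable] <- 1
  list(t2 = t2, p = p)
}

#' One sign-flip permutation of the family contributions
#'
#' Draws one fair sign per family and flips that family's PDT contributions
#' at every marker simultaneously (the whole row shares the sign, which is
#' what preserves LD between markers and linkage within a family), then
#' recomputes the per-marker PDT statistics.
#'
#' @param dmat A [d_matrix()].
#' @return Tibble with one row per marker: `marker_id`, `t2`, `p`, and the
#'   `signs` vector as an attribute.
#' @export
permute_once <- function(dmat) {
  stopifnot(inherits(dmat, "d_matrix"))
  pt <- permute_t2_matrix(dmat, 1L)
  out <- tibble::tibble(marker_id = dmat$marker_ids,
                        t2 = pt$t2[1L, ], p = pt$p[1L, ])
  out
}

# Core of the variable-threshold test given observed and permuted per-marker
# statistics. Shared by optpdt_test() and the harness (which reuses one
# permutation pass across methods).
optpdt_from_perm <- function(obs, perm, thresholds, estimator = "plugin") {
  m <- nrow(perm$t2)
  k <- length(thresholds)
  y_obs <- numeric(k)
  n_sel <- integer(k)
  selected <- vector("list", k)
  for (i in seq_len(k)) {
    s <- select_and_sum(obs$t2, obs$p, thresholds[i])
    selected[[i]] <- s$selected
    n_sel[i] <- length(s$selected)
    y_obs[i] <- s$y
  }
  # permuted Y_k: same empty-sum convention, all m draws serve every k
  y_perm <- vapply(seq_len(k), function(i) {
    rowSums(perm$t2 * (perm$p < thresholds[i]))
  }, numeric(m))
  y_perm <- matrix(y_perm, nrow = m)
  mu <- colMeans(y_perm)
  sigma <- apply(y_perm, 2, stats::sd)           # m - 1 denominator
  available <- is.finite(sigma) & sigma > 0
  z_obs <- ifelse(available, (y_obs - mu) / ifelse(available, sigma, 1),
                  NA_real_)
  if (any(available)) {
    z_perm <- sweep(sweep(y_perm[, available, drop = FALSE], 2,
                          mu[available], "-"),
                    2, sigma[available], "/")
    m_obs <- max(z_obs[available])
    m_perm <- do.call(pmax, as.data.frame(z_perm))
    # ties count as exceedances; permutations tied with the observed
    # statistic in exact arithmetic can differ by a few ulps after the
    # matrix column sums, so compare with a small relative tolerance
    tie_tol <- 1e-8 * max(1, abs(m_obs))
    exceed <- sum(m_perm >= m_obs - tie_tol)
  } else {
    m_obs <- NA_real_
    m_perm <- rep(NA_real_, m)
    exceed <- m
  }
  if (all(n_sel == 0L) || !any(available)) {
    # nothing selected at any threshold (or degenerate null): report p = 1
    exceed <- m
  }
  p <- if (estimator == "add-one") (exceed + 1) / (m + 1) else exceed / m
  list(
    thresholds = tibble::tibble(
      threshold = thresholds, n_selected = n_sel, selected = selected,
      y = y_obs, mu = mu, sigma = sigma, z = z_obs, available = available
    ),
    m = m, statistic = m_obs, null_statistics = m_perm,
    exceedances = exceed, p = p,
    p_min = if (estimator == "add-one") 1 / (m + 1) else 1 / m,
    estimator = estimator
  )
}

#' Optimal p-value threshold PDT for a SNP set
#'
#' Tests whether any subset of a SNP set selected by a grid of single-SNP
#' p-value thresholds shows association, in nuclear families. For each
#' threshold `k`, the statistic `Y_k` is the sum of the single-SNP PDT
#' statistics with p-values below `k`; `Y_k` is standardized to
#' `Z_k = (Y_k - mu_k) / sigma_k` using the mean and standard deviation of
#' `Y_k` over `m` LD-preserving family sign-flip permutations, and the test
#' statistic is `M = max_k Z_k`. The p-value is the fraction of permutations
#' whose own maximum standardized statistic reaches `M`.
#'
#' @param x A [family_study()] or a [d_matrix()].
#' @param set Optional character vector of marker ids restricting the test
#'   to one SNP set (ignored when `x` is already a `d_matrix`).
#' @param thresholds Descending p-value cutoffs; default
#'   [default_thresholds()].
#' @param m Number of permutations (default 2000).
#' @param seed Optional integer seed; when supplied the caller's RNG state
#'   is left untouched.
#' @param estimator `"plugin"` reports `#(M_j >= M) / m` (ties count as
#'   exceedances); `"add-one"` reports `(#(M_j >= M) + 1) / (m + 1)`.
#' @return An object of class `optpdt_fit`; see [tidy.optpdt_fit()] and
#'   [glance.optpdt_fit()]. Key elements: `statistic` (M), `p`, `p_min`
#'   (smallest attainable p-value), per-threshold table, and the per-marker
#'   observed PDT table.
#' @examples
#' study <- simulate_study(scenario_config(n_families = 50), seed = 42)
#' fit <- optpdt_test(study, m = 200, seed = 1)
#' glance(fit)
#' @export
optpdt_test <- function(x, set = NULL, thresholds = default_thresholds(),
                        m = 2000, seed = NULL,
                        estimator = c("plugin", "add-one")) {
  estimator <- match.arg(estimator)
  if (m < 1) stop("m must be at least 1")
  m <- as.integer(m)
  thresholds <- check_thresholds(thresholds)
  dmat <- if (inherits(x, "d_matrix")) x else d_matrix(x, set)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  obs <- marker_stats(dmat)
  testable <- any(obs$ss > 0)
  if (!testable) {
    perm <- list(t2 = matrix(0, m, length(dmat$marker_ids)),
                 p = matrix(1, m, length(dmat$marker_ids)))
  } else {
    perm <- permute_t2_matrix(dmat, m)
  }
  core <- optpdt_from_perm(obs, perm, thresholds, estimator)
  structure(
    c(core,
      list(
        set_name = attr(dmat, "set_name") %||% NA_character_,
        n_families = length(dmat$family_ids),
        n_markers = length(dmat$marker_ids),
        n_informative_families = sum(rowSums(dmat$mask) > 0),
        untestable = !testable,
        markers = tibble::tibble(marker_id = dmat$marker_ids,
                                 n_informative = obs$n_informative,
                                 t2 = obs$t2, p = obs$p),
        seed = seed
      )),
    class = "optpdt_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' @export
print.optpdt_fit <- function(x, ...) {
  cat("<optpdt_fit> ", x$n_markers, " markers, ", x$n_families,
      " families, m = ", x$m, " permutations\n", sep = "")
  best <- which.max(ifelse(x$thresholds$available, x$thresholds$z, -Inf))
  if (length(best) && any(x$thresholds$available)) {
    cat("  selected threshold: ", x$thresholds$threshold[best], " (",
        x$thresholds$n_selected[best], " markers)\n", sep = "")
  }
  cat("  M = ", format(x$statistic, digits = 4), ", p = ",
      format(x$p, digits = 4),
      if (x$p == 0) paste0(" (< ", format(x$p_min, digits = 3), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 17016)
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  if (!is.numeric(n_tests) || n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}
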