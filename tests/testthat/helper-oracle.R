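# Independent oracles, written before the engine and kept free of the
# package's internals: naive per-marker statistics, allele-level triad
# scoring, and exhaustive enumeration of the sign-flip null.

# Naive single-SNP statistic from a (values, mask) pair at one marker.
oracle_marker_stat <- function(d, informative) {
  d <- d[informative]
  ss <- sum(d^2)
  if (length(d) == 0 || ss == 0) return(list(t2 = 0, p = 1))
  t2 <- sum(d)^2 / ss
  list(t2 = t2, p = pchisq(t2, df = 1, lower.tail = FALSE))
}

oracle_set_stats <- function(values, mask) {
  st <- lapply(seq_len(ncol(values)),
               function(j) oracle_marker_stat(values[, j], mask[, j]))
  list(t2 = vapply(st, `[[`, numeric(1), "t2"),
       p = vapply(st, `[[`, numeric(1), "p"))
}

oracle_y <- function(st, thresholds) {
  vapply(thresholds, function(k) sum(st$t2[st$p < k]), numeric(1))
}

# Exact variable-threshold permutation p-value by enumerating all 2^N
# family sign vectors (empty selections contribute Y = 0; degenerate
# thresholds are dropped from the max; all-empty observed selection gives
# p = 1 -- the same conventions the engine documents).
oracle_exact_optpdt <- function(values, mask, thresholds) {
  n_fam <- nrow(values)
  stopifnot(n_fam <= 16)
  n_vec <- 2^n_fam
  ys <- matrix(0, n_vec, length(thresholds))
  for (v in seq_len(n_vec) - 1L) {
    s <- ifelse(bitwAnd(v, 2^(seq_len(n_fam) - 1L)) > 0L, -1, 1)
    ys[v + 1L, ] <- oracle_y(oracle_set_stats(s * values, mask),
                             thresholds)
  }
  mu <- colMeans(ys)
  sg <- apply(ys, 2, sd)
  avail <- is.finite(sg) & sg > 0
  obs_st <- oracle_set_stats(values, mask)
  y_obs <- oracle_y(obs_st, thresholds)
  n_sel <- vapply(thresholds, function(k) sum(obs_st$p < k), numeric(1))
  if (!any(avail) || all(n_sel == 0)) return(1)
  z_obs <- (y_obs[avail] - mu[avail]) / sg[avail]
  m_obs <- max(z_obs)
  zs <- sweep(sweep(ys[, avail, drop = FALSE], 2, mu[avail], "-"),
              2, sg[avail], "/")
  m_j <- apply(zs, 1, max)
  # same tie convention as the engine: exact-arithmetic ties count even if
  # floating-point rounding separates them by a few ulps
  mean(m_j >= m_obs - 1e-8 * max(1, abs(m_obs)))
}

# Allele-level triad scoring: parents and child as explicit allele pairs,
# with the transmitted pair known by construction. Returns the score both
# for the true transmission and with transmitted/untransmitted swapped.
oracle_triad_transmission <- function(counted = "C", other = "A") {
  father <- sample(c(counted, other), 2, replace = TRUE)
  mother <- sample(c(counted, other), 2, replace = TRUE)
  tf <- sample(1:2, 1)                  # which paternal allele transmits
  tm <- sample(1:2, 1)
  transmitted <- c(father[tf], mother[tm])
  untransmitted <- c(father[3 - tf], mother[3 - tm])
  x_t <- sum(transmitted == counted) - sum(untransmitted == counted)
  list(
    father_code = sum(father == counted),
    mother_code = sum(mother == counted),
    child_code = sum(transmitted == counted),
    x_t = x_t,
    x_t_swapped = sum(untransmitted == counted) -
      sum(transmitted == counted),
    informative = sum(father == counted) == 1 || sum(mother == counted) == 1
  )
}
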