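#' Transmission score for one parent-child triad
#'
#' Scores one affected child with two genotyped parents at a biallelic SNP:
#' the number of counted alleles transmitted to the child minus the number
#' not transmitted, over both parental meioses. With genotypes coded as
#' counts of the counted allele, this is `2*child - father - mother`. The
#' triad is informative when at least one parent is heterozygous.
#'
#' @param father,mother,child Genotype codes in `{0, 1, 2}` (copies of the
#'   counted allele), or `NA` for missing.
#' @return Tibble with one row: `informative`, `x_t`, and `mendelian_error`.
#'   A triad with a missing genotype is not a triad (`informative = FALSE`);
#'   a Mendelian-inconsistent triad is excluded the same way but flagged.
#' @examples
#' triad_score(1, 2, 2)  # het father, hom mother -> informative, x_t = +1
#' triad_score(1, 1, 0)  # both het, child hom absent -> x_t = -2
#' @export
triad_score <- function(father, mother, child) {
  s <- triad_score_vec(father, mother, child)
  tibble::tibble(informative = s$informative, x_t = s$x_t,
                 mendelian_error = s$mendel)
}

# Vectorised over markers; inputs are equal-length genotype-code vectors.
triad_score_vec <- function(father, mother, child) {
  complete <- !is.na(father) & !is.na(mother) & !is.na(child)
  f <- ifelse(complete, father, 0L)
  m <- ifelse(complete, mother, 0L)
  cc <- ifelse(complete, child, 0L)
  c_min <- (f == 2L) + (m == 2L)
  c_max <- 2L - (f == 0L) - (m == 0L)
  consistent <- complete & cc >= c_min & cc <= c_max
  informative <- consistent & (f == 1L | m == 1L)
  x_t <- ifelse(informative, 2L * cc - f - m, 0L)
  list(informative = informative, x_t = as.integer(x_t),
       mendel = complete & !consistent)
}

#' Discordance score for one affected/unaffected sib pair
#'
#' Counted-allele count in the affected sibling minus the count in the
#' unaffected sibling. The pair is informative (a discordant sib pair, DSP)
#' when both genotypes are observed and differ.
#'
#' @param affected,unaffected Genotype codes in `{0, 1, 2}` or `NA`.
#' @return Tibble with one row: `informative`, `x_s`.
#' @examples
#' dsp_score(2, 0)  # -> informative, x_s = +2
#' dsp_score(1, 2)  # -> informative, x_s = -1
#' @export
dsp_score <- function(affected, unaffected) {
  s <- dsp_score_vec(affected, unaffected)
  tibble::tibble(informative = s$informative, x_s = s$x_s)
}

dsp_score_vec <- function(affected, unaffected) {
  complete <- !is.na(affected) & !is.na(unaffected)
  informative <- complete & affected != unaffected
  x_s <- ifelse(informative, affected - unaffected, 0L)
  list(informative = informative, x_s = as.integer(x_s))
}

# Per-family transmission summary at every marker (or a subset).
# Returns, per marker: n_t, n_s, x_t, x_s, d, informative, n_mendel.
score_family <- function(study, fam, marker_idx) {
  G <- study$genotypes
  nm <- length(marker_idx)
  father <- if (!is.na(fam$father)) G[fam$father, marker_idx] else
    rep(NA_integer_, nm)
  mother <- if (!is.na(fam$mother)) G[fam$mother, marker_idx] else
    rep(NA_integer_, nm)
  aff_rows <- fam$children[fam$affected %in% TRUE]
  unaff_rows <- fam$children[fam$affected %in% FALSE]
  n_t <- x_t <- n_s <- x_s <- integer(nm)
  n_mendel <- integer(nm)
  for (a in aff_rows) {
    s <- triad_score_vec(father, mother, G[a, marker_idx])
    n_t <- n_t + s$informative
    x_t <- x_t + s$x_t
    n_mendel <- n_mendel + s$mendel
  }
  # every affected x unaffected pairing forms a DSP
  for (a in aff_rows) {
    ga <- G[a, marker_idx]
    for (u in unaff_rows) {
      s <- dsp_score_vec(ga, G[u, marker_idx])
      n_s <- n_s + s$informative
      x_s <- x_s + s$x_s
    }
  }
  den <- n_t + n_s
  list(n_t = n_t, n_s = n_s, x_t = x_t, x_s = x_s,
       d = ifelse(den > 0L, (x_t + x_s) / den, 0),
       informative = den > 0L, n_mendel = n_mendel)
}

#' Per-family transmission summaries
#'
#' Computes, for every nuclear family and marker, the triad and discordant
#' sib pair (DSP) counts and score sums, and the family's per-marker PDT
#' contribution `d = (x_t + x_s) / (n_t + n_s)`.
#'
#' @param study A [family_study()].
#' @param markers Optional character vector of marker ids (default: all).
#' @return Tibble with columns `family_id`, `marker_id`, `n_t`, `n_s`,
#'   `x_t`, `x_s`, `d`, `informative`, `n_mendel_errors`. `d` is `NA` for
#'   uninformative family-marker cells.
#' @export
family_scores <- function(study, markers = NULL) {
  stopifnot(inherits(study, "family_study"))
  idx <- match_markers(study, markers)
  purrr::map_dfr(study$families, function(fam) {
    s <- score_family(study, fam, idx)
    tibble::tibble(
      family_id = fam$family_id,
      marker_id = study$markers$id[idx],
      n_t = s$n_t, n_s = s$n_s, x_t = s$x_t, x_s = s$x_s,
      d = ifelse(s$informative, s$d, NA_real_),
      informative = s$informative,
      n_mendel_errors = s$n_mendel
    )
  })
}

match_markers <- function(study, markers) {
  if (is.null(markers)) return(seq_len(nrow(study$markers)))
  idx <- match(markers, study$markers$id)
  if (anyNA(idx)) {
    stop("unknown marker(s): ",
         paste(utils::head(markers[is.na(idx)], 5), collapse = ", "))
  }
  idx
}

#' Families-by-markers matrix of PDT contributions
#'
#' Builds the substrate of the sign-flip permutation procedure: one row per
#' nuclear family, one column per marker, each informative cell holding the
#' family's PDT contribution `D` (uninformative cells are masked and carry
#' zero so they never enter a sum).
#'
#' @inheritParams family_scores
#' @return An object of class `d_matrix`: list with `values` (numeric
#'   matrix, masked cells 0), `mask` (logical matrix, `TRUE` = informative),
#'   `family_ids`, `marker_ids`, and `n_mendel_errors` (per-marker tally of
#'   excluded Mendelian-inconsistent triads).
#' @export
d_matrix <- function(study, markers = NULL) {
  stopifnot(inherits(study, "family_study"))
  idx <- match_markers(study, markers)
  fams <- study$families
  n <- length(fams)
  nm <- length(idx)
  values <- matrix(0, n, nm)
  mask <- matrix(FALSE, n, nm)
  mendel <- integer(nm)
  for (i in seq_len(n)) {
    s <- score_family(study, fams[[i]], idx)
    values[i, ] <- ifelse(s$informative, s$d, 0)
    mask[i, ] <- s$informative
    mendel <- mendel + s$n_mendel
  }
  structure(
    list(values = values, mask = mask,
         family_ids = vapply(fams, `[[`, character(1), "family_id"),
         marker_ids = study$markers$id[idx],
         n_mendel_errors = mendel),
    class = "d_matrix"
  )
}

#' @export
print.d_matrix <- function(x, ...) {
  cat("<d_matrix> ", length(x$family_ids), " families x ",
      length(x$marker_ids), " markers; ",
      sum(x$mask), " informative cells\n", sep = "")
  invisible(x)
}

#' Single-SNP PDT statistic from per-family contributions
#'
#' The pedigree disequilibrium test statistic over `N` informative families,
#' `T2 = (sum D_i)^2 / sum D_i^2`, compared against a chi-square distribution
#' with 1 degree of freedom.
#'
#' @param d_values Numeric vector of per-family `D` contributions at one
#'   marker (informative families only).
#' @return Tibble with one row: `t2`, `p`, `n_informative`. An empty vector
#'   or one with zero sum of squares is untestable: `t2 = 0`, `p = 1`.
#' @examples
#' pdt_statistic(c(1, 1, 1, 1))  # t2 = 4
#' @export
pdt_statistic <- function(d_values) {
  d_values <- d_values[!is.na(d_values)]
  ss <- sum(d_values^2)
  if (length(d_values) == 0L || ss == 0) {
    t2 <- 0
    p <- 1
  } else {
    t2 <- sum(d_values)^2 / ss
    p <- stats::pchisq(t2, df = 1, lower.tail = FALSE)
  }
  tibble::tibble(t2 = t2, p = p, n_informative = length(d_values))
}

# Column-wise observed statistics for a d_matrix. Returns list(t2, p, ss).
marker_stats <- function(dmat) {
  ss <- colSums(dmat$values^2)
  cs <- colSums(dmat$values)
  testable <- ss > 0
  t2 <- ifelse(testable, cs^2 / ifelse(testable, ss, 1), 0)
  p <- ifelse(testable, stats::pchisq(t2, df = 1, lower.tail = FALSE), 1)
  list(t2 = t2, p = p, ss = ss, n_informative = colSums(dmat$mask))
}

#' Single-SNP PDT over all markers of a study
#'
#' @param x A [family_study()] or a [d_matrix()].
#' @param markers Optional marker ids (ignored when `x` is a `d_matrix`).
#' @return Tibble with one row per marker: `marker_id`, `n_informative`
#'   (families contributing), `t2`, `p`.
#' @export
pdt_test <- function(x, markers = NULL) {
  dmat <- if (inherits(x, "d_matrix")) x else d_matrix(x, markers)
  st <- marker_stats(dmat)
  tibble::tibble(marker_id = dmat$marker_ids,
                 n_informative = st$n_informative,
                 t2 = st$t2, p = st$p)
}
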