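#' Assemble a nuclear-family study
#'
#' A `family_study` bundles the three tables every analysis in this package
#' consumes: a marker table, a pedigree table and a genotype matrix coded as
#' counts of each marker's counted allele. Readers ([read_plink_text()],
#' [read_plink_binary()]) and the simulator ([simulate_study()]) return this
#' container; you rarely need to call the constructor yourself.
#'
#' @param markers Tibble with columns `id`, `chrom`, `pos`, `allele1`,
#'   `allele2`, `counted_allele`. `counted_allele` must equal `allele1` or
#'   `allele2`; genotype codes count copies of it.
#' @param pedigree Tibble with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`, `affected` (logical, `NA` = unknown).
#'   `"0"` in a parent column means no parent declared. Row order matches the
#'   rows of `genotypes`.
#' @param genotypes Integer matrix, individuals x markers, entries in
#'   `{0, 1, 2, NA}` (copies of the counted allele, `NA` = missing).
#' @param provenance Optional list recording source paths and format.
#'
#' @details
#' Only two-generation (nuclear) families are supported: an individual may be
#' a child or a parent within its family, never both, and all children of a
#' family must share the same declared parent pair. A declared parent absent
#' from the data (or present with all-missing genotypes) is treated as
#' ungenotyped, so such families contribute discordant sib pairs but no
#' parent-child triads.
#'
#' @return An object of class `family_study`.
#' @seealso [pdt_test()], [optpdt_test()], [d_matrix()]
#' @export
family_study <- function(markers, pedigree, genotypes,
                         provenance = list()) {
  markers <- tibble::as_tibble(markers)
  pedigree <- tibble::as_tibble(pedigree)
  need_m <- c("id", "chrom", "pos", "allele1", "allele2", "counted_allele")
  if (!all(need_m %in% names(markers))) {
    stop("markers must have columns: ", paste(need_m, collapse = ", "))
  }
  need_p <- c("family_id", "individual_id", "father_id", "mother_id",
              "sex", "affected")
  if (!all(need_p %in% names(pedigree))) {
    stop("pedigree must have columns: ", paste(need_p, collapse = ", "))
  }
  if (anyDuplicated(markers$id)) stop("duplicate marker ids")
  if (any(markers$pos < 1, na.rm = TRUE)) stop("marker positions must be >= 1")
  poly <- markers$allele1 != markers$allele2
  if (any(!poly & !is.na(markers$allele1) & markers$allele1 != "0")) {
    # monomorphic markers are representable (allele2 == "0") but two equal
    # non-missing alleles means a malformed table
    stop("markers with allele1 == allele2: ",
         paste(markers$id[!poly], collapse = ", "))
  }
  ok <- markers$counted_allele == markers$allele1 |
    markers$counted_allele == markers$allele2
  if (!all(ok)) stop("counted_allele must be one of the marker's alleles")
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != nrow(pedigree)) {
    stop("genotypes must have one row per pedigree individual")
  }
  if (ncol(genotypes) != nrow(markers)) {
    stop("genotypes must have one column per marker")
  }
  if (any(genotypes < 0L | genotypes > 2L, na.rm = TRUE)) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  key <- paste(pedigree$family_id, pedigree$individual_id, sep = ":")
  if (anyDuplicated(key)) {
    stop("duplicate individual: ", key[duplicated(key)][1])
  }
  rownames(genotypes) <- key
  colnames(genotypes) <- markers$id
  out <- structure(
    list(markers = markers, pedigree = pedigree, genotypes = genotypes,
         provenance = provenance),
    class = "family_study"
  )
  out$families <- build_family_index(out)
  out
}

# One record per nuclear family: pedigree/genotype row indices of father,
# mother (NA when absent) and children, plus affection flags. Rejects
# three-generation pedigrees and mixed parent pairs.
build_family_index <- function(study) {
  ped <- study$pedigree
  is_child <- ped$father_id != "0" | ped$mother_id != "0"
  fams <- unique(ped$family_id)
  idx <- vector("list", length(fams))
  names(idx) <- fams
  row_of <- stats::setNames(seq_len(nrow(ped)),
                            paste(ped$family_id, ped$individual_id, sep = ":"))
  for (f in fams) {
    in_f <- which(ped$family_id == f)
    kids <- in_f[is_child[in_f]]
    if (length(kids) == 0L) next
    fid <- unique(ped$father_id[kids])
    mid <- unique(ped$mother_id[kids])
    if (length(fid) > 1L || length(mid) > 1L) {
      stop("family ", f, ": children declare more than one parent pair; ",
           "only nuclear families are supported")
    }
    father <- if (fid == "0") NA_integer_ else
      unname(row_of[paste(f, fid, sep = ":")])
    mother <- if (mid == "0") NA_integer_ else
      unname(row_of[paste(f, mid, sep = ":")])
    if (!is.na(father) && is_child[father] ||
        !is.na(mother) && is_child[mother]) {
      stop("family ", f, ": a declared parent is itself a child; ",
           "pedigrees deeper than two generations are not supported")
    }
    one_missing <- xor(is.na(father) && fid != "0",
                       is.na(mother) && mid != "0")
    if (one_missing) {
      warning("family ", f, ": exactly one declared parent is present in ",
              "the data; the family is treated as having ungenotyped ",
              "parents for triad purposes", call. = FALSE)
    }
    idx[[f]] <- list(
      family_id = f,
      father = father,
      mother = mother,
      children = kids,
      affected = ped$affected[kids]
    )
  }
  idx[!vapply(idx, is.null, logical(1))]
}

#' @export
print.family_study <- function(x, ...) {
  n_fam <- length(x$families)
  n_aff <- sum(vapply(x$families, function(f) sum(f$affected %in% TRUE),
                      integer(1)))
  cat("<family_study> ", nrow(x$pedigree), " individuals in ", n_fam,
      " nuclear families, ", nrow(x$markers), " markers\n", sep = "")
  cat("  affected children: ", n_aff, "; missing genotypes: ",
      sum(is.na(x$genotypes)), "\n", sep = "")
  invisible(x)
}

#' Count missing genotypes per marker
#'
#' @param study A [family_study()].
#' @return Tibble with `marker_id` and `n_missing`.
#' @export
missing_counts <- function(study) {
  stopifnot(inherits(study, "family_study"))
  tibble::tibble(
    marker_id = study$markers$id,
    n_missing = unname(colSums(is.na(study$genotypes)))
  )
}
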