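# Fixture builders used across the test files. Everything is constructed in
# code at test time; no stored binary data.

marker_table <- function(n, prefix = "m") {
  tibble::tibble(
    id = paste0(prefix, seq_len(n)),
    chrom = "1",
    pos = seq_len(n) * 100L,
    allele1 = "A",          # major
    allele2 = "C",          # minor = counted
    counted_allele = "C"
  )
}

# A study from explicit genotype rows. `fams` is a list of lists with
# elements: father, mother (genotype vectors or NULL for an absent parent),
# children (list of genotype vectors), affected (logical vector).
build_study <- function(fams, n_markers) {
  ped <- list()
  rows <- list()
  for (i in seq_along(fams)) {
    f <- fams[[i]]
    fid <- paste0("F", i)
    has_father <- !is.null(f$father)
    has_mother <- !is.null(f$mother)
    if (has_father) {
      ped[[length(ped) + 1]] <- list(fid, "1", "0", "0", 1L, NA)
      rows[[length(rows) + 1]] <- f$father
    }
    if (has_mother) {
      ped[[length(ped) + 1]] <- list(fid, "2", "0", "0", 2L, NA)
      rows[[length(rows) + 1]] <- f$mother
    }
    for (k in seq_along(f$children)) {
      ped[[length(ped) + 1]] <- list(fid, as.character(2L + k),
                                     if (has_father) "1" else "9",
                                     if (has_mother) "2" else "8",
                                     1L, f$affected[k])
      rows[[length(rows) + 1]] <- f$children[[k]]
    }
  }
  pedigree <- purrr::map_dfr(ped, function(r) {
    tibble::tibble(family_id = r[[1]], individual_id = r[[2]],
                   father_id = r[[3]], mother_id = r[[4]],
                   sex = r[[5]], affected = r[[6]])
  })
  geno <- do.call(rbind, rows)
  suppressWarnings(
    family_study(marker_table(n_markers), pedigree, geno)
  )
}

# The worked nuclear family: parents het x hom-counted, one affected
# hom-counted child, two unaffected het children. D = 1 at the single SNP.
worked_family_study <- function() {
  build_study(list(list(
    father = 1L, mother = 2L,
    children = list(2L, 1L, 1L),
    affected = c(TRUE, FALSE, FALSE)
  )), n_markers = 1)
}

# Random nuclear-family study via honest gene dropping at independent
# markers: parents draw alleles Bernoulli(maf), children inherit one allele
# from each parent. Used for invariance property tests.
random_study <- function(n_fam = 8, n_markers = 3, maf = 0.4,
                         n_children = 2) {
  fams <- lapply(seq_len(n_fam), function(i) {
    fa <- matrix(rbinom(2 * n_markers, 1, maf), 2)  # rows = 2 haplotypes
    mo <- matrix(rbinom(2 * n_markers, 1, maf), 2)
    kids <- lapply(seq_len(n_children), function(k) {
      fa[sample(1:2, 1), ] + mo[sample(1:2, 1), ]
    })
    aff <- c(TRUE, sample(c(TRUE, FALSE), n_children - 1, replace = TRUE))
    list(father = colSums(fa), mother = colSums(mo),
         children = kids, affected = aff)
  })
  build_study(fams, n_markers)
}

# Swap which allele is counted at every marker: genotype codes g -> 2 - g.
flip_counted <- function(study) {
  mk <- study$markers
  tmp <- mk$allele1
  mk$allele1 <- mk$allele2
  mk$allele2 <- tmp
  mk$counted_allele <- mk$allele1
  g <- 2L - study$genotypes
  family_study(mk, study$pedigree, g, provenance = study$provenance)
}

# Random d_matrix fixtures for the permutation oracle tests.
random_d_matrix <- function(n_fam, n_markers) {
  vals <- matrix(sample(c(-2, -1, -2 / 3, -1 / 3, 1 / 3, 2 / 3, 1, 2),
                        n_fam * n_markers, replace = TRUE),
                 n_fam, n_markers)
  mask <- matrix(runif(n_fam * n_markers) < 0.9, n_fam, n_markers)
  vals[!mask] <- 0
  structure(
    list(values = vals, mask = mask,
         family_ids = paste0("F", seq_len(n_fam)),
         marker_ids = paste0("m", seq_len(n_markers)),
         n_mendel_errors = integer(n_markers)),
    class = "d_matrix"
  )
}
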