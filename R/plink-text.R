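# Shared assembly: turn parsed PED fields + a marker table into a
# family_study. `alleles` is a 2-column character matrix per marker pair.
assemble_study <- function(ped6, allele_a, allele_b, markers, provenance) {
  nm <- nrow(markers)
  n_ind <- nrow(ped6)
  geno <- matrix(NA_integer_, n_ind, nm)
  allele1 <- character(nm)
  allele2 <- character(nm)
  counted <- character(nm)
  for (j in seq_len(nm)) {
    a <- allele_a[, j]
    b <- allele_b[, j]
    obs <- c(a, b)
    obs <- obs[obs != "0"]
    lev <- sort(unique(obs))
    if (length(lev) > 2L) {
      stop("marker ", markers$id[j], " is not biallelic (alleles: ",
           paste(lev, collapse = ", "), ")")
    }
    if (length(lev) == 0L) {            # fully missing marker
      allele1[j] <- "0"; allele2[j] <- "0"; counted[j] <- "0"
      next
    }
    if (length(lev) == 1L) {            # monomorphic: counted allele absent
      allele1[j] <- lev; allele2[j] <- "0"; counted[j] <- lev
      geno[, j] <- ifelse(a == "0" | b == "0", NA_integer_, 2L)
      next
    }
    freq1 <- sum(obs == lev[1]) / length(obs)
    minor <- if (freq1 <= 0.5) lev[1] else lev[2]
    major <- setdiff(lev, minor)
    allele1[j] <- major
    allele2[j] <- minor
    counted[j] <- minor                 # counted allele = sample minor allele
    geno[, j] <- ifelse(a == "0" | b == "0", NA_integer_,
                        (a == minor) + (b == minor))
  }
  markers$allele1 <- allele1
  markers$allele2 <- allele2
  markers$counted_allele <- counted
  pheno <- ped6[[6]]
  pedigree <- tibble::tibble(
    family_id = ped6[[1]], individual_id = ped6[[2]],
    father_id = ped6[[3]], mother_id = ped6[[4]],
    sex = suppressWarnings(as.integer(ped6[[5]])),
    affected = dplyr::case_when(pheno == "2" ~ TRUE, pheno == "1" ~ FALSE,
                                TRUE ~ NA)
  )
  family_study(markers, pedigree, geno, provenance = provenance)
}

read_map <- function(map_path) {
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character")
  if (!ncol(map) %in% c(3L, 4L)) {
    stop("MAP file must have 3 or 4 columns, found ", ncol(map))
  }
  tibble::tibble(
    id = map[[2]],
    chrom = map[[1]],
    pos = as.integer(map[[ncol(map)]]),
    allele1 = NA_character_, allele2 = NA_character_,
    counted_allele = NA_character_
  )
}

#' Read a PLINK text fileset (PED/MAP)
#'
#' Individuals are grouped into nuclear families by family id and parent
#' pointers; `0` alleles become missing genotypes; each marker's counted
#' allele defaults to its minor allele by sample frequency (the PDT
#' statistic is invariant to this orientation).
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @return A [family_study()].
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  markers <- read_map(map_path)
  nm <- nrow(markers)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * nm
  len <- lengths(toks)
  if (any(len != want)) {
    bad <- which(len != want)[1]
    stop("PED line ", bad, ": expected ", want, " fields, found ",
         len[bad])
  }
  tk <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
  ped6 <- as.data.frame(tk[, 1:6, drop = FALSE],
                        stringsAsFactors = FALSE)
  allele_a <- tk[, 6L + 2L * seq_len(nm) - 1L, drop = FALSE]
  allele_b <- tk[, 6L + 2L * seq_len(nm), drop = FALSE]
  assemble_study(ped6, allele_a, allele_b, markers,
                 provenance = list(format = "ped/map",
                                   ped = ped_path, map = map_path))
}

#' Write a PLINK text fileset (PED/MAP)
#'
#' Genotype codes are expanded back to allele pairs (missing becomes
#' `0 0`); affection is written as 2/1/0 (affected/unaffected/unknown).
#'
#' @param study A [family_study()].
#' @param prefix Output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return The two paths, invisibly.
#' @export
write_plink_text <- function(study, prefix) {
  stopifnot(inherits(study, "family_study"))
  mk <- study$markers
  map <- data.frame(chrom = mk$chrom, id = mk$id, cm = 0, pos = mk$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  other <- ifelse(mk$counted_allele == mk$allele1, mk$allele2, mk$allele1)
  other[other == "0" | is.na(other)] <- mk$counted_allele[other == "0" |
                                                            is.na(other)]
  n <- nrow(study$pedigree)
  nm <- nrow(mk)
  G <- study$genotypes
  a <- matrix("0", n, nm)
  b <- matrix("0", n, nm)
  for (j in seq_len(nm)) {
    gj <- G[, j]
    a[, j] <- ifelse(is.na(gj), "0",
                     ifelse(gj >= 1L, mk$counted_allele[j], other[j]))
    b[, j] <- ifelse(is.na(gj), "0",
                     ifelse(gj == 2L, mk$counted_allele[j], other[j]))
  }
  inter <- matrix("", n, 2L * nm)
  inter[, 2L * seq_len(nm) - 1L] <- a
  inter[, 2L * seq_len(nm)] <- b
  ped <- study$pedigree
  pheno <- ifelse(is.na(ped$affected), "0", ifelse(ped$affected, "2", "1"))
  out <- cbind(ped$family_id, ped$individual_id, ped$father_id,
               ped$mother_id, as.character(ped$sex), pheno, inter)
  writeLines(apply(out, 1, paste, collapse = " "), paste0(prefix, ".ped"))
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}
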