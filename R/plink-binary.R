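# PLINK binary genotype codec (SNP-major v1.00). Two bits per individual,
# least-significant bits first within each byte; each marker's block is
# padded to a whole byte. Code (high bit, low bit): 00 = 0 copies of the
# counted (BIM column-5) allele, 01 = missing, 10 = 1 copy, 11 = 2 copies.
bed_magic <- function() as.raw(c(0x6c, 0x1b, 0x01))

decode_bed_payload <- function(payload, n_ind, n_markers) {
  bpm <- ceiling(n_ind / 4)            # bytes per marker
  if (length(payload) != bpm * n_markers) {
    stop("BED payload is corrupt: expected ", bpm * n_markers,
         " bytes for ", n_ind, " individuals x ", n_markers,
         " markers, found ", length(payload))
  }
  bits <- matrix(as.integer(rawToBits(payload)), nrow = 8L * bpm)
  low <- bits[seq(1L, 8L * bpm, by = 2L), , drop = FALSE]
  high <- bits[seq(2L, 8L * bpm, by = 2L), , drop = FALSE]
  code <- low[seq_len(n_ind), , drop = FALSE] +
    2L * high[seq_len(n_ind), , drop = FALSE]
  geno <- matrix(c(0L, NA_integer_, 1L, 2L)[code + 1L], n_ind, n_markers)
  geno
}

encode_bed_payload <- function(geno) {
  n_ind <- nrow(geno)
  n_markers <- ncol(geno)
  bpm <- ceiling(n_ind / 4)
  code <- matrix(1L, 4L * bpm, n_markers)      # pad slots encode "missing"
  code[seq_len(n_ind), ] <- ifelse(is.na(geno), 1L,
                                   c(0L, 2L, 3L)[geno + 1L])
  code[is.na(code)] <- 1L
  bits <- integer(8L * bpm * n_markers)
  bits[seq(1L, length(bits), by = 2L)] <- as.vector(code) %% 2L
  bits[seq(2L, length(bits), by = 2L)] <- as.vector(code) %/% 2L
  packBits(as.integer(bits) > 0L, type = "raw")
}

#' Read a PLINK binary fileset (BED/BIM/FAM)
#'
#' Returns the same study representation as [read_plink_text()]. The BIM
#' column-5 allele is taken as each marker's counted allele; genotype codes
#' count its copies.
#'
#' @param bed_path,bim_path,fam_path Paths to the three files.
#' @return A [family_study()].
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path) {
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  bim <- utils::read.table(bim_path, header = FALSE,
                           colClasses = "character")
  if (ncol(bim) != 6L) stop("BIM file must have 6 columns")
  markers <- tibble::tibble(
    id = bim[[2]], chrom = bim[[1]], pos = as.integer(bim[[4]]),
    allele1 = bim[[6]], allele2 = bim[[5]], counted_allele = bim[[5]]
  )
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = "character")
  if (ncol(fam) != 6L) stop("FAM file must have 6 columns")
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || !identical(raw[1:2], bed_magic()[1:2])) {
    stop("not a PLINK BED file (bad magic bytes): ", bed_path)
  }
  if (raw[3] != bed_magic()[3]) {
    stop("only SNP-major (mode 0x01) BED files are supported")
  }
  geno <- decode_bed_payload(raw[-(1:3)], nrow(fam), nrow(markers))
  pheno <- fam[[6]]
  pedigree <- tibble::tibble(
    family_id = fam[[1]], individual_id = fam[[2]],
    father_id = fam[[3]], mother_id = fam[[4]],
    sex = suppressWarnings(as.integer(fam[[5]])),
    affected = dplyr::case_when(pheno == "2" ~ TRUE, pheno == "1" ~ FALSE,
                                TRUE ~ NA)
  )
  family_study(markers, pedigree, geno,
               provenance = list(format = "bed/bim/fam", bed = bed_path,
                                 bim = bim_path, fam = fam_path))
}

#' Write a PLINK binary fileset (BED/BIM/FAM)
#'
#' @param study A [family_study()].
#' @param prefix Output path prefix; writes `<prefix>.bed`, `.bim`, `.fam`.
#' @return The three paths, invisibly.
#' @export
write_plink_binary <- function(study, prefix) {
  stopifnot(inherits(study, "family_study"))
  mk <- study$markers
  other <- ifelse(mk$counted_allele == mk$allele1, mk$allele2, mk$allele1)
  bim <- data.frame(chrom = mk$chrom, id = mk$id, cm = 0, pos = mk$pos,
                    a1 = mk$counted_allele, a2 = other)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ped <- study$pedigree
  pheno <- ifelse(is.na(ped$affected), "0", ifelse(ped$affected, "2", "1"))
  fam <- data.frame(ped$family_id, ped$individual_id, ped$father_id,
                    ped$mother_id, ped$sex, pheno)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(bed_magic(), con)
  writeBin(encode_bed_payload(study$genotypes), con)
  invisible(c(bed = paste0(prefix, ".bed"), bim = paste0(prefix, ".bim"),
              fam = paste0(prefix, ".fam")))
}
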