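#' Read SNP-set definitions
#'
#' Supports two dialects, autodetected from the first line unless `format`
#' is given: the PLINK `--set` format (a set name, its member marker ids,
#' terminated by an `END` token) and a two-column `gene<TAB>marker` table.
#' Marker ids absent from `markers` are dropped; sets left empty are
#' removed with a warning.
#'
#' @param set_path Path to the set file.
#' @param markers Character vector of known marker ids (e.g.
#'   `study$markers$id`), or a [family_study()].
#' @param format `"auto"`, `"set"` or `"tsv"`.
#' @return Named list of character vectors of marker ids, in file order,
#'   with attribute `n_dropped_sets`.
#' @export
read_snp_sets <- function(set_path, markers,
                          format = c("auto", "set", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(set_path)) stop("set file not found: ", set_path)
  if (inherits(markers, "family_study")) markers <- markers$markers$id
  lines <- readLines(set_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("set file is empty: ", set_path)
  if (format == "auto") {
    first <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
    format <- if (length(first) == 2L && !any(lines == "END")) "tsv"
      else "set"
  }
  sets <- if (format == "tsv") {
    toks <- strsplit(trimws(lines), "[ \t]+")
    if (any(lengths(toks) != 2L)) {
      bad <- which(lengths(toks) != 2L)[1]
      stop("line ", bad, ": a gene map line must have 2 columns")
    }
    gene <- vapply(toks, `[[`, character(1), 1L)
    snp <- vapply(toks, `[[`, character(1), 2L)
    split(snp, factor(gene, levels = unique(gene)))
  } else {
    toks <- unlist(strsplit(trimws(lines), "[ \t]+"))
    out <- list()
    cur <- NULL
    members <- character(0)
    for (tk in toks) {
      if (is.null(cur)) {
        cur <- tk
        members <- character(0)
      } else if (tk == "END") {
        if (cur %in% names(out)) stop("duplicate set name: ", cur)
        out[[cur]] <- members
        cur <- NULL
      } else {
        members <- c(members, tk)
      }
    }
    if (!is.null(cur)) {
      stop("unterminated set block: ", cur, " (missing END)")
    }
    out
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate set name: ", names(sets)[duplicated(names(sets))][1])
  }
  sets <- purrr::imap(sets, function(ids, nm) {
    ids <- unique(ids)
    keep <- ids[ids %in% markers]
    if (length(keep) < length(ids)) {
      warning("set ", nm, ": dropped ", length(ids) - length(keep),
              " unknown marker(s)", call. = FALSE)
    }
    keep
  })
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty)) {
    warning(sum(empty), " empty set(s) dropped: ",
            paste(names(sets)[empty], collapse = ", "), call. = FALSE)
    sets <- sets[!empty]
  }
  attr(sets, "n_dropped_sets") <- sum(empty)
  sets
}

#' Assign markers to genes by position
#'
#' A marker belongs to a gene when its position lies within the gene's
#' 1-based closed interval `[start - padding, end + padding]` on the same
#' chromosome.
#'
#' @param markers Tibble with `id`, `chrom`, `pos` (a study's `markers`
#'   table works directly).
#' @param annotation Tibble with columns `gene`, `chrom`, `start`, `end`.
#' @param padding Flanking distance in base pairs added to both ends
#'   (default 0).
#' @return Named list of marker-id vectors, one per gene with at least one
#'   marker, in annotation order.
#' @export
snp_sets_from_annotation <- function(markers, annotation, padding = 0) {
  if (inherits(markers, "family_study")) markers <- markers$markers
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(annotation)))
  sets <- lapply(seq_len(nrow(annotation)), function(i) {
    g <- annotation[i, ]
    hit <- markers$chrom == as.character(g$chrom) &
      markers$pos >= g$start - padding & markers$pos <= g$end + padding
    markers$id[hit]
  })
  names(sets) <- annotation$gene
  sets[lengths(sets) > 0L]
}
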