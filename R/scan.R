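# Deterministic 31-bit hash of a string; used to derive per-set RNG streams
# so results do not depend on execution order or worker count.
stable_hash <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 2147483629
  as.integer(h)
}

derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) + stable_hash(label)) %% 2147483629 + 1)
}

#' Run the optimal-threshold PDT over many SNP sets
#'
#' Applies [optpdt_test()] to each SNP set (typically one set per gene).
#' Each set draws its permutations from an RNG stream derived
#' deterministically from `seed` and the set name, so the results table is
#' identical for any worker count or set order.
#'
#' @param study A [family_study()].
#' @param sets Named list of character vectors of marker ids (as returned
#'   by [read_snp_sets()]), or a tibble with columns `set` and `marker_id`.
#' @inheritParams optpdt_test
#' @param seed Integer seed for the whole scan.
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @return Tibble with one row per set: `set`, `n_markers`, `n_selected`,
#'   `best_threshold`, `statistic` (M), `p`, `p_min`, `m`, plus one
#'   `z_<threshold>` column per threshold.
#' @export
optpdt_scan <- function(study, sets, thresholds = default_thresholds(),
                        m = 2000, seed = 1, workers = 1,
                        estimator = c("plugin", "add-one")) {
  estimator <- match.arg(estimator)
  sets <- as_set_list(sets)
  if (length(sets) == 0L) return(empty_scan_tibble(thresholds))
  known <- intersect(unlist(sets), study$markers$id)
  sets <- purrr::imap(sets, function(ids, nm) {
    keep <- ids[ids %in% known]
    if (length(keep) < length(ids)) {
      warning("set ", nm, ": dropped ", length(ids) - length(keep),
              " marker(s) absent from the study", call. = FALSE)
    }
    keep
  })
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty)) {
    warning(sum(empty), " set(s) had no markers in the study and were ",
            "dropped", call. = FALSE)
    sets <- sets[!empty]
  }
  if (length(sets) == 0L) return(empty_scan_tibble(thresholds))
  run_one <- function(nm) {
    fit <- optpdt_test(study, set = sets[[nm]], thresholds = thresholds,
                       m = m, seed = derive_seed(seed, nm),
                       estimator = estimator)
    fit$set_name <- nm
    glance(fit)
  }
  nms <- names(sets)
  rows <- if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(nms, run_one, mc.cores = workers)
  } else {
    lapply(nms, run_one)
  }
  dplyr::bind_rows(rows)
}

as_set_list <- function(sets) {
  if (is.list(sets) && !is.data.frame(sets) && length(sets) == 0L) {
    return(list())
  }
  if (is.data.frame(sets)) {
    stopifnot(all(c("set", "marker_id") %in% names(sets)))
    return(split(sets$marker_id, factor(sets$set, levels = unique(sets$set))))
  }
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop("sets must be a named list of marker-id vectors or a ",
         "set/marker_id tibble")
  }
  sets
}

empty_scan_tibble <- function(thresholds) {
  out <- tibble::tibble(
    set = character(), n_markers = integer(), n_selected = integer(),
    best_threshold = numeric(), statistic = numeric(), p = numeric(),
    p_min = numeric(), m = integer()
  )
  for (k in check_thresholds(thresholds)) out[[z_col(k)]] <- numeric()
  out
}

z_col <- function(threshold) paste0("z_", format(threshold, trim = TRUE))

#' Write a scan results table
#'
#' Tab-separated output with a header row, one row per set in input order,
#' p-values in scientific notation, and a `p_display` column that renders an
#' exact zero as the "< 1/m" resolution bound of the permutation estimate.
#'
#' @param results Tibble from [optpdt_scan()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- as.data.frame(results)
  list_cols <- vapply(out, is.list, logical(1))
  out <- out[!list_cols]
  if (nrow(out) > 0 && all(c("p", "p_min") %in% names(out))) {
    out$p_display <- ifelse(out$p == 0,
                            paste0("< ", format(out$p_min, digits = 3)),
                            format(out$p, digits = 4, scientific = TRUE))
    num <- vapply(out, is.numeric, logical(1)) & names(out) %in%
      c("p", "p_min")
    for (j in which(num)) {
      out[[j]] <- format(out[[j]], digits = 4, scientific = TRUE)
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) {
    stop("cannot write results to ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}
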