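write_lines_tmp <- function(lines, ext) {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("PED/MAP parsing maps alleles, families and missingness", {
  map <- write_lines_tmp(c("1\tm1\t0\t100"), ".map")
  ped <- write_lines_tmp(c(
    "F1 1 0 0 1 1  1 1",
    "F1 2 0 0 2 1  1 2",
    "F1 3 1 2 1 2  1 1",
    "F1 4 1 2 2 1  0 0"
  ), ".ped")
  study <- read_plink_text(ped, map)
  expect_length(study$families, 1)
  fam <- study$families[[1]]
  expect_length(fam$children, 2)        # two sibs -> one nuclear family
  # allele "2" is the minor allele by sample frequency, so it is counted;
  # the affected child is hom "1" = 0 copies of the counted allele
  expect_equal(study$markers$counted_allele, "2")
  expect_equal(unname(study$genotypes[, 1]), c(0L, 1L, 0L, NA))
  expect_identical(study$pedigree$affected, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(missing_counts(study)$n_missing, 1)
})

test_that("malformed PED rows and non-biallelic markers are rejected", {
  map <- write_lines_tmp(c("1\tm1\t0\t100"), ".map")
  bad <- write_lines_tmp(c("F1 1 0 0 1 1  1"), ".ped")
  expect_error(read_plink_text(bad, map), "line 1")
  tri <- write_lines_tmp(c(
    "F1 1 0 0 1 1  A C",
    "F1 2 0 0 2 1  G G"
  ), ".ped")
  expect_error(read_plink_text(tri, map), "not biallelic")
})

test_that("a lone declared parent present in the data triggers a warning", {
  map <- write_lines_tmp(c("1\tm1\t0\t100"), ".map")
  ped <- write_lines_tmp(c(
    "F1 1 0 0 1 1  1 2",
    "F1 3 1 2 1 2  1 1"
  ), ".ped")
  expect_warning(read_plink_text(ped, map), "one declared parent")
})

test_that("three-generation pedigrees are rejected", {
  map <- write_lines_tmp(c("1\tm1\t0\t100"), ".map")
  ped <- write_lines_tmp(c(
    "F1 1 0 0 1 1  1 2",
    "F1 2 0 0 2 1  1 1",
    "F1 3 1 2 2 2  1 2",
    "F1 4 3 5 1 2  1 1",
    "F1 5 0 0 2 1  2 2"
  ), ".ped")
  expect_error(read_plink_text(ped, map), "two generations|parent pair")
})

test_that("the BED 2-bit decoding matches the documented byte layout", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "toy")
  writeLines(c("1\tm1\t0\t100\tC\tA"), paste0(prefix, ".bim"))
  writeLines(c("F1\t1\t0\t0\t1\t1", "F1\t2\t0\t0\t2\t1",
               "F2\t1\t0\t0\t1\t1", "F2\t2\t0\t0\t2\t2"),
             paste0(prefix, ".fam"))
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xE4)), con)  # 0b11100100
  close(con)
  study <- read_plink_binary(paste0(prefix, ".bed"), paste0(prefix, ".bim"),
                             paste0(prefix, ".fam"))
  expect_equal(unname(study$genotypes[, 1]), c(0L, NA, 1L, 2L))
  expect_equal(study$markers$counted_allele, "C")
})

test_that("corrupt binary filesets are refused", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "bad")
  writeLines(c("1\tm1\t0\t100\tC\tA"), paste0(prefix, ".bim"))
  writeLines(c("F1\t1\t0\t0\t1\t1"), paste0(prefix, ".fam"))
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0xde, 0xad, 0x01, 0x00)), con)
  close(con)
  expect_error(read_plink_binary(paste0(prefix, ".bed"),
                                 paste0(prefix, ".bim"),
                                 paste0(prefix, ".fam")),
               "magic")
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)  # truncated payload
  close(con)
  expect_error(read_plink_binary(paste0(prefix, ".bed"),
                                 paste0(prefix, ".bim"),
                                 paste0(prefix, ".fam")),
               "corrupt")
})

test_that("text and binary filesets round-trip to identical studies", {
  # MAFs kept below 0.5 so the text reader's minor-allele orientation
  # matches the simulated counted allele
  cfg <- sim_config(maf = c(0.1, 0.2, 0.3), n_families = 40,
                    structure = "nuclear")
  study <- simulate_study(cfg, seed = 3)
  dir <- withr::local_tempdir()
  write_plink_text(study, file.path(dir, "t"))
  write_plink_binary(study, file.path(dir, "b"))
  st_text <- read_plink_text(file.path(dir, "t.ped"),
                             file.path(dir, "t.map"))
  st_bin <- read_plink_binary(file.path(dir, "b.bed"),
                              file.path(dir, "b.bim"),
                              file.path(dir, "b.fam"))
  expect_identical(unname(st_text$genotypes), unname(st_bin$genotypes))
  expect_identical(unname(study$genotypes), unname(st_bin$genotypes))
  expect_equal(st_text$markers$counted_allele, st_bin$markers$counted_allele)
  expect_equal(st_text$pedigree, st_bin$pedigree)
  # downstream statistics agree with the in-memory original
  expect_equal(pdt_test(st_text), pdt_test(study))
  expect_equal(pdt_test(st_bin), pdt_test(study))
})

test_that("missing genotypes survive a text round trip", {
  study <- build_study(list(list(
    father = c(1L, NA), mother = c(2L, 0L),
    children = list(c(2L, 1L), c(1L, NA)), affected = c(TRUE, FALSE)
  )), n_markers = 2)
  dir <- withr::local_tempdir()
  write_plink_text(study, file.path(dir, "m"))
  back <- read_plink_text(file.path(dir, "m.ped"), file.path(dir, "m.map"))
  expect_equal(sum(is.na(back$genotypes)), 2)
  expect_equal(missing_counts(back)$n_missing, c(0, 2))
})

test_that("set files in both dialects parse, filter and warn", {
  known <- c("m1", "m2", "m3", "m4")
  setf <- write_lines_tmp(c("G1", "m1", "m2", "mX", "END",
                            "G2", "m3", "END"), ".set")
  expect_warning(sets <- read_snp_sets(setf, known), "unknown marker")
  expect_identical(names(sets), c("G1", "G2"))
  expect_identical(sets$G1, c("m1", "m2"))
  expect_identical(sets$G2, "m3")

  tsv <- write_lines_tmp(c("GA\tm1", "GA\tm4", "GB\tm2"), ".tsv")
  sets <- read_snp_sets(tsv, known)
  expect_identical(names(sets), c("GA", "GB"))
  expect_identical(sets$GA, c("m1", "m4"))

  unterminated <- write_lines_tmp(c("G1", "m1", "m2"), ".set")
  expect_error(read_snp_sets(unterminated, known), "unterminated")
  dup <- write_lines_tmp(c("G1", "m1", "END", "G1", "m2", "END"), ".set")
  expect_error(read_snp_sets(dup, known), "duplicate")
  allgone <- write_lines_tmp(c("G1", "mX", "END", "G2", "m1", "END"),
                             ".set")
  expect_warning(expect_warning(sets <- read_snp_sets(allgone, known),
                                "unknown"), "empty set")
  expect_identical(names(sets), "G2")
  expect_equal(attr(sets, "n_dropped_sets"), 1L)
})

test_that("annotation intervals assign markers on 1-based closed bounds", {
  markers <- tibble::tibble(
    id = paste0("m", 1:5), chrom = c("1", "1", "1", "2", "1"),
    pos = c(100L, 200L, 300L, 150L, 450L)
  )
  annotation <- tibble::tibble(
    gene = c("GA", "GB"), chrom = c("1", "2"),
    start = c(100L, 100L), end = c(300L, 150L)
  )
  sets <- snp_sets_from_annotation(markers, annotation)
  expect_identical(sets$GA, c("m1", "m2", "m3"))  # closed interval ends
  expect_identical(sets$GB, "m4")
  padded <- snp_sets_from_annotation(markers, annotation, padding = 150)
  expect_true("m5" %in% padded$GA)
})

test_that("results tables serialize with sentinel for exhausted p-values", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "res.tsv")
  empty <- optpdt:::empty_scan_tibble(default_thresholds())
  write_results(empty, out)
  expect_length(readLines(out), 1)      # header only

  res <- tibble::tibble(set = c("G1", "G2"), n_markers = c(3L, 2L),
                        n_selected = c(1L, 0L),
                        best_threshold = c(0.05, NA),
                        statistic = c(2.1, -0.3), p = c(0, 0.62),
                        p_min = c(0.001, 0.001), m = c(1000L, 1000L))
  write_results(res, out)
  lines <- readLines(out)
  expect_length(lines, 3)
  expect_match(lines[1], "p_display")
  expect_match(lines[2], "< 0.001")
  expect_match(lines[2], "0e\\+00|0\\.000e")
})

test_that("scan results are independent of worker count and set order", {
  cfg <- sim_config(maf = seq(0.1, 0.4, length.out = 8), n_families = 60)
  study <- simulate_study(cfg, seed = 9)
  ids <- study$markers$id
  sets <- list(A = ids[1:4], B = ids[5:8])
  r1 <- optpdt_scan(study, sets, m = 100, seed = 7)
  r2 <- optpdt_scan(study, sets[c("B", "A")], m = 100, seed = 7,
                    workers = 2)
  expect_equal(dplyr::arrange(r1, set), dplyr::arrange(r2, set))
  # each set alone reproduces its row: derived seed depends on name only
  solo <- glance(optpdt_test(study, set = sets$B, m = 100,
                             seed = optpdt:::derive_seed(7, "B")))
  solo$set <- "B"
  expect_equal(r1[r1$set == "B", ], solo)
  expect_equal(nrow(optpdt_scan(study, list(), m = 10)), 0)
})
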