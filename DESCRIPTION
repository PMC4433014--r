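Package: optpdt
Title: Optimal-Threshold Pedigree Disequilibrium Tests for SNP-Set
    Association in Nuclear Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Family-based multi-SNP association testing for nuclear-family
    GWAS data. Implements the pedigree disequilibrium test (PDT) for single
    SNPs and its optimal p-value threshold extension (OPTPDT) for SNP sets:
    per-SNP statistics are summed over the markers passing each of several
    p-value cutoffs, standardized against an LD-preserving family sign-flip
    permutation null, and the maximum standardized statistic is assessed by
    the same permutations. Ships PLINK PED/MAP and BED/BIM/FAM readers and
    writers, SNP-set file support, a seeded nuclear-family GWAS simulator
    with LD-structured haplotypes and a calibrated logistic penetrance
    model, and an experiment harness for type-I-error and power studies
    with Fisher, Simes and min-p comparators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
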