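test_that("pool frequencies and LD follow the AR(1) latent model", {
  set.seed(5)
  pool <- haplotype_pool(rep(0.5, 6), rho = 0, n_haplotypes = 4000)
  # independence limit: pairwise allelic correlation near zero
  cors <- cor(pool$haplotypes)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.08)
  # frequency conservation within 3 binomial standard errors
  se <- sqrt(0.5 * 0.5 / 4000)
  expect_true(all(abs(pool$maf_emp - 0.5) <= 3 * se))

  pool <- haplotype_pool(rep(0.3, 10), rho = 0.9, n_haplotypes = 10000)
  r2_adj <- mean(vapply(1:9, function(j) pool_r2(pool, j, j + 1),
                        numeric(1)))
  r2_lag5 <- mean(vapply(1:5, function(j) pool_r2(pool, j, j + 5),
                         numeric(1)))
  expect_gt(r2_adj, 3 * r2_lag5)        # monotone decay with distance
  # AR restarts across gene boundaries: no LD between genes
  pool2 <- haplotype_pool(rep(0.3, 4), rho = 0.9, n_haplotypes = 6000,
                          gene = c(1L, 1L, 2L, 2L))
  expect_lt(pool_r2(pool2, 2, 3), 0.01)
  expect_gt(pool_r2(pool2, 1, 2), 0.5)
})

test_that("genotype coding is definitional per disease model", {
  expect_equal(genotype_code(2, "additive"), 2)
  expect_equal(genotype_code(1, "dominant"), 1)
  expect_equal(genotype_code(1, "recessive"), 0)
  expect_equal(genotype_code(0:2, "recessive"), c(0, 0, 1))
  expect_error(genotype_code(3, "additive"), "0, 1 or 2")
})

test_that("intercept calibration recovers the logit in the no-effect limit", {
  set.seed(15)
  pool <- haplotype_pool(c(0.1, 0.2), n_haplotypes = 500)
  expect_equal(calibrate_intercept(pool, integer(0), numeric(0),
                                   prevalence = 0.05),
               log(0.05 / 0.95))
  expect_equal(calibrate_intercept(pool, 1:2, c(0, 0), prevalence = 0.5), 0)
})

test_that("calibrated penetrance reproduces the target prevalence", {
  set.seed(25)
  sp <- optpdt:::preset_spectrum(1, 5)
  pool <- haplotype_pool(sp$maf, rho = 0.7, n_haplotypes = 10000)
  beta <- rep(log(1.2), 5)
  alpha <- calibrate_intercept(pool, sp$disease, beta, "additive", 0.05)
  n <- 50000
  h1 <- sample.int(10000, n, TRUE)
  h2 <- sample.int(10000, n, TRUE)
  g <- pool$haplotypes[h1, sp$disease] + pool$haplotypes[h2, sp$disease]
  prev <- mean(plogis(alpha + g %*% beta))
  expect_lt(abs(prev - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("disease-marker selection honors the MAF floor and LD cap", {
  set.seed(35)
  pool <- haplotype_pool(c(0.005, rep(0.2, 19)), rho = 0.6,
                         n_haplotypes = 5000)
  idx <- select_disease_markers(pool, 4, maf_min = 0.01, r2_cap = 0.1)
  expect_length(idx, 4)
  expect_true(all(pool$maf_emp[idx] > 0.01))
  pairs <- combn(idx, 2)
  r2 <- apply(pairs, 2, function(ij) pool_r2(pool, ij[1], ij[2]))
  expect_true(all(r2 < 0.1))
})

test_that("ascertained families match their requested structure exactly", {
  for (structure in c("triad", "nuclear", "discordant_sibship")) {
    cfg <- sim_config(maf = c(0.2, 0.4), n_families = 30,
                      structure = structure)
    study <- simulate_study(cfg, seed = 11)
    expect_length(study$families, 30)
    for (fam in study$families) {
      n_child <- if (structure == "triad") 1L else 3L
      expect_length(fam$children, n_child)
      expect_equal(sum(fam$affected), 1L)
      parent_geno <- study$genotypes[c(fam$father, fam$mother), ]
      if (structure == "discordant_sibship") {
        expect_true(all(is.na(parent_geno)))
      } else {
        expect_false(anyNA(parent_geno))
      }
    }
  }
})

test_that("gene dropping is Mendelian-consistent in every draw", {
  cfg <- sim_config(maf = seq(0.1, 0.4, length.out = 5), n_families = 50,
                    structure = "nuclear")
  study <- simulate_study(cfg, seed = 21)
  G <- study$genotypes
  for (fam in study$families) {
    f <- G[fam$father, ]
    m <- G[fam$mother, ]
    for (ch in fam$children) {
      cc <- G[ch, ]
      expect_true(all(cc >= (f == 2) + (m == 2)))
      expect_true(all(cc <= 2 - (f == 0) - (m == 0)))
    }
  }
  expect_true(all(d_matrix(study)$n_mendel_errors == 0))
})

test_that("simulation is deterministic under a seed", {
  cfg <- scenario_config(n_families = 25)
  s1 <- simulate_study(cfg, seed = 31)
  s2 <- simulate_study(cfg, seed = 31)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$pedigree, s2$pedigree)
  s3 <- simulate_study(cfg, seed = 32)
  expect_false(identical(s1$genotypes, s3$genotypes))
})

test_that("the shipped scenario presets carry the documented scale", {
  cfg <- scenario_config(genes = 1, n_families = 500)
  expect_length(cfg$maf, 46)
  expect_equal(cfg$n_families, 500L)
  alt <- scenario_config(genes = 1, odds_ratio = 1.2)
  expect_equal(sort(cfg$maf[alt$disease_markers]),
               sort(c(0.1, 0.13, 0.2, 0.4, 0.42)))
  cfg10 <- scenario_config(genes = 10, odds_ratio = 1.2)
  expect_length(cfg10$maf, 1207)
  expect_length(unique(cfg10$gene), 10)
  expect_length(cfg10$disease_markers, 10)
  expect_equal(sort(cfg10$maf[cfg10$disease_markers]),
               sort(c(0.04, 0.05, 0.1, 0.1, 0.13, 0.2, 0.37, 0.4, 0.42,
                      0.43)))
  # null preset has no associated markers
  expect_null(cfg$disease_markers)
  expect_length(cfg$odds_ratio, 0)
})

test_that("risk alleles are over-transmitted under an additive alternative", {
  cfg <- scenario_config(genes = 1, n_families = 300, odds_ratio = 1.3)
  study <- simulate_study(cfg, seed = 41)
  dmat <- d_matrix(study, study$truth$disease_markers)
  d_mean <- mean(dmat$values[dmat$mask])
  expect_gt(d_mean, 0)
})

test_that("a simulated study round-trips through the writers", {
  cfg <- sim_config(maf = c(0.1, 0.2, 0.3), n_families = 30,
                    structure = "discordant_sibship")
  study <- simulate_study(cfg, seed = 51)
  dir <- withr::local_tempdir()
  write_plink_text(study, file.path(dir, "s"))
  back <- read_plink_text(file.path(dir, "s.ped"), file.path(dir, "s.map"))
  expect_equal(pdt_test(back), pdt_test(study))
  expect_length(back$families, 30)
})
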