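#' Build an LD-structured haplotype pool
#'
#' Simulates a pool of binary haplotypes with target minor-allele
#' frequencies and autoregressive linkage disequilibrium: a latent AR(1)
#' Gaussian is thresholded at each marker's MAF quantile, so marker `i`
#' carries the minor allele with probability `maf[i]` and the allelic
#' correlation between markers decays geometrically with their distance.
#' The AR chain restarts at every gene boundary, so markers in different
#' genes are unlinked. Families are later generated by random mating and
#' gene dropping from this pool.
#'
#' @param maf Numeric vector of per-marker minor-allele frequencies in
#'   (0, 0.5].
#' @param rho AR(1) latent correlation between adjacent markers, in [0, 1).
#' @param n_haplotypes Pool size (default 10000).
#' @param gene Integer vector assigning each marker to a gene (default: all
#'   markers in gene 1).
#' @return An object of class `haplotype_pool`: binary matrix `haplotypes`
#'   (1 = minor allele), the `markers` tibble, target and empirical MAFs,
#'   `rho` and `gene`.
#' @export
haplotype_pool <- function(maf, rho = 0.7, n_haplotypes = 10000,
                           gene = NULL) {
  stopifnot(all(maf > 0 & maf <= 0.5), rho >= 0, rho < 1, n_haplotypes > 1)
  nm <- length(maf)
  if (is.null(gene)) gene <- rep(1L, nm)
  stopifnot(length(gene) == nm)
  z <- matrix(stats::rnorm(n_haplotypes * nm), n_haplotypes, nm)
  w <- sqrt(1 - rho^2)
  for (j in seq_len(nm)[-1]) {
    if (gene[j] == gene[j - 1L]) z[, j] <- rho * z[, j - 1L] + w * z[, j]
  }
  H <- sweep(z, 2, stats::qnorm(maf), "<") + 0L
  storage.mode(H) <- "integer"
  within_gene <- stats::ave(seq_len(nm), gene, FUN = seq_along)
  markers <- tibble::tibble(
    id = sprintf("snp%04d", seq_len(nm)),
    chrom = as.character(gene),
    pos = within_gene * 1000L,
    allele1 = "1", allele2 = "2", counted_allele = "2"
  )
  colnames(H) <- markers$id
  structure(
    list(haplotypes = H, markers = markers, maf_target = maf,
         maf_emp = colMeans(H), rho = rho, gene = gene),
    class = "haplotype_pool"
  )
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("<haplotype_pool> ", nrow(x$haplotypes), " haplotypes x ",
      ncol(x$haplotypes), " markers in ", length(unique(x$gene)),
      " gene(s), rho = ", x$rho, "\n", sep = "")
  invisible(x)
}

#' Pairwise allelic r-squared between two pool markers
#' @param pool A [haplotype_pool()].
#' @param i,j Marker indices.
#' @return Squared allelic correlation on the pool haplotypes.
#' @export
pool_r2 <- function(pool, i, j) {
  stats::cor(pool$haplotypes[, i], pool$haplotypes[, j])^2
}

#' Randomly select disease markers subject to MAF and LD constraints
#'
#' Draws marker indices one at a time, keeping only markers with empirical
#' MAF above `maf_min` and pairwise r-squared with every already-selected
#' marker below `r2_cap`.
#'
#' @param pool A [haplotype_pool()].
#' @param n_disease Number of markers to select.
#' @param maf_min Minimum empirical minor-allele frequency (default 0.01).
#' @param r2_cap Maximum pairwise r-squared among selected markers
#'   (default 0.1).
#' @return Sorted integer vector of marker indices.
#' @export
select_disease_markers <- function(pool, n_disease, maf_min = 0.01,
                                   r2_cap = 0.1) {
  eligible <- which(pool$maf_emp > maf_min & pool$maf_emp < 1 - maf_min)
  chosen <- integer(0)
  pool_left <- sample(eligible)
  for (cand in pool_left) {
    if (length(chosen) == n_disease) break
    ok <- all(vapply(chosen, function(j) pool_r2(pool, cand, j) < r2_cap,
                     logical(1)))
    if (ok) chosen <- c(chosen, cand)
  }
  if (length(chosen) < n_disease) {
    stop("could not select ", n_disease, " markers with MAF > ", maf_min,
         " and pairwise r2 < ", r2_cap)
  }
  sort(chosen)
}

#' Genotype coding under a disease model
#'
#' @param genotype_count Copies of the risk allele, in `{0, 1, 2}`.
#' @param model `"additive"` (0/1/2), `"dominant"` (0/1/1) or
#'   `"recessive"` (0/0/1).
#' @return Numeric coding, vectorised over `genotype_count`.
#' @export
genotype_code <- function(genotype_count,
                          model = c("additive", "dominant", "recessive")) {
  model <- match.arg(model)
  if (any(!genotype_count %in% c(0, 1, 2))) {
    stop("genotype_count must be 0, 1 or 2")
  }
  switch(model,
         additive = as.numeric(genotype_count),
         dominant = as.numeric(genotype_count > 0),
         recessive = as.numeric(genotype_count == 2))
}

code_matrix <- function(g, model) {
  out <- switch(model,
                additive = g,
                dominant = (g > 0) + 0,
                recessive = (g == 2) + 0)
  matrix(as.numeric(out), nrow = nrow(g))
}

#' Calibrate the logistic penetrance intercept to a target prevalence
#'
#' The disease model is `P(affected | X) = plogis(alpha + B.X)` where `X`
#' codes the genotypes at the disease markers under the chosen model. This
#' solves `E[P(affected | X)] = prevalence` for `alpha`, with the population
#' expectation taken over random mating of pool haplotypes (Monte-Carlo over
#' `n_mc` sampled genotypes). With all effects zero the closed form
#' `qlogis(prevalence)` is returned.
#'
#' @param pool A [haplotype_pool()].
#' @param disease_idx Integer indices of the disease markers.
#' @param beta Per-marker log odds ratios (same length as `disease_idx`).
#' @param model Disease model, see [genotype_code()].
#' @param prevalence Target population prevalence in (0, 1).
#' @param n_mc Monte-Carlo population size (default 200000).
#' @return The intercept `alpha` (log-odds scale).
#' @export
calibrate_intercept <- function(pool, disease_idx, beta,
                                model = "additive", prevalence = 0.05,
                                n_mc = 200000) {
  stopifnot(prevalence > 0, prevalence < 1,
            length(beta) == length(disease_idx))
  if (length(beta) == 0L || all(beta == 0)) return(stats::qlogis(prevalence))
  nh <- nrow(pool$haplotypes)
  h1 <- sample.int(nh, n_mc, replace = TRUE)
  h2 <- sample.int(nh, n_mc, replace = TRUE)
  g <- pool$haplotypes[h1, disease_idx, drop = FALSE] +
    pool$haplotypes[h2, disease_idx, drop = FALSE]
  s <- drop(code_matrix(g, model) %*% beta)
  f <- function(a) mean(stats::plogis(a + s)) - prevalence
  sol <- tryCatch(
    stats::uniroot(f, lower = -40, upper = 20, tol = 1e-10),
    error = function(e) {
      stop("intercept calibration did not converge on [-40, 20]: ",
           "f(-40) = ", signif(f(-40), 3), ", f(20) = ", signif(f(20), 3))
    })
  if (abs(f(sol$root)) > 1e-3) {
    stop("intercept calibration residual exceeds 1e-3")
  }
  sol$root
}

#' Describe a family-simulation scenario
#'
#' Low-level constructor: specify per-marker MAFs, gene assignment, disease
#' markers and effects directly. [scenario_config()] builds the shipped
#' 1-gene (46 SNPs) and 10-gene (1207 SNPs) presets on top of this.
#'
#' @param maf Per-marker minor-allele frequencies.
#' @param gene Gene assignment per marker (see [haplotype_pool()]).
#' @param n_families Number of families to ascertain.
#' @param structure `"triad"` (two genotyped parents, one affected child),
#'   `"nuclear"` (two genotyped parents, one affected and two unaffected
#'   children) or `"discordant_sibship"` (two ungenotyped parents, one
#'   affected and two unaffected children).
#' @param disease_markers Integer marker indices carrying effects, or
#'   `NULL` to select `n_disease` at random under the MAF/LD rule.
#' @param n_disease Number of disease markers when selecting at random.
#' @param odds_ratio Per-disease-marker odds ratio(s); recycled.
#' @param model Disease model, see [genotype_code()].
#' @param prevalence Target population prevalence (default 0.05).
#' @param rho Haplotype-pool LD parameter.
#' @param n_haplotypes Haplotype-pool size.
#' @param maf_min,r2_cap Disease-marker selection rule (MAF floor, pairwise
#'   r-squared cap).
#' @param max_attempts Rejection-sampling cap, candidate families per
#'   ascertained family (default 1e6).
#' @param label Scenario label carried into experiment outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(maf, gene = NULL, n_families = 500,
                       structure = c("triad", "nuclear",
                                     "discordant_sibship"),
                       disease_markers = NULL, n_disease = 0,
                       odds_ratio = 1,
                       model = c("additive", "dominant", "recessive"),
                       prevalence = 0.05, rho = 0.7, n_haplotypes = 10000,
                       maf_min = 0.01, r2_cap = 0.1, max_attempts = 1e6,
                       label = "custom") {
  structure_ <- match.arg(structure)
  model <- match.arg(model)
  stopifnot(n_families >= 1, all(odds_ratio > 0))
  if (!is.null(disease_markers)) n_disease <- length(disease_markers)
  structure(
    list(maf = maf, gene = gene, n_families = as.integer(n_families),
         structure = structure_, disease_markers = disease_markers,
         n_disease = as.integer(n_disease),
         odds_ratio = rep(odds_ratio, length.out = n_disease),
         model = model, prevalence = prevalence, rho = rho,
         n_haplotypes = as.integer(n_haplotypes), maf_min = maf_min,
         r2_cap = r2_cap, max_attempts = max_attempts, label = label),
    class = "sim_config"
  )
}

# Fixed marker-frequency spectra for the shipped scenarios. Disease markers
# sit at spaced positions so their pairwise latent correlation (rho^lag) is
# negligible against the r2 cap; remaining MAFs follow a fixed grid over
# (0.05, 0.5).
preset_spectrum <- function(genes, n_disease) {
  if (genes == 1) {
    nm <- 46L
    gene <- rep(1L, nm)
    if (n_disease == 10) {
      didx <- c(3L, 7L, 12L, 16L, 21L, 25L, 30L, 34L, 39L, 43L)
      dmaf <- c(0.04, 0.05, 0.1, 0.1, 0.13, 0.2, 0.37, 0.4, 0.42, 0.43)
    } else {
      didx <- c(5L, 14L, 23L, 32L, 41L)
      dmaf <- c(0.1, 0.13, 0.2, 0.4, 0.42)
    }
  } else if (genes == 10) {
    sizes <- c(rep(121L, 7), rep(120L, 3))  # 1207 markers
    gene <- rep(seq_len(10L), times = sizes)
    starts <- cumsum(c(0L, sizes[-10]))
    didx <- starts + 60L
    dmaf <- c(0.04, 0.05, 0.1, 0.1, 0.13, 0.2, 0.37, 0.4, 0.42, 0.43)
    nm <- sum(sizes)
  } else {
    stop("genes must be 1 or 10")
  }
  maf <- round(seq(0.05, 0.5, length.out = nm), 3)
  maf[didx] <- dmaf
  list(maf = maf, gene = gene, disease = didx,
       n_disease_max = length(didx))
}

#' Shipped simulation scenarios
#'
#' Builds the study conditions used throughout the package's experiments:
#' a 1-gene region of 46 SNPs or a 10-gene region of 1207 SNPs, nuclear
#' families / triads / discordant sibships, 5% disease prevalence, and
#' disease markers with the fixed MAF spectra (0.1, 0.13, 0.2, 0.4, 0.42
#' for 5 markers; 0.04, 0.05, 0.1, 0.1, 0.13, 0.2, 0.37, 0.4, 0.42, 0.43
#' for 10) placed at spaced, effectively unlinked positions.
#' `odds_ratio = 1` gives a null scenario with no associated markers.
#'
#' @param genes 1 or 10 simulated genes.
#' @param n_families Number of ascertained families (default 500).
#' @param structure Family structure, see [sim_config()].
#' @param odds_ratio Common odds ratio for all disease markers; 1 = null.
#' @param model Disease model.
#' @param n_disease 5 or 10 disease markers (10-gene preset: always 10).
#' @param ... Passed on to [sim_config()].
#' @return A [sim_config()].
#' @export
scenario_config <- function(genes = 1, n_families = 500,
                            structure = "triad", odds_ratio = 1,
                            model = "additive",
                            n_disease = if (genes == 1) 5L else 10L, ...) {
  sp <- preset_spectrum(genes, n_disease)
  null_model <- isTRUE(all(odds_ratio == 1))
  disease <- if (null_model) NULL else sp$disease[seq_len(n_disease)]
  sim_config(
    maf = sp$maf, gene = sp$gene, n_families = n_families,
    structure = structure, disease_markers = disease,
    odds_ratio = if (null_model) numeric(0) else odds_ratio,
    model = model,
    label = paste0(genes, "gene-", structure, "-",
                   if (null_model) "null" else
                     paste0("or", paste(unique(odds_ratio), collapse = "/"),
                            "-", model)),
    ...
  )
}

#' Prepare a scenario: pool, disease markers, calibrated intercept
#'
#' Builds the haplotype pool once and calibrates the penetrance intercept;
#' replicate studies are then drawn from the same pool with
#' [simulate_families()], mirroring a simulation design where one haplotype
#' panel underlies every replicate.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for pool construction and calibration.
#' @return An object of class `sim_scenario`.
#' @export
prepare_scenario <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  pool <- haplotype_pool(config$maf, rho = config$rho,
                         n_haplotypes = config$n_haplotypes,
                         gene = config$gene)
  didx <- config$disease_markers
  if (is.null(didx) && config$n_disease > 0) {
    didx <- select_disease_markers(pool, config$n_disease,
                                   config$maf_min, config$r2_cap)
  }
  didx <- as.integer(didx)
  beta <- log(config$odds_ratio)
  alpha <- calibrate_intercept(pool, didx, beta, config$model,
                               config$prevalence)
  structure(
    list(config = config, pool = pool, disease_idx = didx, beta = beta,
         alpha = alpha),
    class = "sim_scenario"
  )
}

# Batch rejection sampler. Returns accepted parental/child haplotype
# indices plus affection flags and the realized acceptance rate.
draw_family_indices <- function(scenario, n) {
  cfg <- scenario$config
  pool <- scenario$pool
  H <- pool$haplotypes
  nh <- nrow(H)
  n_child <- if (cfg$structure == "triad") 1L else 3L
  keep <- list()
  got <- 0L
  attempts <- 0
  cap <- cfg$max_attempts * n
  rate <- 0.05  # running acceptance estimate used to size batches
  while (got < n) {
    b <- min(2e5, max(2000L, ceiling((n - got) / max(rate, 1e-4) * 1.2)))
    attempts <- attempts + b
    if (attempts > cap) {
      stop("family rejection sampling exceeded ", cap, " attempts ",
           "(acceptance rate ", signif(got / attempts, 3), ")")
    }
    fh1 <- sample.int(nh, b, TRUE); fh2 <- sample.int(nh, b, TRUE)
    mh1 <- sample.int(nh, b, TRUE); mh2 <- sample.int(nh, b, TRUE)
    cf <- matrix(0L, b, n_child); cm <- matrix(0L, b, n_child)
    aff <- matrix(FALSE, b, n_child)
    for (j in seq_len(n_child)) {
      cf[, j] <- ifelse(stats::runif(b) < 0.5, fh1, fh2)
      cm[, j] <- ifelse(stats::runif(b) < 0.5, mh1, mh2)
      eta <- if (length(scenario$disease_idx) > 0) {
        g <- H[cf[, j], scenario$disease_idx, drop = FALSE] +
          H[cm[, j], scenario$disease_idx, drop = FALSE]
        scenario$alpha + drop(code_matrix(g, cfg$model) %*% scenario$beta)
      } else scenario$alpha
      aff[, j] <- stats::runif(b) < stats::plogis(eta)
    }
    ok <- rowSums(aff) == 1L  # exactly one affected child per family
    rate <- max(sum(ok) / b, 1e-4)
    if (any(ok)) {
      take <- which(ok)[seq_len(min(sum(ok), n - got))]
      keep[[length(keep) + 1L]] <- list(
        fh1 = fh1[take], fh2 = fh2[take], mh1 = mh1[take], mh2 = mh2[take],
        cf = cf[take, , drop = FALSE], cm = cm[take, , drop = FALSE],
        aff = aff[take, , drop = FALSE])
      got <- got + length(take)
    }
  }
  list(
    fh1 = unlist(lapply(keep, `[[`, "fh1")),
    fh2 = unlist(lapply(keep, `[[`, "fh2")),
    mh1 = unlist(lapply(keep, `[[`, "mh1")),
    mh2 = unlist(lapply(keep, `[[`, "mh2")),
    cf = do.call(rbind, lapply(keep, `[[`, "cf")),
    cm = do.call(rbind, lapply(keep, `[[`, "cm")),
    aff = do.call(rbind, lapply(keep, `[[`, "aff")),
    acceptance_rate = got / attempts,
    n_child = n_child
  )
}

#' Draw ascertained families from a prepared scenario
#'
#' Random mating and gene dropping from the scenario's haplotype pool:
#' each parent is two pool haplotypes drawn uniformly, each child inherits
#' one haplotype from each parent uniformly, affection is sampled from the
#' calibrated logistic penetrance, and families are rejection-sampled until
#' they match the requested structure (exactly one affected child; for
#' discordant sibships the parents' genotypes are then masked to missing).
#'
#' @param scenario A [prepare_scenario()] result.
#' @param seed Integer seed for the draw.
#' @param n Number of families (default: the config's `n_families`).
#' @return A [family_study()] with a `truth` element recording the disease
#'   markers, effects, intercept and realized acceptance rate.
#' @export
simulate_families <- function(scenario, seed = 1, n = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  cfg <- scenario$config
  n <- as.integer(n %||% cfg$n_families)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  dr <- draw_family_indices(scenario, n)
  H <- scenario$pool$haplotypes
  nm <- ncol(H)
  n_child <- dr$n_child
  k <- 2L + n_child
  blocks <- vector("list", k)
  blocks[[1]] <- H[dr$fh1, , drop = FALSE] + H[dr$fh2, , drop = FALSE]
  blocks[[2]] <- H[dr$mh1, , drop = FALSE] + H[dr$mh2, , drop = FALSE]
  for (j in seq_len(n_child)) {
    blocks[[2L + j]] <- H[dr$cf[, j], , drop = FALSE] +
      H[dr$cm[, j], , drop = FALSE]
  }
  G <- do.call(rbind, blocks)
  ord <- as.vector(t(matrix(seq_len(n * k), n, k)))
  G <- G[ord, , drop = FALSE]
  storage.mode(G) <- "integer"
  if (cfg$structure == "discordant_sibship") {
    parent_rows <- as.vector(vapply(seq_len(n),
                                    function(i) (i - 1L) * k + 1:2,
                                    integer(2)))
    G[parent_rows, ] <- NA_integer_
  }
  fam_id <- rep(sprintf("F%04d", seq_len(n)), each = k)
  ind_id <- rep(as.character(seq_len(k)), times = n)
  role_child <- rep(c(FALSE, FALSE, rep(TRUE, n_child)), times = n)
  affected <- rep(NA, n * k)
  affected[role_child] <- as.vector(t(dr$aff))
  pedigree <- tibble::tibble(
    family_id = fam_id,
    individual_id = ind_id,
    father_id = ifelse(role_child, "1", "0"),
    mother_id = ifelse(role_child, "2", "0"),
    sex = rep(c(1L, 2L, rep(1L, n_child)), times = n),
    affected = as.logical(affected)
  )
  study <- family_study(scenario$pool$markers, pedigree, G,
                        provenance = list(source = "simulate",
                                          label = cfg$label, seed = seed))
  study$truth <- list(
    disease_markers = scenario$pool$markers$id[scenario$disease_idx],
    odds_ratio = cfg$odds_ratio, beta = scenario$beta,
    model = cfg$model, alpha = scenario$alpha,
    prevalence_target = cfg$prevalence,
    structure = cfg$structure,
    acceptance_rate = dr$acceptance_rate,
    seed = seed
  )
  study
}

#' Simulate a complete family study
#'
#' Convenience wrapper: [prepare_scenario()] then [simulate_families()],
#' with sub-seeds derived deterministically from `seed`.
#'
#' @param config A [sim_config()] / [scenario_config()].
#' @param seed Integer seed.
#' @return A [family_study()] with a `truth` element; see
#'   [simulate_families()].
#' @export
simulate_study <- function(config, seed = 1) {
  scenario <- prepare_scenario(config, seed = derive_seed(seed, "pool"))
  simulate_families(scenario, seed = derive_seed(seed, "families"))
}
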