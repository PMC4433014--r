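---
title: "Methods: the optimal-threshold pedigree disequilibrium test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the optimal-threshold pedigree disequilibrium test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optpdt)
```

## The problem

Gene- and pathway-level association tests ask whether any subset of the
SNPs in a predefined region is associated with a disease. When only a few
of the region's markers carry signal, summing evidence over *all* markers
dilutes power, while committing in advance to a single inclusion cutoff
(conventionally, markers with single-SNP p < 0.05) risks choosing the
wrong one. This package implements a family-based answer for nuclear
families: score each SNP with the pedigree disequilibrium test (PDT),
evaluate the set statistic at several p-value cutoffs at once, and let an
LD-preserving permutation null calibrate the maximum across cutoffs, so
the "optimal" threshold is chosen by the data without inflating the type I
error.

Family designs are attractive here because transmission-based statistics
are immune to population stratification, and because the within-family
permutation scheme described below is exact in a way case-control label
swapping is not.

## The single-SNP PDT

At a biallelic SNP with counted allele $A_1$, two family units contribute:

* a **triad** — an affected child with two genotyped parents, at least one
  heterozygous — contributes
  $X_T = (\#A_1 \text{ transmitted}) - (\#A_1 \text{ not transmitted})$
  over both parental meioses;
* a **discordant sib pair (DSP)** — an affected and an unaffected sibling
  with different genotypes — contributes
  $X_S = (\#A_1 \text{ in affected}) - (\#A_1 \text{ in unaffected})$.

With genotypes coded as counts of $A_1$, the triad score is
$2c - f - m$. A nuclear family with $n_T$ informative triads and $n_S$
informative DSPs (every affected-by-unaffected pairing counts) summarises
to

$$D = \frac{X_T + X_S}{n_T + n_S}, \qquad D \in [-2, 2],$$

and over $N$ informative families the marker's statistic is

$$T^2 = \frac{\left(\sum_i D_i\right)^2}{\sum_i D_i^2},$$

asymptotically $\chi^2_1$ under the null of no linkage or no association.
Squaring makes the statistic indifferent to which allele is counted — the
package's readers orient to the sample minor allele (PED/MAP) or the BIM
column-5 allele (binary), and a relabeling only negates every $D$.

Conventions where the data run out: a marker with no informative family or
$\sum D_i^2 = 0$ is *untestable* and reported with $T^2 = 0$, $p = 1$, so
it can never be selected into a set statistic. Mendelian-inconsistent
triads are excluded at the offending marker only (and tallied); the same
family's DSPs are kept. These are deliberate, conservative choices — the
inconsistency rate is a data-quality signal, not something to impute
through.

## The variable-threshold set statistic

For a set of $n$ markers and thresholds
$k \in \{0.05, 0.03, 0.01, 0.005\}$ (the default grid; a wider grid adds
little), let $L_k$ collect the markers with single-SNP $p < k$ and
$Y_k = \sum_{i \in L_k} T_i^2$. Each $Y_k$ has a different null
distribution, so the statistics are standardised with permutation moments:

$$Z_k = \frac{Y_k - \hat\mu_k}{\hat\sigma_k},$$

with $\hat\mu_k, \hat\sigma_k$ the mean and (sample, $m-1$ denominator)
standard deviation of $Y_k$ over $m$ permutations. The test statistic is
$M = \max_k Z_k$, and its p-value is the fraction of permutations whose own
$M_j = \max_k Z_{k_j}$ reaches $M$ (ties count as exceedances). One
permutation pass serves every threshold — that is what makes $M$ and the
$M_j$ comparable.

### The sign-flip permutation

Swapping the transmitted and non-transmitted parental alleles negates a
family's $X_T$; swapping the affected/unaffected roles in a DSP negates
$X_S$. Either way the family's $D$ changes sign and nothing else changes,
so the null can be generated by flipping one fair sign per family,
*shared across all markers in the set*. Flipping whole rows of the
families-by-markers $D$ matrix preserves both the LD between markers
(columns move together) and the linkage structure within a family
(identity-by-descent among siblings is untouched). This also works when
parents are ungenotyped, where re-permuting alleles directly would be
impossible. Computationally the flip is a single matrix product: the
denominator $\sum_i D_i^2$ is sign-invariant, so only signed column sums
are recomputed per draw.

### Edge-case policy

* **Empty selection.** When no marker passes threshold $k$, the statistic
  is taken as the empty sum $Y_k = 0$, in the observed data and in every
  permutation. This keeps $\hat\mu_k, \hat\sigma_k$ estimable from all
  $m$ draws; an observed empty selection then simply produces a small
  $Z_k$ that never drives the maximum. (The alternative — dropping the
  threshold only when the *observed* set is empty — breaks the symmetry
  between $M$ and the $M_j$.) If every threshold has an empty observed
  selection the test reports $p = 1$ outright.
* **Degenerate thresholds.** If $\hat\sigma_k = 0$ the Z-score is
  undefined; the threshold is excluded from the maximum symmetrically for
  $M$ and all $M_j$, preserving exchangeability. If no threshold survives,
  $p = 1$.
* **P-value estimator.** The default is the plug-in $\#(M_j \ge M)/m$; a
  switch selects the $(r+1)/(m+1)$ estimator. Either way the result
  carries `p_min`, the smallest attainable value, so a reported 0 is
  interpretable. Exceedances are counted with a small relative tolerance
  ($10^{-8}$): permutations whose statistic ties the observed one in
  exact arithmetic (sign vectors that merely negate or permute the same
  column sums) can land a few ulps apart after floating-point summation,
  and the tie-counts-as-exceedance convention must not depend on that. The default $m = 2000$ resolves set-level p-values to
  $5\times10^{-4}$; genome-wide scans need larger $m$ for the top genes.
  There is no adaptive early stopping by default, so a seed fixes the
  p-value exactly.
* **Per-SNP p-values** in the selection step use the asymptotic
  $\chi^2_1$ tail, not a nested permutation; the outer permutation absorbs
  the approximation error because observed and permuted data are treated
  identically.

Multi-set scans derive each set's RNG stream from the scan seed and the
set *name*, so results are bit-identical for any worker count or set
order.

## The simulator

`scenario_config()` / `simulate_study()` generate nuclear-family GWAS data
with the statistical structure the tests are designed for:

* **Haplotype pool.** A latent first-order autoregressive Gaussian,
  thresholded at each marker's MAF quantile, yields 10,000 binary
  haplotypes with exact marginal MAFs and geometrically decaying LD;
  the chain restarts at gene boundaries. The default $\rho = 0.7$ gives
  adjacent-marker $r^2$ in the 0.2–0.4 range typical of dense gene-scale
  panels. This emulates the *shape* of real LD, not any particular
  population's haplotypes: block structure, recombination hotspots and
  allele-frequency spectra of real panels are not reproduced, so passing
  power numbers characterise the method under this model, not on any
  specific cohort.
* **Shipped scales.** One 46-SNP gene and a 10-gene, 1207-SNP region.
  Disease markers sit at spaced (effectively unlinked) positions with
  fixed MAF lists — (0.1, 0.13, 0.2, 0.4, 0.42) for five markers,
  (0.04, 0.05, 0.1, 0.1, 0.13, 0.2, 0.37, 0.4, 0.42, 0.43) for ten —
  and the remaining markers follow a fixed grid over (0.05, 0.5).
  A random selection rule (`select_disease_markers()`: MAF > 1%, pairwise
  $r^2 < 0.1$) is available for non-preset studies; the 0.1 cap is a
  configuration value, chosen as a conventional "not in LD" operating
  point.
* **Penetrance.** Affection is sampled from
  $P(\text{affected} \mid X) = \operatorname{logit}^{-1}(\alpha + B X)$
  with $X$ the additive/dominant/recessive coding of the disease-marker
  genotypes (risk allele = minor allele) and no interaction terms. The
  intercept $\alpha$ is calibrated by monotone root-finding so the
  population prevalence equals the 5% target (residual $\le 10^{-3}$;
  closed form $\alpha = \operatorname{logit}(0.05) \approx -2.944$ when
  all effects vanish). The population expectation is Monte-Carlo over
  200,000 random-mating genotypes, making the calibration itself
  reproducible under the scenario seed.
* **Families.** Parents are two pool haplotypes each; children inherit one
  haplotype per parent uniformly (gene dropping, no recombination within a
  region — negligible at gene scale). Structures: triads (one affected
  child), nuclear families (one affected + two unaffected siblings) and
  discordant sibships (same, parents masked to missing). Families are
  rejection-sampled in vectorised batches until exactly the requested
  affected/unaffected configuration appears, with a $10^6$-attempts-per-
  family cap that fails loudly on pathological configurations.

One pool underlies all replicates of an experiment
(`prepare_scenario()` once, then `simulate_families()` per replicate):
the pool plays the role of the population, replicates are ascertainment
draws from it.

## The experiment harness

`type1_error_experiment()` and `power_experiment()` reproduce the standard
evaluation design: simulate replicate studies, run each method, report
rejection rates at $\alpha \in \{0.05, 0.01\}$ with exact Clopper-Pearson
95% intervals. All methods see identical replicates (paired comparison),
and the two permutation-based methods — the variable-threshold test and
the fixed-threshold comparator — share the same permutation draws within a
replicate, so power differences cannot be permutation noise. The
`fisher`, `simes` and `minp` comparators combine the per-marker asymptotic
PDT p-values and stand in for the p-value-combination family of set tests;
they are not re-implementations of any published genotype-based set test.

Default problem sizes are chosen to keep Monte-Carlo standard errors
usefully small on a single core: the package's own validation runs use
500 null replicates of 500 triads with $m = 1000$ for the type-I-error
check (binomial SE $\approx 0.01$ at the 0.05 level) and 200 replicates
per odds ratio with $m = 400$ for the 10-gene power ordering (SE
$\approx 0.02$–0.035). Replicate counts, $m$, family counts and structures
are all arguments, not constants.

## Numerical and design notes

* Thresholds are validated to lie in $(0, 1]$, deduplicated and sorted
  descending; selections at descending thresholds are nested, and $Y_k$
  is non-decreasing in $k$ — both properties are tested.
* The genotype container is a plain integer matrix of counted-allele
  copies with `NA` for missing; per-family scoring is vectorised across
  markers, and a 500-family, 1207-marker study tests in well under two
  seconds at $m = 400$.
* Only two-generation pedigrees are accepted; deeper pedigrees and
  families whose children declare mixed parent pairs are rejected with
  explicit errors rather than silently re-interpreted. A child with
  exactly one genotyped parent contributes no triad (a warning notes the
  half-present parent); this follows the PDT's two-genotyped-parents
  definition rather than extending it.
* The binary-format codec maps the 2-bit codes so that code `11` means two
  copies of the BIM column-5 (counted) allele. Files written by other
  tools with the opposite orientation decode to the complementary count;
  every reported statistic is invariant to that flip, only the sign of
  $D$ changes.
* Exhaustive enumeration of all $2^N$ sign vectors (feasible to
  $N \approx 12$) is kept in the test suite as an independent oracle for
  the Monte-Carlo engine; the two agree within binomial error at
  $m = 20{,}000$.

## Limitations

* Nuclear families only — no extended pedigrees, no quantitative traits,
  no X-chromosome dosage handling.
* Designed for common-variant GWAS sets; with very rare variants the
  per-SNP $\chi^2_1$ approximation in the selection step degrades and a
  different set statistic is preferable.
* The simulator's AR(1) LD model is a deliberate simplification; absolute
  power numbers under it should not be read as predictions for any real
  genotyping panel, though orderings between methods have proven stable
  across effect sizes in the shipped experiments.
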