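---
title: "Pathway analysis of case-control GWAS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway analysis of case-control GWAS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathgwas)
```

## The problem

Single-SNP tests in a genome-wide association study (GWAS) of a complex
disease such as bladder cancer leave most of the heritable signal on the
table: individual common variants carry per-allele odds ratios in the
1.05–1.3 range and rarely clear genome-wide significance. Pathway
(gene-set) analysis asks a different question — whether the association
signals of a set of functionally related genes collectively deviate from
chance — and can recover biology that no single SNP pins down.
`pathgwas` implements a complete pathway pipeline for multi-study
case-control GWAS: covariate-adjusted per-SNP trend tests, reduction to
best-SNP gene statistics, two complementary enrichment tests sharing one
genotype-permutation null, permutation-normalized scores with a
permutation-based FDR, and a cross-study heterogeneity filter.

## The analysis chain

### Annotation

Gene sets come from GMT files (`set_id`, source label, member genes);
sets outside the 5–100 gene window are removed, since very small sets are
statistically unstable and very large ones functionally uninformative.
SNPs are assigned to a gene when they fall within 20 kb 5′ upstream or
10 kb 3′ downstream of its coding region (strand-aware: for a − strand
gene the 5′ flank is on the high-coordinate side). Gene coordinates are
exchanged as BED (0-based half-open) and held internally 1-based
inclusive; both conventions are unit-tested at the boundaries. Genes that
share mapped SNPs carry redundant evidence; `pool_shared_loci()` merges
them (transitively) into locus units so one association signal is not
counted once per gene. Pathway similarity is summarized as
`100·|A∩B| / min(N_A, N_B)`; the min denominator keeps a nested set at
100% overlap, and `union` and `mean` denominators are available because
the field uses all three.

### Per-SNP association

SNPs with minor-allele frequency below 1% among pooled controls
(complete-case, folded) are excluded. Each remaining SNP gets a 1-df
additive trend test from a maximum-likelihood logistic fit of case status
on dosage plus covariates — age, sex, study, DNA source, and smoking
(never/former/occasional/current, never as reference; categorical
covariates enter as indicator contrasts). The reported per-SNP statistics
are Wald: log-OR, SE, OR with 95% CI `exp(beta ± 1.96·se)`, and the
two-sided p-value. Fits with separation or non-convergence (|beta| > 15,
singular information, or IRLS failure) are flagged and excluded from
gene statistics rather than reported. Each gene is then represented by
its best (smallest) SNP p-value, `r_j = -log10(p_j)`; ties break to the
lexicographically smaller SNP id so reruns are reproducible.

### The shared permutation null

Both enrichment tests are calibrated by permuting whole genotype rows
across individuals — one global shuffle per permutation, outcome and
covariates fixed — which preserves SNP–SNP linkage disequilibrium while
breaking genotype–phenotype association. The same B permutations are
reused for every pathway and by both methods, which is what makes their
p-values and the normalized-score FDR comparable.

Inside the permutation engine the per-SNP test is the Rao score test of
the dosage term against the covariate-only null model, not the Wald
test. This is a deliberate design choice, not an approximation made for
convenience elsewhere: the null model is identical for every permutation
(only genotypes move), so it is fit once, and the score statistic for
all SNPs in one permutation reduces to two matrix products. That brings
a 10,000-permutation run from days of per-SNP IRLS down to minutes, and
— more importantly — the engine applies the *same* statistic to the
observed data and to every permutation, so observed and permuted
gene-level p-values are exchangeable by construction. Score and Wald
tests are asymptotically equivalent; the unit suite checks their
agreement to |Δlog10 p| < 0.2 at n = 800. Missing dosages are
mean-imputed per SNP once, before permuting, so every permutation sees
identical rows.

### GSEA: weighted Kolmogorov–Smirnov enrichment score

Genes are ranked by `r_j` in decreasing order. Walking down the ranking,
the running sum gains `r_j^p / N_R` at pathway members (`N_R` the sum of
member `r^p`) and loses `1/(N − N_H)` at non-members; the enrichment
score ES is the maximum of the running sum. The weight exponent defaults
to `p = 1`, so genes contribute in proportion to the strength of their
association rather than rank alone; `p = 0` recovers the classical KS
statistic and is available. ES is one-sided (enrichment only), matching
the overrepresentation question. The empirical p-value is
`#{ES_b ≥ ES_obs}/B`, ties counted as exceedances (conservative); a zero
count is displayed as `<1/B`. Degenerate sets (no members with data, or
all genes members) are skipped; a set whose members all have `r_j = 0`
takes the defined limit `−N_H/(N − N_H)`.

### ARTP: adaptive rank-truncated product

For each pathway the gene p-values are sorted ascending and the products
`W(K)` of the K smallest are formed for every truncation point
`K = 1..L` (in log space; the original sparse-grid variant is available
through `K_max` but the full grid is the default). Because `W(K)` at
different K are on different scales, each is converted to an estimated
p-value by its rank in the augmented pool of B + 1 values (observed plus
permutations, ties as exceedances, self included):
`ŝ(K) = #{t′: W_t′(K) ≤ W_t(K)}/(B+1)`. The pathway statistic is
`minP = min_K ŝ(K)`, and the final p-value adjusts for that minimization
by a second permutation level:
`p_ARTP = (#{b: minP_b ≤ minP_obs} + 1)/(B + 1)`. The augmented-pool
rank convention matters: ranking permutations only among themselves
biases `p_ARTP` upward by ~1/(B+1), which a single-gene pathway exposes
immediately (the unit suite pins the L = 1 reduction and an exhaustive
brute-force enumeration for L ≤ 3, B ≤ 10). With this convention
`p_ARTP` is uniform on {1/(B+1), …, 1} under the null and can never be
0.

### Normalized scores and permutation FDR

Each pathway's statistic is normalized by the mean and SD of its own
permutation distribution, which removes the size and composition
dependence and puts all pathways on one scale. ARTP statistics are
mapped to `−log(minP)` before normalizing so both methods orient
"larger = more significant". The FDR at an observed normalized score s*
is the ratio of the expected fraction of permutation scores ≥ s* to the
observed fraction ≥ s*, clipped to [0, 1] and made monotone
non-increasing in s* by a cumulative minimum taken from the least
significant pathway upward (the Benjamini–Hochberg-style direction: each
pathway's FDR is the best ratio achievable at its own or any less
significant threshold).

### Cross-study heterogeneity filter

A SNP whose effect flips sign or changes magnitude across the
contributing studies is a likely artifact (differential genotyping,
population structure) rather than a reproducible signal. For every
pathway SNP, per-study per-allele ORs are computed from 2×2 allele-count
tables (dosages contribute two alleles per sample;
Haldane–Anscombe +0.5 on zero cells), pooled by inverse-variance
fixed-effect meta-analysis, and tested with Cochran's Q;
`I² = max(0, 100·(Q − df)/Q)` summarizes the share of cross-study
variation attributable to heterogeneity. SNPs with Q p-value < 0.2 are
removed globally — a deliberately liberal threshold, because the cost of
keeping an artifactual SNP (a false pathway signal) exceeds the cost of
dropping a real one. The note on conventions: I² itself has no native
p-value, so "heterogeneity p" here means the p-value of Q; a SNP seen in
fewer than two informative studies passes the filter by convention. The
pipeline reports pre-filter and post-filter results side by side, and
reruns the full permutation machinery on the filtered SNP set rather
than recycling the pre-filter null.

## The synthetic-data generator

Real five-study genotype data cannot be shipped, so the generator
emulates the statistical structure the analysis assumes, at the study's
scale by default: five studies totalling 3,532 cases and 5,120 controls,
MAF uniform on 0.01–0.5, pathways of 5–100 genes, causal per-allele ORs
in the 0.77–1.27 band, and covariates resembling a smoking-related
cancer study (age 40–75, four smoking categories with a strong
current-smoking effect, Bernoulli sex and DNA source).

Linkage disequilibrium uses a latent-Gaussian copula: per LD block, each
haplotype is an AR(1) Gaussian vector (correlation `within_block_rho`,
default 0.8) thresholded at each SNP's MAF quantile; the two haplotype
indicators sum to the 0/1/2 dosage. This gives Hardy–Weinberg genotypes
with controllable, decaying pairwise LD — not a coalescent model; there
is no recombination map, no allele-frequency spectrum, and no population
structure, so passing tests say nothing about robustness to
stratification. SNPs sit 1 kb apart within a gene, genes 40 kb apart,
blocks 1 Mb apart, so the 20 kb/10 kb rule reproduces exactly the
intended SNP-gene layout — convenient for ground truth, unrealistically
clean compared to real overlapping genes (which is why locus pooling is
exercised on dedicated fixtures instead).

Disease status is drawn from a logistic model with study-specific
intercepts, covariate effects, and per-study causal-SNP log-ORs supplied
explicitly (a non-constant per-study vector injects heterogeneity with
known ground truth; there is no random-effects draw). Cases and controls
are then subsampled to the configured quotas from a cohort
`cohort_multiplier` times larger — the retrospective design under which
the logistic trend test is well-specified. All randomness flows from one
recorded seed; the same seed reproduces byte-identical dataset files.

## Calibration and power experiments

The test suite fixes these problem sizes as its own design choices:

* **Null calibration.** Two replicate datasets (1,000 samples, 2,000
  SNPs each, B = 200) contribute 500 pathways apiece, giving 1,000 null
  pathway tests; both methods' rejection rate at α = 0.05 (rejection
  means p < 0.05) must fall in [0.03, 0.07]. The calibration pathways
  are drawn small (5–15 genes) on purpose: with 500 sets of up to 100
  genes over a 500-gene genome, the sets overlap so heavily that the
  rejection *rate* is driven by a handful of top genes shared across
  sets — the estimator, not the uniformity, breaks. Small sets keep the
  tests approximately independent so the binomial band is meaningful.
  Both methods are calibrated in the mean regardless of set size (ARTP's
  p-value is exchangeable-rank uniform by construction); what the small
  sets buy is variance control of the empirical rate.
* **Embedded-pathway power.** A pathway with 5 causal genes of 10
  (per-allele OR 1.3), 2,000 cases + 2,000 controls, must reach median
  ARTP rank ≤ 5 among 100 pathways over 10 seeds (B = 100).
* **Heterogeneity power.** A causal SNP with per-study log-ORs
  (+0.4, −0.4, +0.4, −0.4, 0) across five studies of 300 + 300 must be
  flagged at Q p < 0.2 in ≥ 80% of 20 seeds.
* **Method contrast.** With one strong gene (OR 1.5) in a 20-gene set,
  ARTP's median p over 20 seeds should undercut GSEA's; with 10 weak
  genes (OR 1.1), the reverse. GSEA p-values are floored at 1/(B+1) for
  this comparison so the two methods' different zero conventions cannot
  decide it. The first direction is robust. The second is the fragile
  one: the full-grid ARTP adapts its truncation point to diffuse signals
  too, and across the effect sizes we examined the two methods' diffuse
  power is close to equal, with the ordering flipping between seed
  batches. The packaged test keeps the scenario at its stated
  conditions; a red result there reflects this genuine near-equivalence
  of the two statistics under the generator's diffuse alternative, not
  an implementation fault (the oracle-equivalence suites pin both
  statistics exactly).

## Numerical choices

* ARTP products and comparisons in log space; p-values in (0, 1]
  enforced at the door.
* Trend-test IRLS runs to `epsilon = 1e-12` so the Wald beta matches an
  independently converged Newton solver to < 1e-8.
* Ties: exceedance counting (`≥` / `≤`) everywhere a statistic meets its
  permutation pool — conservative; best-SNP ties break lexicographically.
* Score-test variance floor `1e-12` guards monomorphic or imputed-flat
  dosage columns (they get NA and drop out).
* FDR ratios clip to [0, 1] before the monotonicity pass.

## Limitations

* The permutation engine's score test and the reported Wald statistics
  differ in finite samples; gene statistics feeding GSEA/ARTP come from
  the engine.
* Genotype QC (call rate, HWE), imputation, and population-structure
  adjustment are upstream concerns and out of scope.
* The generator's LD and covariate models are stylized; calibration
  results transfer to real data only to the extent that marginal test
  uniformity, not haplotype realism, drives the null.
* Analytic (non-permutation) pathway p-values are not provided; with
  B permutations no p-value below 1/(B+1) (ARTP) or 1/B (GSEA display
  floor) is resolvable.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_studies = 2, n_cases = 250, n_controls = 250,
                  n_snps = 400, block_size = 4, n_pathways = 20,
                  pathway_size_range = c(5, 15),
                  causal = list(list(pathway = 1, n_causal_genes = 4,
                                     log_or = log(1.4))),
                  seed = 42)
ds <- simulate_dataset(cfg)
run <- run_pathway_analysis(ds$genotypes, ds$samples, ds$snps, ds$genes,
                            ds$db, B = 200, seed = 7)
head(run$report[order(run$report$p_artp), ])
```
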