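---
title: "Dissecting a disease risk locus at the haplotype level"
author: "haplorisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a disease risk locus at the haplotype level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplorisk)
```

## The problem

A single strongly associated coding variant rarely exhausts the risk signal
of a locus. At the *APOE* region on chromosome 19 — the strongest common
genetic risk factor for late-onset Alzheimer's disease — the ε4 coding
change (defined jointly by rs429358 and rs7412) sits inside an extended
region of linkage disequilibrium spanning *PVRL2*, *TOMM40*, *APOE* and
*APOC1*, and non-coding haplotypes in the flanking genes carry risk effects
of their own. Dissecting such a locus requires a chain of analyses that are
usually scattered across half a dozen tools: variant QC on phased
genotypes, single-variant association, statistical fine-mapping from
summary statistics, enumeration of phased block haplotypes, a multivariate
dosage regression that conditions on the coding genotype, cross-cohort
meta-analysis, expression and allele-specific-expression testing, and
chromatin-contact enrichment. `haplorisk` implements that chain as one
tested package, and ships seeded generators that emulate each input with
known ground truth, so every stage is verifiable without access to any
controlled human dataset.

## Data model

Phased genotypes are held in a `PhasedGenotypes` object: per sample, two
haploid 0/1 allele vectors over an ordered set of biallelic variants, read
from a phased VCF (`readPhasedVcf()`, the allele left of `|` is haplotype
A) or simulated. Haplotype blocks are *defined variant lists* with an
effect (minor/risk) allele per variant; per-individual block haplotypes are
literal strings, one letter per variant, uppercase for the major and
lowercase for the minor allele (INDELs render as `I`/`D` tokens). A
`HaplotypeCatalog` stores the enumerated strings with chromosome
frequencies per phenotype group, and `buildDosageMatrix()` turns catalog
plus per-individual pairs into the N × (M + 1) dosage matrix: one column
per haplotype at frequency ≥ 1 % plus a pooled `"others"` column, every row
summing to exactly 2.

## Statistical components

**Variant QC.** `qcFilter()` removes variants with minor allele frequency
≤ 5 %, exact Hardy–Weinberg p ≤ 10⁻⁵, or imputation allele-dosage R² ≤
0.30 (all strict inequalities; variants lacking DR2 pass with a warning by
default). The HWE test is the Levene–Haldane exact conditional test:
all heterozygote counts compatible with the allele totals are enumerated,
`P(nAa | n, nA) = n! 2^nAa nA! na! / (nAA! nAa! naa! (2n)!)`, and the
two-sided p sums outcomes no more likely than the observed one. No mid-p
correction is applied, matching mainstream tooling.

**Association.** `logisticAssoc()` is maximum-likelihood logistic
regression by IRLS (`stats::glm`, relative deviance tolerance 10⁻¹⁴, 50
iterations — tight enough that the saturated 2×2 collapse reproduces the
closed-form Woolf log-odds-ratio and SE to 10⁻⁶). Quasi-complete
separation is detected via fitted probabilities within 10⁻⁸ of 0 or 1 and
flagged, never silently reported. Two-sided p-values come from
`pFromZ()`, evaluated in the normal tail directly so |z| up to 37 does not
underflow.

**LD.** `ldR2()`/`ldMatrix()` default to the squared Pearson correlation
of 0/1/2 dosages (the composite r² that PLINK's `--r` family reports);
`mode = "haplotype"` uses phase: r² = D²/(pA qA pB qB). Monomorphic
variants give `NA`, never 0. `stat = "r"` returns the signed correlation,
which is the form fine-mapping consumes. `expandBlockByLd()` grows a
seed set with r² ≥ 0.50 by default.

**Fine-mapping.** `caviarPosteriors()` enumerates causal-indicator
configurations up to `maxCausal` (default 3). Under configuration *c* the
Z-vector is multivariate normal with mean Σλ(c) (λᵢ = σ for causal
variants, default σ = 5.2) and covariance Σ = LD + ε·I (ridge ε = 10⁻³);
the prior is γ^|c|(1−γ)^(m−|c|) with γ = 0.01. Densities are computed in
log space through a Cholesky whitening and normalized by log-sum-exp, so
|z| ≈ 6.5 does not underflow. Because effect-allele orientation is
arbitrary, each variant is first flipped to make its Z non-negative and the
LD matrix is conjugated by the same signs (D Σ D, a congruence transform
that preserves positive definiteness); without this step the non-negative
non-centrality model penalizes negatively correlated perfect proxies and
recovery of an implanted causal variant drops from ≈ 90 % to ≈ 65 % on the
synthetic benchmark below. `credibleSet()` reports both the greedy
ρ-credible set (configuration mass, the null configuration counts for
every set) and the simple threshold rule (marginal posterior ≥ 0.10, the
reporting convention for "likely causal" variants). The defaults are
ordinary fine-mapping settings, exposed in `fineMapConfig()`; published
per-locus posteriors depend on unstated settings and are treated
qualitatively (ranking and threshold membership), not as numeric targets.

**Haplotype regression.** `haplotypeLogistic()` fits one joint model over
the minor-haplotype dosage columns of all supplied blocks — each block's
major haplotype (most frequent in controls, ties broken by overall
frequency then lexicographically) is excluded, so betas are log-odds
*relative to the major haplotype* — plus optional APOE ε4/ε2 genotype
dosages and covariates. The `"others"` column stays in the design by
default and is flagged composite; with the major column removed the design
is full rank. Both regression entry points QR-screen the assembled design
first and drop-and-report aliased columns, because IRLS does not reliably
pivot exact collinearities away. Quantitative endophenotypes go through
`haplotypeRobustLinear()`: Huber M-estimation (tuning 1.345, MAD scale,
via `MASS::rlm`) with robust standard errors and a normal reference; an
OLS engine is available for comparison. `partialSpearman()` implements
rank-transform → covariate residualization → Pearson correlation of
residuals, with t-based p on n − 2 − k df; with no covariates it equals
classical Spearman exactly. `adjustPvalues()` applies the two grouped
corrections used for biomarker panels: Bonferroni across haplotypes within
a biomarker, Benjamini–Hochberg across biomarkers within a haplotype.

**Meta-analysis.** `heterogeneity()` and `metaRe()` are the
DerSimonian–Laird formulas exactly as usually printed (Q, p(Q), I² =
max(0, (Q − (k−1))/Q)·100, τ² with its floor at 0, w* = 1/(se² + τ²));
`metafor::rma(method = "DL")` is used in the test suite as an independent
oracle, never as the implementation (note metafor defines I² differently).
`metaRe2()` is the Han–Eskin RE2 likelihood-ratio test: βᵢ ~ N(μ, seᵢ² +
τ²), H₀: μ = 0, τ² = 0, H₁ maximized by a bounded profile search over τ²
(bracket [0, 10·max(se²) + var(β)], Brent tolerance 10⁻¹⁰, boundary
checked explicitly, grid fallback), p from the asymptotic 50:50 χ²₁/χ²₂
mixture. The tabulated small-k corrections that METASOFT applies are not
reproduced; consequently the test is mildly conservative at k ≈ 6 (null
rejection ≈ 0.03 at α = 0.05 in the calibration the acceptance script
recomputes), which affects small-k p-values modestly and is a documented
limitation.

**Expression and ASE.** `inverseNormalTransform()` maps average ranks
through Φ⁻¹((rank − ½)/n); it is invariant under monotone transforms and
its output is exactly the target normal grid for tie-free data.
`expressionAssoc()` delegates to the robust haplotype regression (or OLS
for a single variant). `allelicFraction()` computes per-sample
minor-allele fractions above a depth filter (default 8 reads; the upstream
filter used for the published ASE tables is unstated, so this is an
explicit parameter); the minor allele is named by the caller, never
inferred. `imbalanceTest()` is the one-sample two-sided t-test of the mean
fraction against 0.5 (balanced expression) on n − 1 df, with the
zero-variance limit flagged.

**Contact enrichment.** On a binned symmetric contact matrix,
`expectedByDistance()` is the mean count per bin-separation stratum, and
`callEnrichment()` scores each pair (separation ≥ 1; the diagonal is
excluded, self-ligation dominates it) by enrichment = observed/expected
with an upper-tail Poisson p and BH FDR over all tested pairs. A stratum
with expected 0 falls back to a pseudocount of 0.5, flagged per record.
This distance-stratified expected model deliberately replaces spline-based
genome-wide fits: for a ~20-bin region it is transparent, has no smoothing
ambiguity, and its operating characteristics are calibrated on synthetic
matrices (below) rather than claimed to reproduce published FDR values.

**Population frequencies.** `apoeIsoformHaplotypes()` classifies each
phased chromosome by the rs429358/rs7412 combination (alt/ref → ε4,
ref/alt → ε2, ref/ref → ε3, alt/alt flagged as the rare ε1-like
haplotype); `populationFrequencies()` tabulates chromosome frequencies per
super-population panel label. Reproducing published per-population
frequencies requires the 1000 Genomes phase 3 phased chr19 panel (a
download documented in the README); the default test suite instead checks
the machinery on synthetic panels generated at those published
frequencies.

## The synthetic cohort generator

`simulateCohort()` draws, per individual, two haplotypes i.i.d. from a
`HaplotypePool`'s population frequencies (Hardy–Weinberg; recombination is
ignored because a ~200 kb block analyzed as intact haplotypes is the
analysis model itself), then covariates (age ~ Normal truncated to
[50, 100], matching late-onset cohort inclusion; sex ~ Bernoulli), then
case/control status prospectively from the logistic model
logit P = β₀ + Σ βₕ·dosageₕ + β_age(age − mean) + β_sex·sex. Prospective
sampling rather than case-control ascertainment keeps the generator simple
while leaving the log-odds-ratio estimand unchanged. Each component draws
from its own derived RNG sub-stream, so enlarging one component does not
perturb the others, and everything is byte-reproducible from the seed.
Expression traits are linear-additive in haplotype dosage with Gaussian
noise; ASE counts are Binomial(depth, f) with Poisson depth resampled away
from zero; contact matrices are Poisson with a power-law distance decay
C·d^(−α) and implanted enriched pairs. Both linear and logistic trait
modes are available for endophenotypes because the published effect scales
are stated per-figure, not per-model.

What the generator does *not* emulate — recombinants and phase-switch
errors, imputation dosage uncertainty, genotyping batch effects, reference
mapping bias in ASE counts, and matrix-balancing artifacts in contacts —
bounds what green tests mean: they certify the statistical machinery on
data that obey the stated models, not robustness to those real-data
pathologies.

## Numerical and design choices

* Coordinates are 1-based inclusive at the VCF boundary; internal arrays
  are 0/1 integer matrices. Multiallelic records are skipped with a
  warning (haplotype strings need one token per variant); unphased
  genotypes are an error under the default strict policy or masked on
  request; missing alleles cause per-block complete-case exclusion with a
  report, never imputation.
* Major-haplotype ties: control-group frequency, then overall frequency,
  then lexicographic — a deterministic reference in degenerate catalogs.
* HWE two-sidedness: sum of outcomes with probability ≤ observed, with a
  1 + 10⁻⁹ relative guard against ties lost to floating point.
* The fine-mapping ridge is added to the LD matrix rather than truncating
  eigenvalues, preserving LD structure with a one-line contract; a
  non-positive-definite matrix after the ridge is a hard error.
* RE2's τ² profile is unimodal in practice but the boundary τ² = 0 is
  always evaluated explicitly since `optimize()` never returns an
  endpoint.
* Robust regression uses Huber M-estimation rather than the MM-estimator
  some published pipelines name, because the latter's tuning is unstated
  there; on clean Gaussian data the two agree to well within combined
  standard errors, and the contrast that matters — resistance to gross
  outliers that drag OLS — is property-tested.

## Problem sizes used in the checks

The test-suite and acceptance-script simulations use: 2 000 individuals ×
200 replicates for confidence-interval coverage of a true haplotype
log-OR of 0.4; 3 000 individuals, 20 block variants and 50 seeds for
implanted-causal recovery; 2 000 null meta-analyses (k = 6) for RE2
calibration; 1 000 balanced ASE cohorts (n = 200, depth 100) for t-test
calibration; 100 seeded 12-bin contact matrices (baseline 50, decay 1,
one fold-10 pair) for detection; and 500 random instances for the
haplotype-enumeration brute-force identity. These sizes give Monte-Carlo
standard errors comfortably inside the asserted bands.

## A small worked run

```{r example}
pool <- HaplotypePool(
    variants = data.frame(id = c("v1", "v2", "v3"), chrom = "19",
                          pos = c(45411941L, 45412079L, 45412200L),
                          ref = c("T", "C", "A"), alt = c("C", "T", "G")),
    haplotypes = c(H1 = "000", H2 = "110", H3 = "011"),
    frequencies = c(H1 = 0.6, H2 = 0.3, H3 = 0.1))
sim <- simulateCohort(pool,
    cohortSpec(1000, beta0 = -0.5, betaHaplotypes = c(H2 = 0.4), seed = 1),
    "pop")
ph <- extractBlockHaplotypes(sim$genotypes,
    data.frame(id = c("v1", "v2", "v3"), effect_allele = c("C", "T", "G")))
cat_ <- enumerateHaplotypes(ph,
    groups = ifelse(sim$phenotypes$status == 1, "AD", "NC"))
cat_
dm <- buildDosageMatrix(cat_, ph)
haplotypeLogistic(dm, sim$phenotypes$status,
                  covariates = sim$phenotypes[, c("age", "sex")])
```

The implanted log-odds ratio of 0.4 on the H2-derived minor haplotype is
recovered within sampling error, with the beta expressed relative to the
all-major haplotype, exactly as the dosage-matrix model defines it.

## Known limitations

Fine-mapping enumerates configurations, so m·choose(c) growth caps the
variant count (a guard errors before memory does); no functional priors or
summary-statistic imputation are provided. RE2 p-values at very small k
are conservative as described. The Hi-C caller targets small regions and
deliberately omits matrix balancing and TAD structure. Stratified analyses
drop the stratifying covariate from the model inside each stratum. None of
the estimators model related individuals; panels are assumed unrelated.
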