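---
title: "Models, calibration and design choices in pcoscausal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, calibration and design choices in pcoscausal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pcoscausal)
```

This vignette records the statistical models the package implements, the
assumptions they lean on, the tunable parameters and their defaults, what
the synthetic-data generators do and do not emulate, and the choices made
where the design was genuinely open. Nothing here reports an empirical
number that the test suite or `scripts/acceptance.R` does not itself
compute.

## Case-control association and genomic control

`logistic_assoc()` fits, per SNP, the additive-model logistic regression
logit P(case) = α + β·dose + γ'·covariates by iteratively reweighted least
squares (`stats::glm.fit`, convergence tolerance 1e-10, default cap 25
iterations), reporting the Wald β, its standard error from the inverse
observed information, and a two-sided normal p capped at 1 (no mid-p).
Quasi-complete separation — a real hazard for rare alleles in small strata —
is detected by coefficient divergence (|β| > 15, roughly an odds ratio of
3×10⁶, far outside anything estimable from finite case-control data) and the
variant is flagged rather than reported; non-convergence is flagged
likewise. The additive dosage coding assumes per-allele multiplicative odds;
dominance is out of scope.

`genomic_control()` estimates the inflation factor λ as the observed median
1-d.f. χ² over its null median `qchisq(0.5, 1) ≈ 0.4549`, and divides all
statistics by λ only when λ > 1. Leaving deflation (λ ≤ 1) uncorrected is
the standard convention: deflated statistics indicate over-correction
elsewhere, not confounding to be amplified.

## Inverse-variance meta-analysis

All pooling happens on the log-odds scale. Printed odds-ratio intervals are
back-converted by `ci_to_se()` under the assumption that the interval was a
symmetric Wald interval on the log scale at the stated level:
β = ln(OR), se = ln(CI_hi/CI_lo)/(2z) with z = Φ⁻¹(0.975) = 1.959964 for
95%. A degenerate point interval yields se = 0 with a warning rather than an
error, since direction-only rows do occur in published tables. `ivw_meta()`
is the fixed-effect estimator; Cochran's Q is referred to χ²(k−1).
Random-effects pooling is deliberately absent: the reconstructed tables
combine two or three cohorts measuring one population-level quantity, where
the fixed-effect model is the estimand being reproduced.

Reconstructing a published combined row from printed per-arm intervals is
approximate in one documented way: when arms share participants (the
follow-up arms here share some clinically validated cases), the printed
combined analysis de-duplicated them, which per-arm IVW cannot. The
acceptance checks carry that tolerance explicitly.

## Mendelian randomization by weighted allele scores

The instrument is the weighted score Sᵢ = Σⱼ wⱼ·doseᵢⱼ with wⱼ the published
per-allele effect on the exposure in standard-deviation units. MR's causal
reading rests on the usual three assumptions — instruments associated with
the exposure, independent of confounders, and acting on the outcome only
through the exposure; the package's contribution is the estimating
machinery plus the sensitivity diagnostics used to probe the third
assumption.

**Harmonization** (`build_score()`, `harmonize()`, `mr_summary()`): dosages
are aligned to the score's effect allele by direct letter match or strand
complement; allele-swapped storage flips the dosage (2 − dose) or the sign
of β and complements the frequency. Palindromic (A/T, C/G) SNPs carry no
strand information in their letters and are resolved by allele frequency
when both sides are informative (|eaf − 0.5| > 0.08, a margin conservative
enough that drift and sampling noise rarely cross sides), otherwise dropped
with a warning. Missing dosages are mean-imputed from the sample frequency,
which preserves the score's expectation and only slightly shrinks its
variance at realistic missingness.

**Calibration** (`calibrate_score()`): the constant converting one raw
score unit into exposure standard deviations is the OLS slope of the
(standardised) exposure on the raw score. Dividing the score by it makes
`mr_individual()` — logistic regression of the outcome on the calibrated
score — the ratio (two-stage) estimator. Its reported standard error is
first-order: it conditions on the calibration constant, ignoring the
denominator's sampling variability. With strong instruments (the intended
regime; the simulated cohorts give first-stage F well above 50) the
neglected term is a few percent of the variance. This is a documented
limitation, not an oversight.

**Summary-level estimator** (`mr_summary()`):
β̂ = Σ wⱼβⱼ/sⱼ² / Σ wⱼ²/sⱼ², se = (Σ wⱼ²/sⱼ²)^(-1/2). The suite verifies to
1e-10 the algebraic identity with inverse-variance-weighted per-SNP Wald
ratios, and verifies on shared simulated data that the summary and
individual-level estimators agree within one combined standard error.

**What "recovered" means.** The outcome model is logistic, so the marginal
coefficient on a score explaining part of the exposure is attenuated by
non-collapsibility: regressing on S* = calibrated score rather than the full
exposure x shrinks β by roughly (1 + 0.346·β²·Var(x − E[x|S*]))^(-1/2).
With β = ln 1.9 and instruments explaining a few percent of exposure
variance, the attenuation is ~4% — visible as estimates centring just below
the generating value while 95% CI coverage stays in its nominal band, which
is exactly what the recovery suite measures (grid of causal odds ratios
{1.0, 1.11, 1.6, 1.9}, n = 80,000, 15 instrument SNPs with per-allele
effects U(0.02, 0.1) s.d., 200 seeds per grid point; type-I error from
1,000 null replicates at n = 5,000, where size does not depend on n).

**Sensitivity** (`per_snp_sensitivity()`): per-SNP Wald ratios βⱼ/wⱼ with
first-order standard errors sⱼ/|wⱼ|, paired with precisions 1/se for funnel
plots; a SNP is flagged when its ratio sits more than 3 of its own standard
errors from the combined estimate — a deliberately blunt screen for
pleiotropic outliers, not a formal test. `trait_screen()` is the Bonferroni
threshold 0.05/n_traits (0.0033 at 15 traits). `cumulative_score_trait()`
regresses ln(trait) on the raw risk score by OLS for strictly positive
biomarkers such as serum AMH; log-normality of the biomarker is assumed, as
is conventional for hormone concentrations.

For exposures reported on transformed scales (SHBG and DHEAS were analysed
in natural-log units in their source GWAS), the published per-allele weights
are only approximately in s.d. units; the calibration constant is the
user-visible scalar absorbing that approximation — supply a calibration
estimated on data of the target scale rather than 1.

## Selection tests

**Region overlap** (`region_overlap_test()`): intervals are held 0-based
half-open (BED native) and merged on construction; "within 1 Mb" means the
SNP lies inside the region grown by the flank on each side, with flanked
intervals re-merged before their total length L is computed so overlapping
flanks are never double-counted. The p-value is the exact binomial tail
P(X ≥ hits), X ~ Bin(n_snps, L/G). `overlap_binomial_p()` exposes the tail
directly so published counts and lengths can be re-tested without the
region coordinates. The test treats lead SNPs as uniformly placed on an
accessible genome of stated length — adequate for ten approximately
independent GWAS signals.

**Qx** (`qx_test()`): genetic values Z_m = Σⱼ 2wⱼp_mj per population, mean-
centred, scaled by the additive variance 4Σwⱼ²p̄ⱼ(1−p̄ⱼ), and formed into a
quadratic form against the drift covariance F estimated from genome-wide
panel SNPs in its simplest mean-centred form (each panel SNP contributes the
outer product of (p_m − p̄)/√(p̄(1−p̄)); the pseudo-inverse handles the rank
M−1). Significance never relies on the χ² approximation: the null is built
by replacing every tested SNP with a random panel SNP from the same
minor-allele-frequency bin (20 equal-width bins on [0, 0.5], edge ties to
the lower bin, empty bins widened to their nearest non-empty neighbours with
a warning) and recomputing the statistic, default 10,000 times;
p = (1 + #{null ≥ observed})/(n_boot + 1).

Two roles of the panel are deliberately separated. The covariance estimate
uses only panel SNPs with mean minor-allele frequency ≥ `panel_maf_min`
(default 0.05): near-fixed SNPs make the heterozygosity standardisation
explode and a handful of them can corrupt F — the same reason
genotyping-chip reference panels are ascertained towards common variants.
The matching pool keeps every polymorphic panel SNP, so tested SNPs that
happen to sit in rare-frequency bins are matched to SNPs of like frequency
rather than to common ones with smaller drift scale. The type-I calibration
suite (400 seeded drift-null runs, 10 SNPs, 4 populations, Balding–Nichols
panels at F_ST = 0.1, n_boot reduced to 1,000) checks the resulting size at
α = 0.05. Population subsets for the covariance are explicit arguments
(`populations`), since which populations enter the drift estimate is an
analysis choice, not a property of the data.

**iHS** (`ihs()`, `standardize_ihs()`): EHH is the probability that two
random haplotypes carrying the focal allele are identical from the focal
site out to a marker, computed exactly by partition refinement; curves are
trapezoid-integrated outward until EHH < 0.05 (both the threshold and the
integration rule are the common convention and are exposed as `min_ehh`),
summed over both directions into iHH per allele class, and
iHS = ln(iHH_A/iHH_D). A derived class with zero integrated homozygosity is
flagged, not fabricated. Standardisation subtracts the mean and divides by
the s.d. within derived-allele-frequency bins (default 20), so standardised
scores are comparable across frequencies; callers following the usual scan
convention should pre-filter to focal minor-allele frequency > 0.2.

**DIND** (`dind()`): nucleotide diversity π (mean pairwise differences per
site, computed from column allele counts) within a window around the focal
site, separately for ancestral- and derived-allele carriers; the statistic
is π_A/π_D, with π_D = 0 reported as +Inf and flagged. Both haplotype
statistics are verified exactly against brute-force pair-enumeration oracles
on small matrices.

## Gene-set enrichment

`gene_scores()` maps each gene to its best SNP p within a window extending
110 kb beyond the transcript start and 40 kb beyond the end, flipped for
minus-strand genes; boundaries are closed (a SNP exactly at the window edge
counts). Genes overlapping supplied exclusion regions (the HLA region being
the canonical case, where LD defeats the confounder model) are dropped;
genes with no window SNP are left unscored rather than given a pseudo-score.

`adjust_scores()` regresses −ln(best p) on log gene length, log SNP count
and log1p of the LD proxy, then ranks the residuals (average ranks on ties,
so the result is independent of input order). The log transforms are not
cosmetic: the null expectation of a best-of-n p-value is E[−ln min(U₁..Uₙ)]
= Hₙ ≈ ln n + γ, linear in log SNP count, so the confounder model is
well-specified on that scale — the deconfounding test (5,000 genes whose
scores are pure min-of-n artefacts) requires the adjusted ranks to be
uncorrelated with SNP count. The LD proxy is the window SNP count unless
genotypes are available to count r² > 0.5 partners; the exact LD covariates
of the original gene-score method are not fully specified publicly, and this
proxy is the documented approximation. Collinear covariates are dropped with
a warning rather than failing the run.

`enrichment()` compares each set's count of member genes above the 95th or
75th percentile of all adjusted scores with the same count in `n_perm`
random same-size gene draws without replacement;
p = (1 + #{null ≥ obs})/(n_perm + 1), Benjamini–Hochberg FDR across sets
within each cutoff. The default `n_perm = 10,000` is a desk-scale setting;
the original method's 1,000,000 permutations are one argument away. A tiny
instance (20 genes, 3-member set) is checked against exhaustive enumeration
of all C(20,3) draws.

## Synthetic-data generators

`simulate_cohort()` draws unlinked genotypes Binomial(2, p) per SNP (exact
HWE), builds the exposure as the additive genetic score plus Gaussian noise,
standardises it within-sample (so "per 1 s.d." downstream means realised
s.d., matching how allele scores are calibrated), and draws the outcome from
a logistic model whose intercept is solved by bisection to hit the target
prevalence within 1e-3. Default prevalence 0.06 matches the case fraction of
a large self-reported discovery cohort (~5,200 cases / ~83,000 controls).
All draws come from one seeded generator per call; the global RNG state is
saved and restored (`withr::with_seed`), so generators are reproducible and
side-effect-free.

`simulate_pop_freqs()` is the Balding–Nichols model: population frequencies
Beta-distributed with mean p and variance F_ST·p(1−p), clipped to [0, 1].
It generates marginal drift of the right first two moments; it does not
model shared population history (a tree-structured F), migration or
ascertainment.

`simulate_haplotypes()` is a forward Wright–Fisher simulation of 2N
haplotypes resampled directly each generation (no diploid pairing), with
infinite-sites mutation on a linear map of discrete sites and, optionally, a
selected derived allele with multiplicative fitness (1 + s) per copy,
injected at frequency 1/2N after a configurable burn-in and re-injected if
lost. Recombination is omitted: EHH decay is driven by mutation alone, which
suffices to exercise and order the haplotype statistics but does not emulate
realistic LD decay, recombination hotspots or the spatial scale of real
sweep signatures. Neutral runs are checked against the Watterson
expectation for the singleton fraction of the site-frequency spectrum.

Consequently, passing tests demonstrate correctness of the statistical
machinery under the stated generating assumptions — independent SNPs, HWE,
logistic outcomes, marginal drift, mutation-limited haplotype structure.
They do not demonstrate robustness to LD between instruments, population
stratification within a cohort, genotyping error, imputation uncertainty or
ascertainment, none of which the generators produce.

## Problem sizes and numerical conventions

The test suite runs the recovery grid at n = 80,000 with 200 seeds per
causal odds ratio, the null size check at 1,000 replicates, the Qx
calibration at 400 runs with n_boot = 1,000, Wright–Fisher checks at 2N of
100–200 over hundreds of generations, and exact-oracle haplotype checks on
≤ 8-haplotype matrices; these sizes were chosen as the smallest at which the
binomial noise of the measured rates is comfortably inside the asserted
bands. Other conventions: two-sided p-values are min(1, 2Φ(−|z|));
permutation and bootstrap p-values use the add-one form and can never be 0;
output tables serialise floats at 6 significant digits with p-values in
scientific notation; genomic intervals are 0-based half-open internally,
converted at the BED/VCF boundaries; 1-Mb signal windows mean ±500 kb around
a lead SNP and are configurable.

## Known limitations

Fixed-effect meta-analysis only; first-order (delta-method) MR standard
errors; no MR-Egger or median estimators; palindromic-SNP resolution
requires allele frequencies; the Qx drift covariance assumes exchangeable
SNP-wise drift around a shared mean rather than an explicit population
tree; iHS without a recombination map measures position-scaled, not
genetic-distance-scaled, homozygosity decay; enrichment permutes gene
labels, not LD blocks, so clumped signals can inflate small sets; the
simulators' omissions listed above.
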