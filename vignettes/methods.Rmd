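---
title: "Methods: linking GWAS risk loci to regulatory chromatin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking GWAS risk loci to regulatory chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskloci)
```

## The problem

Most GWAS risk variants for chronic lymphocytic leukemia (CLL) and other
common diseases fall in non-coding DNA, so their mechanism must be read
off the regulatory genome rather than the protein code.  `riskloci`
implements an integrative annotation pipeline for this setting: risk
loci are expanded from sentinel SNPs into linkage-disequilibrium (LD)
regions, scored for chromatin-state enrichment against a genome-wide
background, and interrogated with molecular quantitative trait locus
(QTL) scans across four layers (chromatin accessibility, H3K27ac
histone acetylation, DNA methylation, gene expression), allele-specific
read-count tests, and transcription-factor motif disruption scoring.

Because the underlying patient-level data are controlled-access, the
package ships a first-class synthetic-data generator that emulates every
layer with known planted effects.  All statistical machinery is exercised
end-to-end on those fixtures; the generator's truth tables make each
stage's operating characteristics testable.

## Risk loci and LD regions

A risk locus is anchored at its sentinel SNP (the strongest association
at the locus).  Its LD region is the interval spanning all SNPs with
`r^2 >= 0.2` to the sentinel (`define_ld_region`); the threshold
comparison is inclusive and the interval is 0-based half-open, closing
at one past the last proxy position.  For phased haplotypes
`r^2 = D^2 / (pA pa pB pb)`; for unphased dosages it is the squared
Pearson correlation.  The spanning-interval reading (rather than a union
of proxy points) was adopted because the locus is treated as one
contiguous regulatory neighbourhood in all downstream interval
operations.

Background regions are the merged LD regions of every panel SNP with any
merged interval that overlaps a risk locus removed entirely.  Removal is
region-level, not base-level trimming: a background interval touching a
risk locus is conservative to exclude outright, and it keeps the
background construction independent of locus boundary precision.

## Chromatin-state enrichment

Segmentations partition the genome into 200-bp bins over 12 states
(active/weak/poised promoter, strong/weak enhancer, transcription
states, repressed and low-signal states).  For a locus region and a
sample, coverage fractions per state are base-weighted and sum to one.
Enrichment per state is

    E = log2( C[state; locus] / C[state; background] )

with two deliberate sentinels: a zero locus fraction gives `NaN` and a
zero background fraction with positive locus fraction gives `+Inf`.  No
pseudocounts are added; sentinels are excluded from medians instead.
This keeps the enrichment literal and makes "state absent from the
locus" distinguishable from "state depleted".

A locus counts as *active* when at least one proxy SNP sits in an active
state (ActProm, StrEnh1, StrEnh2) in at least one sample; a sample-level
*active fraction* counts loci with strictly positive `E` for any active
state.  Strict positivity was chosen because the natural null (locus
coverage equal to background) must not count as enrichment.

Loci are grouped by a deterministic rule on median-across-samples
enrichment: state families Active = {ActProm, StrEnh1, StrEnh2}, Weak =
{WkProm, WkEnh}, Transcribed = {Txn_Trans, Txn_Elong, Wk_Txn}; group 1 =
active only, 2 = active + transcribed, 3 = weak only, 4 = weak +
transcribed, 5 = neither.  Active takes precedence over weak when both
are positive.  This grouping is a reconstruction of the five observed
locus classes and is documented as a heuristic, not a fitted model.

The permutation machinery (`permutation_expected`) resamples
length-matched interval sets uniformly from the background (weighting
each background interval by its number of valid placements) and reports
the mean permuted count, an add-one-corrected empirical p-value
`(1 + #{perm >= obs}) / (n_perm + 1)` (never exactly zero), and a Fisher
comparison of observed versus rounded expected counts.  Only placement
is randomized; no GC or SNP-density matching is attempted.

Cross-trait comparison of per-sample active fractions uses the
two-sided Wilcoxon rank-sum test with Bonferroni correction over the
number of trait pairs.

## Statistical core

All primitives are implemented in the package and tested against
independent oracles (base-R tests, dense enumeration, numeric
integration):

* **Fisher exact 2x2, Hardy-Weinberg exact, beta-binomial test** — all
  two-sided p-values use the minimum-likelihood rule: sum the
  probabilities of every outcome no more likely than the observed one
  (with a `1 + 1e-7` tie guard against floating-point ties).  This
  matches the base-R Fisher convention and is applied uniformly since no
  alternative two-sided rule was specified for the exact tests.
* **Wilcoxon rank-sum** — the statistic is the Mann-Whitney U (pairs
  with `x > y` plus half the ties).  The default is the tie-corrected
  normal approximation with a 0.5 continuity correction; exact mode
  enumerates the permutation distribution and refuses ties.
* **Multiple testing** — Benjamini-Hochberg step-up and Bonferroni,
  implemented directly and checked against `p.adjust`.
* **Inverse normal transform** — rank `r` maps to
  `qnorm((r - 0.5) / n)` with average ranks for ties.  The simple
  `-0.5` offset was preferred over Blom-style constants; constant input
  is an error rather than silent zeros, because a constant feature
  reaching the transform indicates an upstream defect worth surfacing.
* **Beta-binomial likelihood and MLE** — the log-likelihood is the sum
  of `log[C(n,k) B(k+a, n-k+b) / B(a,b)]`.  Fitting maximizes over
  `(log a, log b)` from a method-of-moments start using BFGS with a
  Nelder-Mead polish; the reported optimum's numeric gradient norm is
  stored, and parameters are capped at `1e6`, where the distribution is
  numerically binomial (the cap keeps that limit finite and explicit).

## Genotype reconciliation

Imputed probability triples become hard calls when the uncertainty
`1 - max(triple)` does not exceed 0.1.  SNP QC fails on call rate
below 95%, minor allele frequency below 1%, or exact Hardy-Weinberg
p below 1e-6, accumulating all reasons.  Sample QC flags
heterozygosity outliers (3 SD) and related pairs (genotype identity
above 0.9; the lower-call-rate member is dropped).

`reconcile` applies the assignment ledger in a fixed order: drop
low-information SNPs (info < 0.85), call from probabilities, mask calls
inside per-sample copy-number-altered intervals, validate WGS calls
(depth >= 10, quality flags, normal equal to tumor), exclude samples
with imputed/WGS concordance below 90%, demote SNPs with concordance
below 90% to WGS-only, resolve remaining conflicts to WGS, and fill
imputation gaps from WGS.  Two denominators required decisions the
source description leaves open: per-sample concordance is computed over
a designated fidelity (sentinel) subset when one is supplied, and
per-SNP concordance over the full sample universe — a SNP that imputes
badly does so regardless of which samples survive, and at small cohort
sizes any other reading makes the sample-level and SNP-level rules
collide.  Every output call carries a provenance label (imputed / wgs /
filled / masked / conflict_resolved / missing) and the report's counts
partition the matrix exactly.

## QTL scan

Features enter the scan when present in at least
`max(2, ceiling(0.10 x subgroup))` patients of at least one
sentinel-genotype subgroup; expression features use a strict
`> 4.5` floor instead of peak presence.  Latent confounders are removed
by principal-component residualization: features are standardized, the
top-k left singular vectors projected out.  The per-layer defaults (10,
10, 45, 65 components for accessibility, H3K27ac, methylation,
expression) follow the factor counts appropriate for reference-scale
matrices (hundreds of thousands of probes).  On the synthetic cohort
(tens to hundreds of features) those counts would remove the signal
itself, so `run_pipeline` removes exactly the generator's configured
number of latent factors instead, capped by the layer default — on
simulated data the confounder dimension is known, and the choice is
recorded in the run manifest.

Residualized features are inverse-normal transformed per feature and
regressed on risk-allele dosage (0/1/2); the slope's two-sided t test at
`n - 2` degrees of freedom gives the p-value.  The candidate features
for a locus are those intersecting the TAD window spanning its LD
region; the same window is applied to all four layers for symmetry (the
TAD restriction is only essential for expression, but a common window
keeps per-layer test universes comparable).  BH correction is applied
per layer across all sentinel-feature tests, with significance at
FDR < 0.05.  Direction concordance of overlapping significant QTLs
expects equal slope signs between accessibility and H3K27ac and opposite
signs for methylation against either.

## Allelic imbalance

Testable SNPs are LD proxies inside accessibility peaks with at least 3
heterozygous samples and at least 10 pooled reads.  Heterozygote counts
pool across samples after a per-sample reference-ratio filter of
[0.1, 0.9] (closed interval — the endpoints are kept), which guards
against genotyping errors; homozygotes never contribute.  The null is a
beta-binomial fitted on pooled counts of background SNPs (not in LD with
any sentinel, with optional exclusion regions removed).  Each testable
SNP's pooled count is tested two-sided against that null
(minimum-likelihood rule), BH-corrected at FDR < 0.1, and reported with
its pooled reference ratio and a 95% normal-approximation interval using
the pooled read total as the sample size (clipped to [0, 1]).
Enrichment of imbalance among accessibility-QTL SNPs is a Fisher exact
test on the 2x2 of significance by overlap.

## The synthetic cohort

`sim_config()` fixes the study conditions; the defaults are the
generator's definition of the experiment, not tuning knobs:

* **Cohort**: 42 risk loci on a 10-Mb contig, 99 genotyped samples,
  7 chromatin-state samples, 12 SNPs per LD block with the sentinel at
  the centre, 1000 panel haplotypes.
* **LD**: within a block each SNP copies its left neighbour's haplotype
  allele with a switch probability of `(1 - sqrt(decay))/2`, so `r^2`
  decays by the factor `decay` (default 0.9) per SNP step; blocks are
  independent.  This block-copy channel gives tunable LD without
  coalescent machinery; it does not reproduce recombination hotspots or
  allele-frequency/LD correlations of real panels.
* **Chromatin**: 34 loci are enriched (active-heavy state frequencies
  in every sample), 5 more carry a single active proxy-SNP bin in one
  sample (active but not enriched), 3 exclude active states entirely —
  so 39 of 42 loci have an active proxy SNP and the expected per-sample
  active fraction is 34/42.  Background bins draw from a fixed
  12-state frequency vector dominated by low-signal chromatin.
* **QTLs**: planted per-layer locus sets (14 accessibility, 9 H3K27ac,
  28 methylation, 20 expression) whose union covers 36 of 42 loci, with
  effect size 1 on the dosage scale, shared latent confounders
  (3 factors, loadings ~ N(0, 0.36)), and unit noise.  Accessibility and
  H3K27ac effects share sign; methylation effects are opposite.
* **Allele counts**: 225 proxy SNPs in peaks, 189 testable (the rest
  receive near-zero depth), 9 imbalanced at a fixed latent ratio of
  0.8, read depth ~ Poisson(40) per heterozygote.  Each SNP's latent
  sampling ratio is shared across its heterozygous carriers, drawn from
  Beta(20.5, 20.3) for null SNPs — so pooled heterozygote counts are
  exactly beta-binomial and the null refit recovers the shapes.
  Homozygote counts include a 0.5% error allele, which exercises the
  ratio filter.  5000 background SNPs with independent Hardy-Weinberg
  genotypes feed the null fit.
* **Genotype sources**: the imputation layer concentrates 93-100% of
  probability on a genotype with a 1% error rate; ~1% of SNPs get a low
  information measure; the WGS layer carries planted normal/tumor
  discordances, low-depth calls, and three per-sample CNA intervals.

All randomness flows from one root seed through named substreams
(`stage_seed`), so each generator is reproducible in isolation and a
bundle is byte-identical under a fixed configuration.

What passing tests on these fixtures do **not** show: robustness to
reference bias in allele counts (WASP-style filtering is assumed
upstream), to population structure in the genotypes, to
non-Gaussian feature noise, to segmentation errors, or to LD panels
mismatched to the cohort.  The fixtures are calibrated for the planted
effects to be comfortably detectable at the configured sample sizes;
real effect sizes near the detection boundary will behave differently.

## Motif disruption

Position weight matrices are scored with an information-content-weighted
log-likelihood ratio: with pseudocounted position probabilities `q_p`
(pseudocount 1e-3) and background `bg`,
`score = sum_p IC_p * log2(q_p(base)/bg(base))`, where
`IC_p = 2 + sum_b q_p(b) log2 q_p(b)`.  A uniform PWM scores zero
everywhere.  For each allele of a SNP, every motif window covering the
SNP is scanned on both strands and the maximum is kept.  Score p-values
are the exact tail probability of a background-random sequence, by
exhaustive position-wise convolution for motifs up to 8 positions and a
discretized convolution (grid step 1e-3) beyond.  Deltas are computed on
scores normalized to the PWM's achievable range, so the strong/weak
disruption thresholds (0.7 / 0.4, closed at the boundary) are comparable
across motifs; these thresholds are package conventions, and scores are
comparable within this implementation only.

## Problem sizes and determinism

The shipped test-suite and acceptance runs use the default cohort
(42 loci, 99 samples, 5000 background SNPs) for single end-to-end runs,
a reduced 8-locus/60-sample cohort for per-module fixtures, 50 seeds per
arm for the imbalance calibration study, 15 seeds for QTL recovery, and
5000 single tests for null-uniformity checks — sizes at which every
planted-effect check is stable across seeds while the whole suite runs
in minutes on one CPU.  `run_pipeline` is a pure function of
(configuration, seed): identical inputs give identical output tables,
and the run manifest echoes every threshold.

## Known limitations

* The locus grouping rule and the PCA residualizer are reconstructions
  of methods whose originals (manual curation; a Bayesian latent-factor
  model) are not re-implemented; results at the margins can differ.
* The permutation scheme matches template lengths only.
* Pooled imbalance testing ignores between-sample overdispersion beyond
  the SNP-level beta; a sample-level hierarchical model is out of scope.
* Interval logic assumes a single linear contig; multi-chromosome input
  requires per-contig application.
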