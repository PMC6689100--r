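# riskloci

Integrative regulatory annotation of GWAS risk loci: an R package that
links disease-associated sentinel SNPs to the regulatory chromatin
through LD-region construction, chromatin-state enrichment, molecular
QTL mapping, beta-binomial allelic-imbalance testing, and
transcription-factor motif disruption scoring — with a seeded
synthetic-data generator so the whole pipeline runs and is testable
without access to controlled patient data.

## Who this is for

Statistical geneticists and regulatory genomicists who need a tested,
reproducible implementation of the standard post-GWAS functional
annotation toolkit for a cohort with multi-layer molecular profiles
(chromatin accessibility, H3K27ac, DNA methylation, expression), or who
want calibrated synthetic cohorts with planted effects to benchmark
such analyses.

## The methods at the core

* **LD0.2 risk regions** — a risk locus is the interval spanning all
  SNPs with r² ≥ 0.2 to its sentinel SNP; background regions are the
  merged LD regions of all panel SNPs minus intervals overlapping any
  risk locus.
* **Chromatin-state enrichment** — per sample and state *j*, a locus
  *i* is scored as

  E<sub>ij</sub> = log₂( C<sub>j;i</sub> / C<sub>j;B</sub> )

  where C<sub>j;i</sub> and C<sub>j;B</sub> are the fractions of the
  locus and of the background covered by state *j* in a 12-state,
  200-bp-binned segmentation.
* **QTL scan** — feature values are residualized against latent
  confounders (top principal components), inverse-normal transformed,
  and regressed on risk-allele dosage; per-layer Benjamini–Hochberg FDR
  at 0.05, with candidate features restricted to the TAD window of each
  locus.
* **Allelic imbalance** — heterozygote reference/alternative read
  counts are pooled per SNP (per-sample ratio filter 0.1–0.9), tested
  two-sided against a beta-binomial null fitted by maximum likelihood on
  background SNPs, at FDR 0.1 with a normal-approximation CI on the
  pooled ratio.
* **Motif disruption** — PWM windows over each SNP are scored with an
  information-content-weighted log-likelihood ratio on both strands for
  both alleles; score p-values come from the exact convolution of the
  background score distribution.

Genotypes are assembled by a reconciliation ledger that converts
imputation probability triples to calls (uncertainty ≤ 0.1), applies
SNP/sample QC (call rate, MAF, exact Hardy–Weinberg; heterozygosity and
relatedness), masks copy-number-altered intervals, and merges with
WGS calls under 90% concordance rules.

## Worked example

The 2×2 test behind the question "do SNPs with allelic imbalance
overlap accessibility QTLs more often than expected?" — 8 of 9
imbalanced SNPs overlap, against 35 of 180 non-imbalanced:

```r
library(riskloci)
fisher_exact_2x2(8, 1, 35, 145)
#> Fisher exact test (two-sided)
#>   statistic = 8   p = 3.11e-05
#>   estimate  = 33.14286
```

The p-value of 3.1×10⁻⁵ says the overlap is far beyond chance; the
odds ratio of 33 quantifies how strongly imbalance and QTL status
co-occur.  Comparing per-sample active-locus fractions between two
traits (7 samples each, completely separated):

```r
cll <- c(0.86, 0.84, 0.81, 0.81, 0.80, 0.76, 0.74)
crc <- c(0.59, 0.57, 0.54, 0.53, 0.50, 0.47, 0.45)
compare_active_fractions(list(CLL = cll, CRC = crc))
#>   trait_a trait_b  W    p_value median_a median_b median_diff p_corrected
#> 1     CLL     CRC 49 0.00214071     0.81     0.53        0.28  0.00214071
```

W = 49 is the maximum possible Mann–Whitney statistic for 7-vs-7
(every CLL fraction exceeds every CRC fraction); the median difference
of 0.28 is the effect size.  Fitting the beta-binomial null on
simulated background allele counts recovers the generating shapes:

```r
set.seed(7)
n <- rpois(2000, 40); k <- rbinom(2000, n, rbeta(2000, 20.5, 20.3))
fit_betabinom(k, n)
#> Beta-binomial null model
#>   alpha = 22.23, beta = 21.93  (mean ratio 0.5034)
#>   log-likelihood -5752.632 over 2000 SNPs
```

A full synthetic cohort and pipeline run:

```r
res <- run_pipeline(sim_config(seed = 1))
res
#> Pipeline result
#>   42 risk loci; 39 active (>=1 proxy SNP in an active state)
#>   mean per-sample active fraction: 0.81
#>   loci with >=1 QTL: 36 (acc 14, H3K27ac 10, meth 28, expr 20)
#>   allelic imbalance: 9 significant SNPs in 4 loci
```

`res$overview` holds the per-locus table (QTL flags per layer,
candidate target genes from expression QTLs, imbalance flag,
chromatin-state group); `res$ai`, `res$qtl`, `res$profiles` and
`res$motif` hold the stage tables.  See the methods vignette
(`vignettes/methods.Rmd`) for the models, parameter defaults and design
decisions.

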