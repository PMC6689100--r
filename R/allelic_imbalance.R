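# Allelic-imbalance analysis.  Heterozygote allele counts are pooled per
# SNP after a genotyping-error ratio filter; a beta-binomial null is
# fitted on background SNPs (outside LD with any sentinel); risk-locus
# SNPs are tested two-sided against that null at FDR < 0.1 with a
# normal-approximation confidence interval on the pooled reference ratio.

#' Pool heterozygote allele counts for one SNP
#'
#' Sums reference and total read counts over heterozygous samples whose
#' per-sample reference ratio lies inside the closed ratio window
#' (genotyping-error guard).  Homozygous samples never contribute.
#'
#' @param counts Data frame \code{snp, sample, ref_count, alt_count,
#'   genotype}.
#' @param snp SNP id.
#' @param ratio_window Closed interval of admissible per-sample reference
#'   ratios (default \code{c(0.1, 0.9)}).
#' @return Named vector \code{c(ref, total)}.
#' @export
pool_het_counts <- function(counts, snp, ratio_window = c(0.1, 0.9)) {
  d <- counts[counts$snp == snp & counts$genotype == 1L, , drop = FALSE]
  if (nrow(d) == 0) return(c(ref = 0, total = 0))
  tot <- d$ref_count + d$alt_count
  keep <- tot > 0
  ratio <- ifelse(keep, d$ref_count / tot, NA)
  keep <- keep & ratio >= ratio_window[1] & ratio <= ratio_window[2]
  c(ref = sum(d$ref_count[keep]), total = sum(tot[keep]))
}

#' Select SNPs testable for allelic imbalance
#'
#' Keeps SNPs flagged as LD proxies inside accessibility peaks with at
#' least \code{min_het} heterozygous samples and at least
#' \code{min_reads} pooled reads after the ratio filter.
#'
#' @param counts Allele-count data frame.
#' @param annotations SNP annotation data frame (\code{snp, in_peak,
#'   ld_proxy, background}).
#' @param min_het Minimum heterozygous samples (default 3).
#' @param min_reads Minimum pooled reads (default 10).
#' @param ratio_window Passed to \code{\link{pool_het_counts}}.
#' @return Character vector of testable SNP ids.
#' @export
select_test_snps <- function(counts, annotations, min_het = 3,
                             min_reads = 10, ratio_window = c(0.1, 0.9)) {
  cand <- annotations$snp[annotations$ld_proxy & annotations$in_peak]
  het_tab <- table(counts$snp[counts$genotype == 1L])
  keep <- character(0)
  for (s in cand) {
    nh <- if (s %in% names(het_tab)) het_tab[[s]] else 0L
    if (nh < min_het) next
    pooled <- pool_het_counts(counts, s, ratio_window)
    if (pooled["total"] >= min_reads) keep <- c(keep, s)
  }
  keep
}

#' Fit the beta-binomial null on background SNPs
#'
#' Pools each background SNP's heterozygote counts (same ratio filter),
#' removes SNPs inside exclusion regions (e.g. HLA-like loci), and fits
#' the beta-binomial by maximum likelihood.
#'
#' @param counts Allele-count data frame.
#' @param annotations SNP annotation data frame with \code{background}
#'   flag and \code{pos}.
#' @param exclusion_regions Optional data frame (\code{start}, \code{end})
#'   of regions whose SNPs are excluded from fitting.
#' @param ratio_window Passed to \code{\link{pool_het_counts}}.
#' @param min_reads Background SNPs need at least this many pooled reads
#'   (default 10).
#' @return A \code{"betabinom_null"} object.
#' @export
build_null <- function(counts, annotations, exclusion_regions = NULL,
                       ratio_window = c(0.1, 0.9), min_reads = 10) {
  bg <- annotations[annotations$background, , drop = FALSE]
  if (!is.null(exclusion_regions) && nrow(exclusion_regions) > 0) {
    excl <- rep(FALSE, nrow(bg))
    for (i in seq_len(nrow(exclusion_regions)))
      excl <- excl | (bg$pos >= exclusion_regions$start[i] &
                        bg$pos < exclusion_regions$end[i])
    bg <- bg[!excl, , drop = FALSE]
  }
  if (nrow(bg) < 10) stop("too few background SNPs after filters")
  cnt <- counts[counts$snp %in% bg$snp & counts$genotype == 1L, ,
                drop = FALSE]
  tot <- cnt$ref_count + cnt$alt_count
  ratio <- ifelse(tot > 0, cnt$ref_count / tot, NA)
  keep <- tot > 0 & ratio >= ratio_window[1] & ratio <= ratio_window[2]
  cnt <- cnt[keep, , drop = FALSE]
  pooled_ref <- tapply(cnt$ref_count, cnt$snp, sum)
  pooled_tot <- tapply(cnt$ref_count + cnt$alt_count, cnt$snp, sum)
  use <- pooled_tot >= min_reads
  if (sum(use) < 10) stop("too few background SNPs after filters")
  fit_betabinom(as.numeric(pooled_ref[use]), as.numeric(pooled_tot[use]))
}

#' Test selected SNPs for allelic imbalance
#'
#' Per-SNP two-sided beta-binomial test on pooled heterozygote counts,
#' Benjamini-Hochberg adjusted, with the pooled reference ratio and its
#' 95 percent normal-approximation confidence interval (computed on the
#' pooled read total and clipped to \[0, 1\]).
#'
#' @param counts Allele-count data frame.
#' @param snps SNP ids from \code{\link{select_test_snps}}.
#' @param null A \code{"betabinom_null"}.
#' @param fdr_q Significance threshold (default 0.1).
#' @param ratio_window Passed to \code{\link{pool_het_counts}}.
#' @return Data frame: snp, pooled_ref, pooled_total, ratio, ci_low,
#'   ci_high, p_value, fdr, significant.
#' @export
test_imbalance <- function(counts, snps, null, fdr_q = 0.1,
                           ratio_window = c(0.1, 0.9)) {
  rows <- lapply(snps, function(s) {
    pooled <- pool_het_counts(counts, s, ratio_window)
    k <- pooled[["ref"]]; n <- pooled[["total"]]
    tr <- betabinom_test(k, n, null)
    ratio <- k / n
    half <- 1.96 * sqrt(ratio * (1 - ratio) / n)
    data.frame(snp = s, pooled_ref = k, pooled_total = n, ratio = ratio,
               ci_low = max(0, ratio - half), ci_high = min(1, ratio + half),
               p_value = tr$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- adjust_pvalues(out$p_value, "bh")
  out$significant <- out$fdr < fdr_q
  rownames(out) <- NULL
  out
}

#' Enrichment of allelic imbalance among QTL SNPs
#'
#' Cross-tabulates imbalance significance against accessibility-QTL
#' overlap and applies the two-sided Fisher exact test.
#'
#' @param ai Result data frame from \code{\link{test_imbalance}}.
#' @param qtl_snps Character vector of SNPs overlapping accessibility
#'   QTLs (same universe as \code{ai$snp}).
#' @return A \code{\link{test_result}} with the 2x2 table attached as
#'   attribute \code{"table"}.
#' @export
qtl_overlap_enrichment <- function(ai, qtl_snps) {
  if (nrow(ai) == 0) stop("empty SNP universe")
  in_qtl <- ai$snp %in% qtl_snps
  a <- sum(ai$significant & in_qtl)
  b <- sum(ai$significant & !in_qtl)
  c <- sum(!ai$significant & in_qtl)
  d <- sum(!ai$significant & !in_qtl)
  res <- fisher_exact_2x2(a, b, c, d)
  attr(res, "table") <- matrix(c(a, b, c, d), 2, byrow = TRUE,
                               dimnames = list(c("imbalanced", "balanced"),
                                               c("qtl", "no_qtl")))
  res
}
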