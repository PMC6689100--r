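# End-to-end orchestration: simulate a fixture bundle (or accept one),
# define LD regions, score chromatin-state enrichment, reconcile
# genotypes, scan the four molecular layers for QTLs, test allelic
# imbalance, score motif disruptions, and assemble the per-locus
# overview.  Identical configuration and seed give identical outputs.

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on a simulated fixture bundle:
#' LD-region definition, background construction, chromatin-state
#' enrichment and locus grouping, genotype reconciliation and QC, the
#' four-layer QTL scan, allelic-imbalance testing with QTL-overlap
#' enrichment, motif-disruption scoring, and the per-locus overview.
#'
#' @param config A \code{\link{sim_config}}; its seed drives every stage.
#' @param bundle Optional pre-built \code{"fixture_bundle"} (skips the
#'   simulate stage; must match \code{config}).
#' @param outdir Optional directory; when given, stage tables are written
#'   as TSV and a JSON run manifest records every threshold.
#' @param fdr_qtl,fdr_ai QTL and allelic-imbalance significance
#'   thresholds (defaults 0.05 and 0.1).
#' @return A list of class \code{"pipeline_result"}: loci, background,
#'   enrichment profiles and groups, SNP-state annotation, per-sample
#'   active fractions, genotype reconciliation, per-layer QTL results,
#'   concordance table, allelic-imbalance summary and overlap test, motif
#'   calls, and the \code{overview} table.
#' @export
run_pipeline <- function(config = sim_config(), bundle = NULL,
                         outdir = NULL, fdr_qtl = 0.05, fdr_ai = 0.1) {
  if (is.null(bundle)) bundle <- simulate_bundle(config)
  panel <- bundle$panel
  regions <- bundle$truth$locus_regions

  # --- LD stage -----------------------------------------------------------
  loci <- lapply(regions$sentinel, function(s) {
    blk <- panel$snps$block[match(s, panel$snps$snp)]
    cand <- panel$snps[panel$snps$block == blk, c("snp", "pos")]
    define_ld_region(s, cand, panel$haplotypes)
  })
  names(loci) <- regions$sentinel
  ltab <- loci_table(loci)
  all_regions <- snp_ld_regions(panel)
  background <- build_background_regions(all_regions, ltab)

  # --- enrichment stage ---------------------------------------------------
  backgrounds <- stats::setNames(
    lapply(bundle$tracks,
           function(tr) state_coverage_regions(background$intervals, tr)),
    vapply(bundle$tracks, `[[`, "", "sample"))
  profiles <- enrichment_profiles(loci, bundle$tracks, backgrounds)
  groups <- classify_locus_groups(profiles)
  annotation <- snp_state_annotation(loci, bundle$tracks)
  active_fractions <- vapply(bundle$tracks, function(tr) {
    fraction_active_per_sample(loci, tr, backgrounds[[tr$sample]])
  }, numeric(1))
  names(active_fractions) <- names(backgrounds)

  # --- genotype reconciliation -------------------------------------------
  snp_pos <- stats::setNames(panel$snps$pos, panel$snps$snp)
  rec <- reconcile(bundle$genotype_sources$imputed,
                   bundle$genotype_sources$wgs, snp_pos,
                   bundle$genotype_sources$cna_mask,
                   sentinel_snps = panel$sentinels)
  G <- rec$genotypes
  sq <- snp_qc(G)
  G <- G[, sq$snp[sq$pass], drop = FALSE]
  samp_excl <- sample_qc(G)
  G <- G[setdiff(rownames(G), samp_excl$sample), , drop = FALSE]

  # --- QTL stage ----------------------------------------------------------
  # On simulated cohorts the confounder count is known from the config;
  # remove exactly that many components, capped by the per-layer default
  # that applies to reference-scale matrices.
  set.seed(stage_seed(config$seed, "qtl_scan"))
  qtl <- lapply(bundle$layers, function(fm) {
    k <- min(default_k_factors[[fm$layer]], config$n_latent_factors)
    run_layer_scan(fm, loci, G, bundle$tads, fdr_q = fdr_qtl,
                   k_factors = k)
  })
  concordance <- direction_concordance(
    qtl, lapply(bundle$layers, `[[`, "features"))

  # --- allelic imbalance ---------------------------------------------------
  counts <- bundle$allele_counts
  ann <- bundle$snp_annotations
  testable <- select_test_snps(counts, ann)
  null <- build_null(counts, ann)
  ai <- test_imbalance(counts, testable, null, fdr_q = fdr_ai)
  acc_sig_loci <- which(
    regions$sentinel %in% qtl$accessibility$sentinel[
      qtl$accessibility$significant])
  qtl_snps <- ann$snp[!is.na(ann$locus) & ann$locus %in% acc_sig_loci]
  ai_overlap <- if (nrow(ai) > 0)
    qtl_overlap_enrichment(ai, qtl_snps) else NULL

  # --- motif stage ---------------------------------------------------------
  motif <- scan_disruptions(bundle$motif$snps, bundle$motif$pwms)

  overview <- summarize_layers(qtl, ai, annotation, groups, regions, ann)

  thresholds <- list(fdr_qtl = fdr_qtl, fdr_ai = fdr_ai,
                     r2_threshold = 0.2, min_het = 3, min_reads = 10,
                     ratio_window = c(0.1, 0.9), info_min = 0.85,
                     uncertainty_threshold = 0.1, concordance_min = 0.9,
                     seed = config$seed)

  result <- structure(
    list(config = config, loci = loci, loci_table = ltab,
         background = background, profiles = profiles, groups = groups,
         annotation = annotation, active_fractions = active_fractions,
         reconciliation = rec, snp_qc = sq, sample_exclusions = samp_excl,
         genotypes = G, qtl = qtl, concordance = concordance,
         ai_null = null, ai = ai, ai_overlap = ai_overlap,
         motif = motif, overview = overview, thresholds = thresholds),
    class = "pipeline_result")

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_df_tsv(ltab, file.path(outdir, "loci.tsv"))
    write_bed(background$intervals, file.path(outdir, "background.bed"))
    write_df_tsv(profiles, file.path(outdir, "enrichment.tsv"))
    write_df_tsv(groups, file.path(outdir, "locus_groups.tsv"))
    write_df_tsv(do.call(rbind, qtl), file.path(outdir, "qtl.tsv"))
    write_df_tsv(ai, file.path(outdir, "allelic_imbalance.tsv"))
    write_df_tsv(motif, file.path(outdir, "motif_disruption.tsv"))
    write_df_tsv(overview, file.path(outdir, "overview.tsv"))
    jsonlite::write_json(
      list(thresholds = thresholds,
           null = list(alpha = null$alpha, beta = null$beta)),
      file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  result
}

#' Per-locus overview of all analysis layers
#'
#' One row per risk locus: per-layer QTL flags, candidate target genes
#' (significant expression QTLs), allelic-imbalance flag, chromatin-state
#' group and active-element flag.
#'
#' @param qtl Named list of per-layer QTL result data frames.
#' @param ai Allelic-imbalance summary data frame.
#' @param annotation Output of \code{\link{snp_state_annotation}}.
#' @param groups Output of \code{\link{classify_locus_groups}}.
#' @param regions Locus-region data frame (\code{sentinel}, \code{block},
#'   \code{start}, \code{end}).
#' @param snp_ann SNP annotation data frame mapping allele-count SNPs to
#'   loci.
#' @return Data frame with one row per locus.
#' @export
summarize_layers <- function(qtl, ai, annotation, groups, regions,
                             snp_ann) {
  sig_by_layer <- lapply(qtl, function(d)
    unique(d$sentinel[d$significant]))
  expr_sig <- qtl$expression[qtl$expression$significant, , drop = FALSE]
  ai_sig_loci <- if (nrow(ai) > 0) {
    loc <- snp_ann$locus[match(ai$snp[ai$significant], snp_ann$snp)]
    unique(loc[!is.na(loc)])
  } else integer(0)

  rows <- lapply(seq_len(nrow(regions)), function(i) {
    s <- regions$sentinel[i]
    genes <- expr_sig$feature[expr_sig$sentinel == s]
    data.frame(
      sentinel = s, start = regions$start[i], end = regions$end[i],
      qtl_accessibility = s %in% sig_by_layer$accessibility,
      qtl_h3k27ac = s %in% sig_by_layer$h3k27ac,
      qtl_methylation = s %in% sig_by_layer$methylation,
      qtl_expression = s %in% sig_by_layer$expression,
      any_qtl = s %in% unlist(sig_by_layer),
      candidate_genes = paste(genes, collapse = ";"),
      allelic_imbalance = i %in% ai_sig_loci,
      group = groups$group[match(s, groups$sentinel)],
      active = annotation$locus_summary$active[
        match(s, annotation$locus_summary$sentinel)],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  ov <- x$overview
  cat("Pipeline result\n")
  cat(sprintf("  %d risk loci; %d active (>=1 proxy SNP in an active state)\n",
              nrow(ov), sum(ov$active)))
  cat(sprintf("  mean per-sample active fraction: %.2f\n",
              mean(x$active_fractions)))
  cat(sprintf("  loci with >=1 QTL: %d (acc %d, H3K27ac %d, meth %d, expr %d)\n",
              sum(ov$any_qtl), sum(ov$qtl_accessibility),
              sum(ov$qtl_h3k27ac), sum(ov$qtl_methylation),
              sum(ov$qtl_expression)))
  cat(sprintf("  allelic imbalance: %d significant SNPs in %d loci\n",
              sum(x$ai$significant), sum(ov$allelic_imbalance)))
  invisible(x)
}
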