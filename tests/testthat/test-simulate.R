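# Synthetic-data generator: LD structure of the haplotype panel, planted
# QTL effects, overdispersed allele counts, segmentation structure, seed
# determinism and truth-table soundness.

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(haplotypes_per_block = 2), "haplotypes_per_block")
  expect_error(sim_config(block_r2_decay = 1.5), "block_r2_decay")
  expect_error(sim_config(genome_length = 1001, bin_width = 200),
               "genome_length")
  expect_error(sim_config(overdispersion_alpha = -1), "overdispersion_alpha")
  expect_error(sim_config(qtl_effect_size = Inf), "qtl_effect_size")
  expect_error(sim_config(fraction_imbalanced_snps = 1.2),
               "fraction_imbalanced_snps")
  expect_error(sim_config(n_enriched_loci = 40, n_active_snp_loci = 39),
               "n_enriched_loci")
})

test_that("haplotype panel LD structure follows the configured decay", {
  # no decay: all within-block pairs in perfect LD
  cfg <- small_config(block_r2_decay = 1)
  p <- make_haplotype_panel(cfg)
  blk <- p$snps[p$snps$block == "blk01", ]
  for (i in 2:nrow(blk))
    expect_equal(compute_r2(p$haplotypes, blk$snp[1], blk$snp[i]), 1.0)

  # independent blocks: cross-block r2 near zero
  b1 <- p$snps$snp[p$snps$block == "blk01"][1]
  b2 <- p$snps$snp[p$snps$block == "blk02"][1]
  expect_lt(compute_r2(p$haplotypes, b1, b2), 0.05)

  # 1000 haplotypes, decay 0.8: mean lag-1 r2 within 0.1 of 0.8
  cfg <- small_config(block_r2_decay = 0.8, haplotypes_per_block = 1000)
  p <- make_haplotype_panel(cfg)
  lag1 <- unlist(lapply(sprintf("blk%02d", 1:8), function(bl) {
    ids <- p$snps$snp[p$snps$block == bl]
    vapply(seq_len(length(ids) - 1), function(i) {
      compute_r2(p$haplotypes, ids[i], ids[i + 1])
    }, numeric(1))
  }))
  expect_lt(abs(mean(lag1) - 0.8), 0.1)
})

test_that("sentinels have proxies above and non-proxies below the threshold", {
  p <- make_haplotype_panel(small_config())
  for (s in p$sentinels[1:4]) {
    blk <- p$snps$block[match(s, p$snps$snp)]
    neighbors <- setdiff(p$snps$snp[p$snps$block == blk], s)
    r2n <- vapply(neighbors, function(x) compute_r2(p$haplotypes, s, x),
                  numeric(1))
    expect_true(any(r2n >= 0.2))
    other <- p$snps$snp[p$snps$block != blk][1]
    expect_lt(compute_r2(p$haplotypes, s, other), 0.2)
  }
})

test_that("genotype allele frequencies match panel frequencies", {
  cfg <- small_config(n_samples = 200)
  p <- make_haplotype_panel(cfg)
  G <- make_genotypes(p, cfg)
  panel_af <- colMeans(p$haplotypes)
  sample_af <- colMeans(G) / 2
  # binomial sampling error at n = 400 chromosomes
  se <- sqrt(panel_af * (1 - panel_af) / (2 * 200))
  expect_gt(mean(abs(sample_af - panel_af) <= 4 * se + 1e-9), 0.95)
})

test_that("identical configurations give byte-identical bundles", {
  cfg <- small_config(seed = 77)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1, b2)
  b3 <- simulate_bundle(small_config(seed = 78))
  expect_false(identical(b1$genotypes, b3$genotypes))
})

test_that("feature layers plant the configured QTL structure", {
  # zero effect size: empty truth table
  cfg0 <- small_config(qtl_effect_size = 0)
  p <- make_haplotype_panel(cfg0)
  G <- make_genotypes(p, cfg0)
  fl <- make_feature_layers(p, G, cfg0)
  expect_equal(nrow(fl$truth), 0)

  # noiseless limit with no confounders: regression recovers the slope
  cfg1 <- small_config(noise_sd = 0, n_latent_factors = 0,
                       qtl_effect_size = 1)
  p <- make_haplotype_panel(cfg1)
  G <- make_genotypes(p, cfg1)
  fl <- make_feature_layers(p, G, cfg1)
  tq <- fl$truth[fl$truth$layer == "accessibility", ][1, ]
  fit <- lm(fl$layers$accessibility$values[, tq$feature] ~ G[, tq$sentinel])
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-9)

  # signs: accessibility and H3K27ac share sign, methylation is opposite
  cfg <- small_config()
  b <- cached_small_bundle()
  expect_true(all(b$truth$qtl$beta[b$truth$qtl$layer %in%
                                     c("accessibility", "h3k27ac")] > 0))
  expect_true(all(b$truth$qtl$beta[b$truth$qtl$layer == "methylation"] < 0))
})

test_that("planted slopes are recoverable within sampling error over seeds", {
  hits <- vapply(1:20, function(s) {
    cfg <- small_config(seed = 100 + s, n_samples = 200,
                        qtl_effect_size = 0.8, n_latent_factors = 0)
    p <- make_haplotype_panel(cfg)
    G <- make_genotypes(p, cfg)
    fl <- make_feature_layers(p, G, cfg)
    tq <- fl$truth[fl$truth$layer == "accessibility", ][1, ]
    bhat <- unname(coef(lm(fl$layers$accessibility$values[, tq$feature] ~
                             G[, tq$sentinel]))[2])
    abs(bhat - 0.8) <= 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("allele counts are null-symmetric and carry the planted shift", {
  # symmetric null, no planted imbalance: pooled ratio near 0.5
  cfg <- small_config(overdispersion_alpha = 20, overdispersion_beta = 20,
                      fraction_imbalanced_snps = 0)
  p <- make_haplotype_panel(cfg)
  G <- make_genotypes(p, cfg)
  ac <- make_allele_counts(G, p, cfg)
  het <- ac$counts[ac$counts$genotype == 1, ]
  expect_lt(abs(sum(het$ref_count) /
                  sum(het$ref_count + het$alt_count) - 0.5), 0.02)
  expect_equal(nrow(ac$truth), 0)

  # planted ratio 0.8: pooled ratio of imbalanced SNPs in [0.7, 0.9]
  ok <- vapply(1:20, function(s) {
    cfg <- small_config(seed = 200 + s)
    p <- make_haplotype_panel(cfg)
    G <- make_genotypes(p, cfg)
    ac <- make_allele_counts(G, p, cfg)
    d <- ac$counts[ac$counts$snp %in% ac$truth$snp &
                     ac$counts$genotype == 1, ]
    r <- sum(d$ref_count) / sum(d$ref_count + d$alt_count)
    r >= 0.7 && r <= 0.9
  }, logical(1))
  expect_gte(mean(ok), 0.95)

  # homozygous samples are near-monoallelic
  b <- cached_small_bundle()
  hom <- b$allele_counts[b$allele_counts$genotype == 0, ]
  expect_gt(sum(hom$ref_count) / sum(hom$ref_count + hom$alt_count), 0.98)
})

test_that("background null counts refit to the generating shapes", {
  cfg <- small_config(n_background_snps = 3000)
  p <- make_haplotype_panel(cfg)
  G <- make_genotypes(p, cfg)
  ac <- make_allele_counts(G, p, cfg)
  null <- build_null(ac$counts, ac$annotations)
  expect_lt(abs(null$alpha - 20.5) / 20.5, 0.15)
  expect_lt(abs(null$beta - 20.3) / 20.3, 0.15)
})

test_that("segmentations tile the genome and match configured frequencies", {
  b <- cached_small_bundle()
  cfg <- b$config
  for (tr in b$tracks) {
    expect_equal(length(tr$states),
                 cfg$genome_length %/% cfg$bin_width)
    expect_false(anyNA(tr$states))
  }

  # background-only genome: per-state fractions within 2 points
  cfg0 <- small_config(n_active_snp_loci = 0, n_enriched_loci = 0)
  p <- make_haplotype_panel(cfg0)
  tracks <- make_segmentations(p, cfg0)
  # only the small planted-locus regions deviate; measure genome-wide
  frac <- table(tracks[[1]]$states) / length(tracks[[1]]$states)
  expect_true(all(abs(frac - cfg0$state_background_freq[names(frac)]) <
                    0.02))

  # same seed, two samples generated in one call are reproducible
  t2 <- make_segmentations(p, cfg0)
  expect_identical(lapply(tracks, `[[`, "states"),
                   lapply(t2, `[[`, "states"))

  expect_error(
    make_segmentations(p, small_config(genome_length = 1999900L)),
    "multiple")
})

test_that("planted fully-active loci reach coverage 1 over active states", {
  f <- rep(0, 12); names(f) <- chromatin_states()
  f[active_states()] <- c(0.5, 0.3, 0.2)
  cfg <- small_config(state_active_freq = f)
  p <- make_haplotype_panel(cfg)
  tracks <- make_segmentations(p, cfg)
  b <- cached_small_bundle()
  reg <- planted_region <- b$truth$locus_regions[1, ]
  cov <- state_coverage(reg$start, reg$end, tracks[[1]])
  expect_equal(sum(cov[active_states()]), 1, tolerance = 1e-12)
})

test_that("truth tables reference only entities present in the bundle", {
  b <- cached_small_bundle()
  all_feats <- unlist(lapply(b$layers, function(l) l$features$feature_id))
  expect_true(all(b$truth$qtl$feature %in% all_feats))
  expect_true(all(b$truth$qtl$sentinel %in% b$panel$sentinels))
  expect_true(all(b$truth$imbalanced_snps$snp %in%
                    b$snp_annotations$snp))
  expect_true(all(b$truth$testable_snps %in% b$snp_annotations$snp))
  expect_true(all(b$truth$imbalanced_snps$snp %in% b$truth$testable_snps))
  expect_equal(length(b$truth$testable_snps), b$config$n_ai_testable)
})
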