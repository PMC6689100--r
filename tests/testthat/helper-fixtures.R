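# Shared fixtures: a reduced simulation configuration that keeps the
# planted structure of the default cohort but runs in seconds, and a
# session-level cache so expensive bundles are built once per test run.

small_config <- function(seed = 42, ...) {
  args <- list(
    seed = seed, n_samples = 60, n_chromatin_samples = 3, n_loci = 8,
    snps_per_block = 8, haplotypes_per_block = 300,
    genome_length = 2000000L,
    n_background_snps = 150, n_background_blocks = 12,
    n_ai_snps = 30, n_ai_testable = 24, fraction_imbalanced_snps = 3 / 24,
    n_active_snp_loci = 7, n_enriched_loci = 6,
    qtl_loci = list(accessibility = 5:8, h3k27ac = 6:7,
                    methylation = 1:4, expression = 1:3))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

.fixture_cache <- new.env(parent = emptyenv())

cached_small_bundle <- function() {
  if (is.null(.fixture_cache$bundle))
    .fixture_cache$bundle <- simulate_bundle(small_config())
  .fixture_cache$bundle
}

cached_small_loci <- function() {
  if (is.null(.fixture_cache$loci)) {
    b <- cached_small_bundle()
    regions <- b$truth$locus_regions
    .fixture_cache$loci <- lapply(regions$sentinel, function(s) {
      blk <- b$panel$snps$block[match(s, b$panel$snps$snp)]
      cand <- b$panel$snps[b$panel$snps$block == blk, c("snp", "pos")]
      define_ld_region(s, cand, b$panel$haplotypes)
    })
  }
  .fixture_cache$loci
}

# a segmentation track built directly from a state-per-bin vector
manual_track <- function(states, bin_width = 200L, sample = "T1") {
  structure(list(sample = sample, bin_width = bin_width,
                 genome_length = bin_width * length(states),
                 states = factor(states, levels = chromatin_states())),
            class = "segmentation_track")
}

# beta-binomial sampler used to build parameter-recovery fixtures
rbetabinom_oracle <- function(m, n, alpha, beta) {
  stats::rbinom(m, n, stats::rbeta(m, alpha, beta))
}

# independent beta-binomial pmf via numeric integration of the
# binomial-beta mixture (oracle for betabinom_test / betabinom_loglik)
bb_pmf_integrate <- function(k, n, alpha, beta) {
  vapply(k, function(kk) {
    stats::integrate(function(p) {
      stats::dbinom(kk, n, p) * stats::dbeta(p, alpha, beta)
    }, 0, 1, rel.tol = 1e-12, abs.tol = 1e-14)$value
  }, numeric(1))
}

# --- hand-enumerated reconciliation toy ------------------------------------
# 10 samples (S01..S10) x 10 SNPs (s01..s10), true genotype 1 everywhere.
# Per-sample concordance is checked on the fidelity (sentinel) subset
# {s03, s04, s05, s06, s08, s09, s10}.
#  - s01: information measure 0.80 -> imputed dropped, WGS fills (9 cells)
#  - s02: WGS = 2 for S01, S02 -> SNP concordance 8/10 < 0.9 -> WGS-only
#    (not in the fidelity subset, so S01/S02 stay)
#  - s03: S01 has uncertain triple -> imputed missing, WGS fills (1 cell)
#  - s04: CNA mask covers S03 at this SNP -> masked (1 cell)
#  - s05: WGS normal != tumor for S04 -> WGS invalid, imputed kept
#  - s06: WGS depth 5 for S05 -> WGS invalid, imputed kept
#  - s07: WGS = 0 for S06 -> single conflict, WGS wins (1 cell)
#  - S10: WGS = 2 at s08, s09, s10 -> fidelity concordance 4/7 < 0.9 ->
#    sample excluded
# Retained matrix: 9 x 10 = 90 cells; provenance partition:
#   masked 1, wgs 9, filled 10, conflict_resolved 1, imputed 69, missing 0.
make_reconcile_toy <- function() {
  samples <- sprintf("S%02d", 1:10)
  snps <- sprintf("s%02d", 1:10)
  probs <- array(0, dim = c(10, 10, 3), dimnames = list(samples, snps, NULL))
  probs[, , 2] <- 1   # certain heterozygote everywhere
  probs["S01", "s03", ] <- c(0.6, 0.3, 0.1)
  info <- stats::setNames(rep(0.99, 10), snps)
  info["s01"] <- 0.80

  normal <- matrix(1L, 10, 10, dimnames = list(samples, snps))
  tumor <- normal
  depth <- matrix(30L, 10, 10, dimnames = list(samples, snps))
  qual_ok <- matrix(TRUE, 10, 10, dimnames = list(samples, snps))
  normal[c("S01", "S02"), "s02"] <- 2L; tumor[c("S01", "S02"), "s02"] <- 2L
  tumor["S04", "s05"] <- 2L                      # normal/tumor discordant
  depth["S05", "s06"] <- 5L                      # below depth threshold
  normal["S06", "s07"] <- 0L; tumor["S06", "s07"] <- 0L   # conflict
  normal["S10", c("s08", "s09", "s10")] <- 2L
  tumor["S10", c("s08", "s09", "s10")] <- 2L

  snp_pos <- stats::setNames(seq(100L, 1000L, by = 100L), snps)
  cna <- list(S03 = data.frame(start = 350L, end = 450L))  # covers s04 only
  list(imputed = list(info = info, probs = probs),
       wgs = list(normal = normal, tumor = tumor, depth = depth,
                  qual_ok = qual_ok),
       snp_pos = snp_pos, cna = cna,
       sentinels = c("s03", "s04", "s05", "s06", "s08", "s09", "s10"))
}

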