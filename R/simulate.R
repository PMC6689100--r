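# Synthetic-data generator.  Produces seeded fixtures carrying the
# statistical structure that every downstream stage assumes: an LD-blocked
# haplotype panel with sentinel SNPs and proxies, per-sample chromatin-state
# segmentations in 200-bp bins, genotype-dependent molecular feature layers
# with planted QTL effects and latent confounders, beta-binomially
# overdispersed allele-specific read counts with planted imbalance, and
# imputation/WGS genotype sources with planted conflicts.
#
# All randomness flows from one root seed through named substreams, so each
# generator is reproducible on its own and the whole bundle is byte-stable.

#' Derive a named substream seed from a root seed
#'
#' @param seed Root integer seed.
#' @param stream Stream name.
#' @return A deterministic integer seed below 2^31.
#' @keywords internal
stage_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' The 12-state chromatin alphabet
#'
#' Active promoters/enhancers first, then weak, transcribed, and
#' poised/repressed states.
#' @return Character vector of the 12 state labels.
#' @export
chromatin_states <- function() {
  c("ActProm", "WkProm", "PoisProm", "StrEnh1", "StrEnh2", "WkEnh",
    "Txn_Trans", "Txn_Elong", "Wk_Txn", "H3K9me3_Repr", "H3K27me3_Repr",
    "Het;LowSign")
}

#' States counted as active regulatory elements
#' @return Character vector (active promoter and strong enhancers).
#' @export
active_states <- function() c("ActProm", "StrEnh1", "StrEnh2")

default_background_freq <- function() {
  f <- c(ActProm = 0.06, WkProm = 0.05, PoisProm = 0.03, StrEnh1 = 0.03,
         StrEnh2 = 0.02, WkEnh = 0.06, Txn_Trans = 0.03, Txn_Elong = 0.07,
         Wk_Txn = 0.10, H3K9me3_Repr = 0.05, H3K27me3_Repr = 0.08,
         `Het;LowSign` = 0.42)
  f / sum(f)
}

default_active_freq <- function() {
  f <- c(ActProm = 0.28, StrEnh1 = 0.22, StrEnh2 = 0.15, WkProm = 0.06,
         WkEnh = 0.08, PoisProm = 0.02, Txn_Trans = 0.04, Txn_Elong = 0.05,
         Wk_Txn = 0.05, H3K9me3_Repr = 0.01, H3K27me3_Repr = 0.02,
         `Het;LowSign` = 0.02)
  f[chromatin_states()] / sum(f)
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic cohort.  Defaults emulate the
#' study conditions: 42 risk loci profiled in a genotyped cohort of 99
#' samples with 7 chromatin-state reference samples; 39 loci carrying a
#' proxy SNP in an active element of which 34 are enriched for active
#' chromatin; per-layer QTL loci whose union covers 36 loci; 225 LD-proxy
#' SNPs in accessibility peaks of which 189 are testable for allelic
#' imbalance and 9 imbalanced; and a beta-binomial allele-count null with
#' shapes 20.5 and 20.3.
#'
#' @param seed Root seed (integer).
#' @param n_samples Genotyped cohort size.
#' @param n_chromatin_samples Number of per-sample segmentation tracks.
#' @param n_loci Number of sentinel risk loci.
#' @param snps_per_block SNPs per LD block (sentinel at the centre).
#' @param haplotypes_per_block Haplotypes in the panel (>= 4).
#' @param block_r2_decay Per-SNP-step decay factor of within-block
#'   r-squared, in (0, 1].
#' @param genome_length Synthetic contig length (bp); must be a multiple of
#'   \code{bin_width}.
#' @param bin_width Segmentation bin width (bp), default 200.
#' @param qtl_effect_size Planted standardized QTL slope.
#' @param noise_sd Residual noise SD of molecular features.
#' @param n_latent_factors Latent confounders added to every layer.
#' @param overdispersion_alpha,overdispersion_beta Beta-binomial shapes of
#'   the null allele-count model (both > 0).
#' @param fraction_imbalanced_snps Fraction of testable SNPs with planted
#'   allelic imbalance.
#' @param imbalance_ratio Mean reference-allele ratio of imbalanced SNPs.
#' @param depth_mean Mean read depth per heterozygous sample at testable
#'   SNPs.
#' @param n_background_snps Background SNPs used to fit the allele-count
#'   null.
#' @param n_background_blocks,background_block_snps LD blocks outside the
#'   risk loci used to build genome-wide background regions.
#' @param n_active_snp_loci Loci with >= 1 proxy SNP in an active state.
#' @param n_enriched_loci Loci enriched for active chromatin in every
#'   sample (must be <= \code{n_active_snp_loci}).
#' @param n_ai_snps LD-proxy SNPs inside accessibility peaks.
#' @param n_ai_testable Of these, SNPs meeting the testability rules.
#' @param qtl_loci Named list of locus index vectors per layer
#'   (accessibility, h3k27ac, methylation, expression) carrying planted
#'   QTLs.
#' @param state_alphabet Chromatin-state labels (12 states).
#' @param state_background_freq Named background state frequencies.
#' @param state_active_freq Named state frequencies inside enriched loci.
#' @return An object of class \code{"sim_config"} (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 99L,
                       n_chromatin_samples = 7L,
                       n_loci = 42L,
                       snps_per_block = 12L,
                       haplotypes_per_block = 1000L,
                       block_r2_decay = 0.9,
                       genome_length = 10000000L,
                       bin_width = 200L,
                       qtl_effect_size = 1,
                       noise_sd = 1,
                       n_latent_factors = 3L,
                       overdispersion_alpha = 20.5,
                       overdispersion_beta = 20.3,
                       fraction_imbalanced_snps = 9 / 189,
                       imbalance_ratio = 0.8,
                       depth_mean = 40,
                       n_background_snps = 5000L,
                       n_background_blocks = 60L,
                       background_block_snps = 5L,
                       n_active_snp_loci = 39L,
                       n_enriched_loci = 34L,
                       n_ai_snps = 225L,
                       n_ai_testable = 189L,
                       qtl_loci = list(accessibility = 23:36,
                                       h3k27ac = 27:35,
                                       methylation = 1:28,
                                       expression = 1:20),
                       state_alphabet = chromatin_states(),
                       state_background_freq = default_background_freq(),
                       state_active_freq = default_active_freq()) {
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              n_chromatin_samples = as.integer(n_chromatin_samples),
              n_loci = as.integer(n_loci),
              snps_per_block = as.integer(snps_per_block),
              haplotypes_per_block = as.integer(haplotypes_per_block),
              block_r2_decay = block_r2_decay,
              genome_length = as.integer(genome_length),
              bin_width = as.integer(bin_width),
              qtl_effect_size = qtl_effect_size, noise_sd = noise_sd,
              n_latent_factors = as.integer(n_latent_factors),
              overdispersion_alpha = overdispersion_alpha,
              overdispersion_beta = overdispersion_beta,
              fraction_imbalanced_snps = fraction_imbalanced_snps,
              imbalance_ratio = imbalance_ratio, depth_mean = depth_mean,
              n_background_snps = as.integer(n_background_snps),
              n_background_blocks = as.integer(n_background_blocks),
              background_block_snps = as.integer(background_block_snps),
              n_active_snp_loci = as.integer(n_active_snp_loci),
              n_enriched_loci = as.integer(n_enriched_loci),
              n_ai_snps = as.integer(n_ai_snps),
              n_ai_testable = as.integer(n_ai_testable),
              qtl_loci = qtl_loci, state_alphabet = state_alphabet,
              state_background_freq = state_background_freq,
              state_active_freq = state_active_freq)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid config field '", field, "': ", msg, call. = FALSE)
  }
  chk(cfg$haplotypes_per_block >= 4, "haplotypes_per_block", "must be >= 4")
  chk(cfg$block_r2_decay > 0 && cfg$block_r2_decay <= 1, "block_r2_decay",
      "must be in (0, 1]")
  chk(cfg$genome_length %% cfg$bin_width == 0, "genome_length",
      "must be a multiple of bin_width")
  chk(is.finite(cfg$qtl_effect_size), "qtl_effect_size", "must be finite")
  chk(cfg$overdispersion_alpha > 0, "overdispersion_alpha", "must be > 0")
  chk(cfg$overdispersion_beta > 0, "overdispersion_beta", "must be > 0")
  chk(cfg$fraction_imbalanced_snps >= 0 && cfg$fraction_imbalanced_snps <= 1,
      "fraction_imbalanced_snps", "must be in [0, 1]")
  chk(cfg$imbalance_ratio > 0 && cfg$imbalance_ratio < 1, "imbalance_ratio",
      "must be in (0, 1)")
  chk(cfg$n_enriched_loci <= cfg$n_active_snp_loci, "n_enriched_loci",
      "must be <= n_active_snp_loci")
  chk(cfg$n_active_snp_loci <= cfg$n_loci, "n_active_snp_loci",
      "must be <= n_loci")
  chk(cfg$n_ai_testable <= cfg$n_ai_snps, "n_ai_testable",
      "must be <= n_ai_snps")
  chk(length(cfg$state_alphabet) == 12, "state_alphabet",
      "must list 12 states")
  chk(abs(sum(cfg$state_background_freq) - 1) < 1e-6,
      "state_background_freq", "must sum to 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: %d loci, %d samples, %d chromatin tracks, seed %d\n",
    x$n_loci, x$n_samples, x$n_chromatin_samples, x$seed))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Haplotype panel

#' Generate the LD-blocked haplotype panel
#'
#' Risk-locus blocks (one per locus, sentinel SNP in the middle) and
#' smaller background blocks are laid out along a single synthetic contig.
#' Within a block, each SNP copies the previous SNP's haplotype alleles
#' with a per-haplotype switch probability chosen so that r-squared decays
#' by the factor \code{block_r2_decay} per SNP step; blocks are mutually
#' independent.
#'
#' @param config A \code{\link{sim_config}}.
#' @return An object of class \code{"haplotype_panel"}: a list with
#'   \code{haplotypes} (0/1 matrix, haplotypes x SNPs), \code{snps} (data
#'   frame \code{snp, pos, block, is_sentinel, ref, alt}),
#'   \code{sentinels}, \code{genome_length} and \code{contig}.
#' @export
make_haplotype_panel <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "panel"))
  H <- config$haplotypes_per_block
  # switch probability giving r ~= sqrt(decay) per step, i.e. r^2 ~= decay
  mu <- (1 - sqrt(config$block_r2_decay)) / 2
  spacing <- 400L

  blocks <- list()
  n_risk <- config$n_loci
  n_bg <- config$n_background_blocks
  slot <- config$genome_length / n_risk
  for (b in seq_len(n_risk)) {
    centre <- as.integer((b - 0.5) * slot)
    pos <- centre + spacing * (seq_len(config$snps_per_block) -
                                 (config$snps_per_block + 1) / 2)
    blocks[[length(blocks) + 1L]] <- list(
      id = sprintf("blk%02d", b), pos = as.integer(round(pos)),
      sentinel_idx = ceiling(config$snps_per_block / 2), risk = TRUE)
  }
  # background blocks midway between risk blocks, cycling
  for (b in seq_len(n_bg)) {
    at <- ((b - 1) %% n_risk) + 1
    centre <- as.integer(at * slot - slot / 4 -
                           2000 * ((b - 1) %/% n_risk))
    pos <- centre + spacing * (seq_len(config$background_block_snps) - 1)
    blocks[[length(blocks) + 1L]] <- list(
      id = sprintf("bgblk%03d", b), pos = as.integer(round(pos)),
      sentinel_idx = NA_integer_, risk = FALSE)
  }

  cols <- list(); meta <- list()
  for (blk in blocks) {
    m <- length(blk$pos)
    p0 <- stats::runif(1, 0.3, 0.7)
    g <- matrix(0L, nrow = H, ncol = m)
    repeat {
      g[, 1] <- stats::rbinom(H, 1, p0)
      if (stats::var(g[, 1]) > 0) break
    }
    if (m > 1) for (j in 2:m) {
      flip <- stats::rbinom(H, 1, mu) == 1L
      g[, j] <- ifelse(flip, 1L - g[, j - 1], g[, j - 1])
    }
    ids <- sprintf("%s_snp%02d", blk$id, seq_len(m))
    if (!is.na(blk$sentinel_idx))
      ids[blk$sentinel_idx] <- sprintf("rs_%s", blk$id)
    cols[[length(cols) + 1L]] <- g
    meta[[length(meta) + 1L]] <- data.frame(
      snp = ids, pos = blk$pos, block = blk$id,
      is_sentinel = seq_len(m) == ifelse(is.na(blk$sentinel_idx), -1L,
                                         blk$sentinel_idx),
      risk_block = blk$risk, stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, meta)
  rownames(snps) <- NULL
  hap <- do.call(cbind, cols)
  dimnames(hap) <- list(sprintf("H%04d", seq_len(H)), snps$snp)
  bases <- c("A", "C", "G", "T")
  snps$ref <- sample(bases, nrow(snps), replace = TRUE)
  snps$alt <- vapply(snps$ref, function(r) sample(setdiff(bases, r), 1),
                     character(1))
  structure(
    list(haplotypes = hap, snps = snps,
         sentinels = snps$snp[snps$is_sentinel],
         genome_length = config$genome_length, contig = "chrS"),
    class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("Haplotype panel: %d haplotypes x %d SNPs, %d sentinels, %s:%d bp\n",
              nrow(x$haplotypes), ncol(x$haplotypes), length(x$sentinels),
              x$contig, x$genome_length))
  invisible(x)
}

#' Draw sample genotypes from the haplotype panel
#'
#' Each sample is formed from two haplotypes drawn with replacement, so
#' genotype dosages follow Hardy-Weinberg proportions at the panel allele
#' frequencies.
#'
#' @param panel A \code{"haplotype_panel"}.
#' @param config A \code{\link{sim_config}}.
#' @return Integer dosage matrix (samples x SNPs) with sample row names.
#' @export
make_genotypes <- function(panel, config) {
  set.seed(stage_seed(config$seed, "genotypes"))
  H <- nrow(panel$haplotypes)
  i1 <- sample.int(H, config$n_samples, replace = TRUE)
  i2 <- sample.int(H, config$n_samples, replace = TRUE)
  G <- panel$haplotypes[i1, , drop = FALSE] +
    panel$haplotypes[i2, , drop = FALSE]
  rownames(G) <- sprintf("S%03d", seq_len(config$n_samples))
  storage.mode(G) <- "integer"
  G
}

planted_locus_regions <- function(panel) {
  snps <- panel$snps[panel$snps$risk_block, ]
  out <- do.call(rbind, lapply(split(snps, snps$block), function(d) {
    data.frame(block = d$block[1], sentinel = d$snp[d$is_sentinel],
               start = min(d$pos), end = max(d$pos) + 1L,
               stringsAsFactors = FALSE)
  }))
  out[order(out$start), ]
}

# ---------------------------------------------------------------------------
# Segmentations

#' Generate per-sample chromatin-state segmentation tracks
#'
#' Bins tile the genome exactly at \code{bin_width}.  Background bins draw
#' states from the configured background frequencies.  The first
#' \code{n_enriched_loci} risk loci draw their bins from an active-heavy
#' state distribution in every sample; the next
#' \code{n_active_snp_loci - n_enriched_loci} loci are background-like
#' (active states excluded) except for a single proxy-SNP bin set to an
#' active state in the first sample; the remaining loci exclude active
#' states entirely.
#'
#' @param panel A \code{"haplotype_panel"}.
#' @param config A \code{\link{sim_config}}.
#' @return List of \code{"segmentation_track"} objects (one per chromatin
#'   sample), each a list with \code{sample}, \code{bin_width},
#'   \code{genome_length} and \code{states} (factor over the alphabet).
#' @export
make_segmentations <- function(panel, config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "segmentation"))
  nb <- config$genome_length %/% config$bin_width
  alphabet <- config$state_alphabet
  bgf <- config$state_background_freq[alphabet]
  actf <- config$state_active_freq[alphabet]
  act <- active_states()
  inact_f <- bgf; inact_f[act] <- 0; inact_f <- inact_f / sum(inact_f)

  regions <- planted_locus_regions(panel)
  n_enr <- config$n_enriched_loci
  n_act <- config$n_active_snp_loci

  tracks <- vector("list", config$n_chromatin_samples)
  for (s in seq_len(config$n_chromatin_samples)) {
    states <- sample(alphabet, nb, replace = TRUE, prob = bgf)
    for (i in seq_len(nrow(regions))) {
      bins <- (regions$start[i] %/% config$bin_width):
        ((regions$end[i] - 1L) %/% config$bin_width)
      if (i <= n_enr) {
        states[bins + 1L] <- sample(alphabet, length(bins), replace = TRUE,
                                    prob = actf)
      } else {
        states[bins + 1L] <- sample(alphabet, length(bins), replace = TRUE,
                                    prob = inact_f)
        if (i <= n_act && s == 1L) {
          sent_pos <- panel$snps$pos[match(regions$sentinel[i],
                                           panel$snps$snp)]
          states[sent_pos %/% config$bin_width + 1L] <- "ActProm"
        }
      }
    }
    tracks[[s]] <- structure(
      list(sample = sprintf("C%02d", s), bin_width = config$bin_width,
           genome_length = config$genome_length,
           states = factor(states, levels = alphabet)),
      class = "segmentation_track")
  }
  tracks
}

#' @export
print.segmentation_track <- function(x, ...) {
  cat(sprintf("Segmentation track %s: %d bins of %d bp\n",
              x$sample, length(x$states), x$bin_width))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Feature layers

#' Generate molecular feature layers with planted QTL effects
#'
#' Builds one matrix per layer (accessibility, H3K27ac, methylation
#' M-values, expression).  Planted QTL features follow
#' \code{value = intercept + beta * dosage + latent factors + noise}, with
#' accessibility and H3K27ac effects sharing the sign of
#' \code{qtl_effect_size} and methylation effects carrying the opposite
#' sign (higher methylation with lower activity).  Null features have
#' beta = 0.  Each locus carries three peak/probe features per epigenetic
#' layer; expression features are genes laid out inside per-locus TADs.
#'
#' @param panel A \code{"haplotype_panel"}.
#' @param genotypes Dosage matrix from \code{\link{make_genotypes}}.
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{layers} (named list of
#'   \code{"feature_matrix"} objects), \code{tads} (data frame
#'   \code{tad, start, end}), \code{genes} (data frame
#'   \code{gene, start, end, tad}) and \code{truth} (data frame of planted
#'   QTL pairs: layer, sentinel, feature, beta).
#' @export
make_feature_layers <- function(panel, genotypes, config) {
  validate_sim_config(config)
  if (!is.finite(config$qtl_effect_size))
    stop("invalid config field 'qtl_effect_size': must be finite")
  set.seed(stage_seed(config$seed, "features"))
  regions <- planted_locus_regions(panel)
  n_loci <- nrow(regions)
  ns <- nrow(genotypes)
  beta <- config$qtl_effect_size

  # latent confounders shared across layers
  Fmat <- matrix(stats::rnorm(ns * config$n_latent_factors), nrow = ns)

  dosage <- function(sent) genotypes[, sent]

  make_layer <- function(layer, sign, intercept, feat_prefix,
                         planted_loci) {
    feats <- list(); vals <- list(); truth <- list()
    for (i in seq_len(n_loci)) {
      for (k in 1:3) {
        fid <- sprintf("%s_L%02d_%d", feat_prefix, i, k)
        b <- if (k == 1 && i %in% planted_loci && beta != 0) sign * beta else 0
        load <- stats::rnorm(config$n_latent_factors, 0, 0.6)
        v <- intercept + b * dosage(regions$sentinel[i]) +
          as.numeric(Fmat %*% load) +
          stats::rnorm(ns, 0, config$noise_sd)
        w <- (regions$end[i] - regions$start[i])
        feats[[fid]] <- data.frame(
          feature_id = fid,
          start = regions$start[i] + as.integer((k - 1) * w / 3),
          end = regions$start[i] + as.integer(k * w / 3),
          locus = i, stringsAsFactors = FALSE)
        vals[[fid]] <- v
        if (b != 0)
          truth[[fid]] <- data.frame(layer = layer,
                                     sentinel = regions$sentinel[i],
                                     feature = fid, beta = b,
                                     stringsAsFactors = FALSE)
      }
    }
    V <- do.call(cbind, vals)
    rownames(V) <- rownames(genotypes)
    presence <- matrix(stats::runif(length(V)) < 0.95, nrow = nrow(V),
                       dimnames = dimnames(V))
    list(fm = structure(list(layer = layer, values = V,
                             features = do.call(rbind, feats),
                             presence = presence),
                        class = "feature_matrix"),
         truth = if (length(truth)) do.call(rbind, truth) else NULL)
  }

  acc <- make_layer("accessibility", +1, 5, "peak",
                    config$qtl_loci$accessibility)
  hk <- make_layer("h3k27ac", +1, 5, "k27", config$qtl_loci$h3k27ac)
  me <- make_layer("methylation", -1, 0, "cg", config$qtl_loci$methylation)

  # TADs: one per locus, centred on the locus region; genes inside
  tad_w <- 40000L
  tads <- data.frame(
    tad = sprintf("TAD%02d", seq_len(n_loci)),
    start = pmax(0L, as.integer((regions$start + regions$end) / 2) -
                   tad_w %/% 2L),
    end = pmin(config$genome_length,
               as.integer((regions$start + regions$end) / 2) + tad_w %/% 2L),
    stringsAsFactors = FALSE)
  genes <- do.call(rbind, lapply(seq_len(n_loci), function(i) {
    gs <- tads$start[i] + as.integer((0:2) * 12000 + 1000)
    data.frame(gene = sprintf("GENE%02d_%d", i, 1:3),
               start = gs, end = gs + 8000L, tad = tads$tad[i],
               locus = i, stringsAsFactors = FALSE)
  }))

  expr_feats <- list(); expr_vals <- list(); expr_truth <- list()
  for (i in seq_len(n_loci)) {
    for (k in 1:3) {
      g <- genes[genes$locus == i, ][k, ]
      b <- if (k == 1 && i %in% config$qtl_loci$expression && beta != 0)
        beta else 0
      load <- stats::rnorm(config$n_latent_factors, 0, 0.6)
      v <- 6 + b * dosage(regions$sentinel[i]) +
        as.numeric(Fmat %*% load) + stats::rnorm(ns, 0, config$noise_sd)
      expr_feats[[g$gene]] <- data.frame(feature_id = g$gene,
                                         start = g$start, end = g$end,
                                         locus = i, stringsAsFactors = FALSE)
      expr_vals[[g$gene]] <- v
      if (b != 0)
        expr_truth[[g$gene]] <- data.frame(layer = "expression",
                                           sentinel = regions$sentinel[i],
                                           feature = g$gene, beta = b,
                                           stringsAsFactors = FALSE)
    }
  }
  EV <- do.call(cbind, expr_vals)
  rownames(EV) <- rownames(genotypes)
  expr <- structure(
    list(layer = "expression", values = EV,
         features = do.call(rbind, expr_feats),
         presence = EV > 4.5),
    class = "feature_matrix")

  truth <- rbind(acc$truth, hk$truth, me$truth,
                 if (length(expr_truth)) do.call(rbind, expr_truth))
  if (is.null(truth))
    truth <- data.frame(layer = character(), sentinel = character(),
                        feature = character(), beta = numeric())
  rownames(truth) <- NULL
  list(layers = list(accessibility = acc$fm, h3k27ac = hk$fm,
                     methylation = me$fm, expression = expr),
       tads = tads, genes = genes, truth = truth)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix [%s]: %d samples x %d features\n",
              x$layer, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Allele counts

rbetabinom <- function(n_draws, size, alpha, beta) {
  p <- stats::rbeta(n_draws, alpha, beta)
  stats::rbinom(n_draws, size, p)
}

# the latent allele-sampling ratio is a property of the SNP (mapping and
# chromatin context), shared by all heterozygous carriers: pooled counts
# over heterozygotes are then exactly beta-binomial
snp_ref_counts <- function(g, n, alpha, beta, fixed_p = NULL) {
  ref <- integer(length(g))
  het <- g == 1L
  p_snp <- if (is.null(fixed_p)) stats::rbeta(1, alpha, beta) else fixed_p
  ref[het] <- stats::rbinom(sum(het), n[het], p_snp)
  hr <- g == 0L   # dosage counts alternative alleles; 0 = hom reference
  ref[hr] <- n[hr] - stats::rbinom(sum(hr), n[hr], 0.005)
  ha <- g == 2L
  ref[ha] <- stats::rbinom(sum(ha), n[ha], 0.005)
  ref
}

#' Generate allele-specific read counts with planted imbalance
#'
#' Each SNP carries a latent reference-allele sampling ratio shared by all
#' of its heterozygous carriers: null SNPs draw it from the configured
#' beta null (so pooled heterozygote counts are exactly beta-binomial),
#' while planted imbalanced SNPs fix it at \code{imbalance_ratio} (a cis
#' effect of the variant itself).
#' Homozygous pairs are near-monoallelic with a 0.5 percent sequencing
#' error allele.  Testable SNPs (LD proxies inside accessibility peaks)
#' receive full read depth; the remaining proxy-peak SNPs receive near-zero
#' depth so they fail the 10-read rule.  Background SNPs (not in LD with
#' any sentinel) get independent Hardy-Weinberg genotypes and null counts.
#'
#' @param genotypes Dosage matrix (used for the proxy-peak SNPs).
#' @param panel A \code{"haplotype_panel"} (SNP annotation source).
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{counts} (data frame
#'   \code{snp, sample, ref_count, alt_count, genotype}),
#'   \code{annotations} (data frame \code{snp, pos, in_peak, ld_proxy,
#'   background, locus}) and \code{truth} (data frame of planted
#'   imbalanced SNPs with their mean ratios).
#' @export
make_allele_counts <- function(genotypes, panel, config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "allele_counts"))
  a0 <- config$overdispersion_alpha
  b0 <- config$overdispersion_beta
  regions <- planted_locus_regions(panel)

  # candidate proxy SNPs: non-sentinel members of risk blocks
  snps <- panel$snps[panel$snps$risk_block & !panel$snps$is_sentinel, ]
  snps$locus <- match(snps$block, regions$block)
  if (nrow(snps) < config$n_ai_snps)
    stop("panel has too few proxy SNPs for n_ai_snps")
  # spread the AI SNPs across loci in a deterministic round-robin
  ord <- order(ave(seq_len(nrow(snps)), snps$block, FUN = seq_along),
               snps$locus)
  ai <- snps[ord[seq_len(config$n_ai_snps)], ]

  # testable = first n_ai_testable, preferring accessibility-QTL loci so
  # imbalance and accessibility QTLs can co-occur
  acc_loci <- config$qtl_loci$accessibility
  ai <- ai[order(!(ai$locus %in% acc_loci), ai$locus), ]
  testable <- rep(FALSE, nrow(ai)); testable[seq_len(config$n_ai_testable)] <- TRUE

  n_imb <- round(config$fraction_imbalanced_snps * config$n_ai_testable)
  imb <- rep(FALSE, nrow(ai))
  if (n_imb > 0) {
    # planted imbalanced SNPs: most in accessibility-QTL loci (at most 3
    # per locus, so imbalance clusters in a handful of loci), one outside
    in_acc <- which(testable & ai$locus %in% acc_loci)
    out_acc <- which(testable & !(ai$locus %in% acc_loci))
    by_locus <- split(in_acc, ai$locus[in_acc])
    take <- integer(0)
    for (grp in by_locus) {
      need <- (n_imb - 1) - length(take)
      if (need <= 0) break
      take <- c(take, grp[seq_len(min(3, length(grp), need))])
    }
    take <- c(take, out_acc[seq_len(min(1, max(0, n_imb - length(take)),
                                        length(out_acc)))])
    if (length(take) < n_imb)
      take <- c(take, setdiff(which(testable), take)[
        seq_len(n_imb - length(take))])
    imb[take[seq_len(n_imb)]] <- TRUE
  }

  samples <- rownames(genotypes)
  count_rows <- vector("list", nrow(ai))
  for (i in seq_len(nrow(ai))) {
    g <- genotypes[, ai$snp[i]]
    depth_mean <- if (testable[i]) config$depth_mean else 0.05
    n <- stats::rpois(length(g), depth_mean)
    # planted SNPs carry a fixed latent allele ratio (a cis effect of the
    # variant itself); null SNPs draw theirs from the technical null
    ref <- snp_ref_counts(g, n, a0, b0,
                          fixed_p = if (imb[i]) config$imbalance_ratio)
    keep <- n > 0
    count_rows[[i]] <- data.frame(
      snp = rep(ai$snp[i], sum(keep)), sample = samples[keep],
      ref_count = ref[keep], alt_count = n[keep] - ref[keep],
      genotype = g[keep], stringsAsFactors = FALSE)
  }

  # background SNPs: independent HWE genotypes, null counts
  nbg <- config$n_background_snps
  bg_ids <- sprintf("bg_%05d", seq_len(nbg))
  gap <- config$genome_length / (nbg + 1)
  bg_pos <- as.integer(seq_len(nbg) * gap)
  bg_rows <- vector("list", nbg)
  for (i in seq_len(nbg)) {
    p <- stats::runif(1, 0.2, 0.8)
    g <- stats::rbinom(length(samples), 2, p)
    n <- stats::rpois(length(g), config$depth_mean)
    ref <- snp_ref_counts(g, n, a0, b0)
    keep <- n > 0 & g == 1L    # only heterozygote counts are ever used
    bg_rows[[i]] <- data.frame(
      snp = rep(bg_ids[i], sum(keep)), sample = samples[keep],
      ref_count = ref[keep], alt_count = n[keep] - ref[keep],
      genotype = g[keep], stringsAsFactors = FALSE)
  }

  ann <- rbind(
    data.frame(snp = ai$snp, pos = ai$pos, in_peak = TRUE, ld_proxy = TRUE,
               background = FALSE, locus = ai$locus,
               stringsAsFactors = FALSE),
    data.frame(snp = bg_ids, pos = bg_pos, in_peak = TRUE, ld_proxy = FALSE,
               background = TRUE, locus = NA_integer_,
               stringsAsFactors = FALSE))

  truth <- data.frame(snp = ai$snp[imb],
                      locus = ai$locus[imb],
                      ratio = rep(config$imbalance_ratio, sum(imb)),
                      stringsAsFactors = FALSE)
  counts <- do.call(rbind, c(count_rows, bg_rows))
  rownames(counts) <- NULL
  rownames(ann) <- NULL
  list(counts = counts,
       annotations = ann,
       testable_truth = ai$snp[testable],
       truth = truth)
}

# ---------------------------------------------------------------------------
# Genotype sources (imputation + WGS) for the reconciliation stage

#' Generate imputed and WGS genotype sources with planted defects
#'
#' Starting from the true dosage matrix, emits an imputation layer
#' (probability triples with per-SNP information measures; 99 percent of
#' calls concentrate on the true genotype) and a WGS layer (normal and
#' tumor calls with read depth and quality flags), plus per-sample copy
#' number alteration masks.  Planted defects exercise every
#' reconciliation rule: low-information SNPs, uncertain calls,
#' normal/tumor-discordant WGS calls, low-depth WGS calls, imputation
#' errors that WGS corrects, and CNA-masked intervals.
#'
#' @param genotypes True dosage matrix (samples x SNPs).
#' @param panel A \code{"haplotype_panel"} (for SNP positions).
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{imputed} (list: \code{info} named vector,
#'   \code{probs} 3-d array samples x SNPs x genotype), \code{wgs} (list:
#'   \code{normal}, \code{tumor}, \code{depth} matrices and \code{qual_ok}
#'   flag matrix), \code{cna_mask} (named list of per-sample interval data
#'   frames) and \code{truth} (planted defect ledger).
#' @export
make_genotype_sources <- function(genotypes, panel, config) {
  set.seed(stage_seed(config$seed, "geno_sources"))
  samples <- rownames(genotypes)
  snp_ids <- colnames(genotypes)
  ns <- length(samples); np <- length(snp_ids)

  err_rate <- 0.01
  probs <- array(0, dim = c(ns, np, 3),
                 dimnames = list(samples, snp_ids, NULL))
  imput_called <- matrix(0L, ns, np, dimnames = list(samples, snp_ids))
  for (j in seq_len(np)) {
    g <- genotypes[, j]
    wrong <- stats::runif(ns) < err_rate
    gi <- ifelse(wrong, (g + sample(1:2, ns, replace = TRUE)) %% 3L, g)
    conf <- stats::runif(ns, 0.93, 1.0)
    for (s in seq_len(ns)) {
      p <- rep((1 - conf[s]) / 2, 3)
      p[gi[s] + 1L] <- conf[s]
      probs[s, j, ] <- p
    }
    imput_called[, j] <- gi
  }
  info <- stats::setNames(stats::runif(np, 0.9, 1.0), snp_ids)
  low_info <- sample(snp_ids, max(1L, np %/% 100L))
  info[low_info] <- stats::runif(length(low_info), 0.5, 0.84)

  wgs_err <- 0.002
  wrongw <- matrix(stats::runif(ns * np) < wgs_err, ns, np)
  normal <- (genotypes + wrongw * sample(1:2, ns * np, replace = TRUE)) %% 3L
  normal[!wrongw] <- genotypes[!wrongw]
  tumor <- normal
  # planted normal/tumor discordance (these WGS calls become invalid)
  nt_disc <- cbind(sample.int(ns, 20, replace = TRUE),
                   sample.int(np, 20, replace = TRUE))
  tumor[nt_disc] <- (tumor[nt_disc] + 1L) %% 3L
  depth <- matrix(stats::rpois(ns * np, 30), ns, np,
                  dimnames = list(samples, snp_ids))
  qual_ok <- matrix(stats::runif(ns * np) > 0.01, ns, np,
                    dimnames = list(samples, snp_ids))
  dimnames(normal) <- dimnames(tumor) <- list(samples, snp_ids)

  # per-sample CNA masks: 3 samples with one masked interval each
  masked_samples <- sample(samples, 3)
  cna_mask <- stats::setNames(
    lapply(seq_along(masked_samples), function(i) {
      at <- sample(panel$snps$pos, 1)
      data.frame(start = max(0L, at - 5000L), end = at + 5000L)
    }), masked_samples)

  list(imputed = list(info = info, probs = probs),
       wgs = list(normal = normal, tumor = tumor, depth = depth,
                  qual_ok = qual_ok),
       cna_mask = cna_mask,
       truth = list(low_info_snps = low_info, nt_discordant = nt_disc,
                    masked_samples = masked_samples))
}

# ---------------------------------------------------------------------------
# Motif fixture

#' Generate the motif-disruption fixture
#'
#' A strong SPI1-like PWM (purine-rich GGAA core) plus, for a handful of
#' proxy SNPs, flanking sequences (+/- 20 bp) whose reference allele
#' completes the consensus and whose alternative allele destroys it, and
#' matched control SNPs embedded in random sequence.
#'
#' @param panel A \code{"haplotype_panel"}.
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{pwms} (list of \code{"pwm"} objects),
#'   \code{snps} (data frame \code{snp, context, offset, ref, alt}) and
#'   \code{truth} (planted disrupted SNP ids).
#' @export
make_motif_fixture <- function(panel, config) {
  set.seed(stage_seed(config$seed, "motif"))
  consensus <- c("A", "G", "A", "G", "G", "A", "A", "G", "T")
  L <- length(consensus)
  bases <- c("A", "C", "G", "T")
  mat <- matrix(0.02, nrow = 4, ncol = L, dimnames = list(bases, NULL))
  for (p in seq_len(L)) mat[consensus[p], p] <- 0.94
  mat <- sweep(mat, 2, colSums(mat), "/")
  pwm <- structure(list(id = "MA0080_syn", name = "SPI1_synthetic",
                        mat = mat, bg = rep(0.25, 4)), class = "pwm")

  flank <- 20L
  rand_seq <- function(n) paste(sample(bases, n, replace = TRUE),
                                collapse = "")
  snp_rows <- list()
  disrupted <- character(0)
  sent <- panel$sentinels[seq_len(6)]
  for (i in seq_along(sent)) {
    left <- rand_seq(flank - 4L)
    right <- rand_seq(flank - (L - 5L))
    # embed consensus so that its 5th base is the SNP position
    ctx <- paste0(left, paste(consensus[1:4], collapse = ""),
                  consensus[5], paste(consensus[6:L], collapse = ""), right)
    if (i <= 3) {
      ref <- consensus[5]
      alt <- sample(setdiff(bases, ref), 1)
      disrupted <- c(disrupted, sent[i])
    } else {
      ctx <- rand_seq(2L * flank + 1L)
      ref <- substr(ctx, flank + 1L, flank + 1L)
      alt <- sample(setdiff(bases, ref), 1)
    }
    snp_rows[[i]] <- data.frame(snp = sent[i], context = ctx,
                                offset = flank, ref = ref, alt = alt,
                                stringsAsFactors = FALSE)
  }
  list(pwms = list(pwm), snps = do.call(rbind, snp_rows),
       truth = disrupted)
}

# ---------------------------------------------------------------------------
# Bundle

#' Simulate the complete fixture bundle
#'
#' Runs every generator under named substreams of the root seed and
#' assembles the result: haplotype panel, genotypes, genotype sources,
#' segmentation tracks, feature layers with TAD/gene maps, allele counts,
#' motif fixture, and the truth tables of every planted effect.
#'
#' @param config A \code{\link{sim_config}} (or NULL for defaults).
#' @return An object of class \code{"fixture_bundle"}.
#' @export
simulate_bundle <- function(config = sim_config()) {
  validate_sim_config(config)
  panel <- make_haplotype_panel(config)
  genotypes <- make_genotypes(panel, config)
  sources <- make_genotype_sources(genotypes, panel, config)
  tracks <- make_segmentations(panel, config)
  feats <- make_feature_layers(panel, genotypes, config)
  ac <- make_allele_counts(genotypes, panel, config)
  motif <- make_motif_fixture(panel, config)
  regions <- planted_locus_regions(panel)

  truth <- list(
    qtl = feats$truth,
    imbalanced_snps = ac$truth,
    testable_snps = ac$testable_truth,
    enriched_loci = regions$sentinel[seq_len(config$n_enriched_loci)],
    active_snp_loci = regions$sentinel[seq_len(config$n_active_snp_loci)],
    locus_regions = regions)

  structure(
    list(config = config, panel = panel, genotypes = genotypes,
         genotype_sources = sources, tracks = tracks,
         layers = feats$layers, tads = feats$tads, genes = feats$genes,
         allele_counts = ac$counts, snp_annotations = ac$annotations,
         motif = motif, truth = truth),
    class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("Synthetic fixture bundle\n")
  cat(sprintf("  %d loci, %d samples, %d chromatin tracks\n",
              x$config$n_loci, x$config$n_samples, length(x$tracks)))
  cat(sprintf("  panel: %d SNPs; allele-count table: %d rows\n",
              ncol(x$panel$haplotypes), nrow(x$allele_counts)))
  cat(sprintf("  planted: %d QTL pairs, %d imbalanced SNPs, %d enriched loci\n",
              nrow(x$truth$qtl), nrow(x$truth$imbalanced_snps),
              length(x$truth$enriched_loci)))
  invisible(x)
}
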