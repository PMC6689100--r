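# Chromatin-state enrichment of risk loci.  Coverage fractions of a region
# by each of the 12 states are compared against the background-region
# coverage on the log2 scale:
#
#     E[state] = log2( C[state; locus] / C[state; background] )
#
# A locus fraction of 0 yields NaN; a zero background fraction with a
# positive locus fraction yields +Inf.  Sentinels propagate (they are
# excluded from medians) rather than being patched with pseudocounts.

state_at <- function(track, pos) {
  if (pos < 0 || pos >= track$genome_length) stop("position outside track")
  as.character(track$states[pos %/% track$bin_width + 1L])
}

#' Chromatin-state coverage of a region
#'
#' Base-weighted fraction of the region covered by each state, from a
#' binned segmentation track.  Fractions sum to 1.
#'
#' @param start,end Region bounds, 0-based half-open.
#' @param track A \code{"segmentation_track"}.
#' @return Named numeric vector of per-state fractions over the full state
#'   alphabet.
#' @export
state_coverage <- function(start, end, track) {
  if (start < 0 || end > track$genome_length || end <= start)
    stop("region outside track extent")
  w <- track$bin_width
  first <- start %/% w
  last <- (end - 1L) %/% w
  idx <- first:last
  ov <- pmin(end, (idx + 1) * w) - pmax(start, idx * w)
  st <- track$states[idx + 1L]
  cov <- vapply(split(ov, st), sum, numeric(1))
  cov <- cov[levels(track$states)]
  names(cov) <- levels(track$states)
  cov[is.na(cov)] <- 0
  cov / (end - start)
}

#' Chromatin-state coverage of an interval set
#'
#' Length-weighted coverage fractions over the union of intervals (used
#' for background regions).
#'
#' @param intervals Data frame with \code{start} and \code{end}.
#' @param track A \code{"segmentation_track"}.
#' @return Named per-state fraction vector summing to 1.
#' @export
state_coverage_regions <- function(intervals, track) {
  if (nrow(intervals) == 0) stop("empty interval set")
  tot <- sum(intervals$end - intervals$start)
  acc <- 0
  for (i in seq_len(nrow(intervals))) {
    len <- intervals$end[i] - intervals$start[i]
    acc <- acc + state_coverage(intervals$start[i], intervals$end[i],
                                track) * len
  }
  acc / tot
}

#' Per-state enrichment of a locus against background
#'
#' \code{E = log2(locus fraction / background fraction)} per state.
#'
#' @param locus_cov Named per-state fractions of the locus region.
#' @param background_cov Named per-state fractions of the background.
#' @return Named numeric vector of log2 enrichments; NaN where the locus
#'   fraction is 0, +Inf where only the background fraction is 0.
#' @export
enrichment_score <- function(locus_cov, background_cov) {
  if (!identical(names(locus_cov), names(background_cov)))
    stop("mismatched state alphabets")
  E <- ifelse(locus_cov == 0, NaN,
              ifelse(background_cov == 0, Inf,
                     log2(locus_cov / background_cov)))
  names(E) <- names(locus_cov)
  E
}

#' Per-SNP chromatin-state annotation of risk loci
#'
#' Reports the chromatin state at each proxy SNP of each locus in each
#' segmentation track, and flags a locus active when at least one proxy
#' SNP falls in an active state (active promoter or strong enhancer) in at
#' least one sample.  Sentinel-only annotation is reported alongside.
#'
#' @param loci List of \code{"risk_locus"} objects.
#' @param tracks List of \code{"segmentation_track"} objects.
#' @return List with \code{per_snp} (data frame: sentinel, snp, pos,
#'   sample, state, active), \code{locus_summary} (data frame: sentinel,
#'   active, sentinel_active) and counts \code{n_active},
#'   \code{n_sentinel_active}.
#' @export
snp_state_annotation <- function(loci, tracks) {
  act <- active_states()
  rows <- list()
  for (l in loci) {
    for (tr in tracks) {
      st <- vapply(l$proxies$pos, function(p) state_at(tr, p), character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        sentinel = l$sentinel, snp = l$proxies$snp, pos = l$proxies$pos,
        sample = tr$sample, state = st, active = st %in% act,
        stringsAsFactors = FALSE)
    }
  }
  per_snp <- do.call(rbind, rows)
  agg <- split(per_snp, per_snp$sentinel)
  locus_summary <- do.call(rbind, lapply(agg, function(d) {
    data.frame(sentinel = d$sentinel[1],
               active = any(d$active),
               sentinel_active = any(d$active[d$snp == d$sentinel[1]]),
               stringsAsFactors = FALSE)
  }))
  # keep input locus order
  locus_summary <- locus_summary[match(vapply(loci, `[[`, "", "sentinel"),
                                       locus_summary$sentinel), ]
  rownames(locus_summary) <- NULL
  list(per_snp = per_snp, locus_summary = locus_summary,
       n_active = sum(locus_summary$active),
       n_sentinel_active = sum(locus_summary$sentinel_active))
}

#' Fraction of loci with active-chromatin enrichment in one sample
#'
#' A locus counts when its enrichment E is strictly positive for at least
#' one active state (active promoter or strong enhancer) in the given
#' track.
#'
#' @param loci List of \code{"risk_locus"} objects.
#' @param track A \code{"segmentation_track"}.
#' @param background_cov Per-state background fractions for this track
#'   (from \code{\link{state_coverage_regions}}).
#' @return Fraction in \[0, 1\].
#' @export
fraction_active_per_sample <- function(loci, track, background_cov) {
  act <- active_states()
  hits <- vapply(loci, function(l) {
    cov <- state_coverage(l$start, l$end, track)
    E <- enrichment_score(cov, background_cov)
    any(is.finite(E[act]) & E[act] > 0) || any(is.infinite(E[act]) & E[act] > 0)
  }, logical(1))
  mean(hits)
}

#' Enrichment profiles of loci across all samples
#'
#' @param loci List of \code{"risk_locus"} objects.
#' @param tracks List of segmentation tracks.
#' @param backgrounds Named list (by track sample) of background coverage
#'   vectors.
#' @return Data frame: sentinel, sample, state, locus_fraction,
#'   background_fraction, E.
#' @export
enrichment_profiles <- function(loci, tracks, backgrounds) {
  rows <- list()
  for (l in loci) {
    for (tr in tracks) {
      cov <- state_coverage(l$start, l$end, tr)
      bg <- backgrounds[[tr$sample]]
      E <- enrichment_score(cov, bg)
      rows[[length(rows) + 1L]] <- data.frame(
        sentinel = l$sentinel, sample = tr$sample, state = names(cov),
        locus_fraction = as.numeric(cov),
        background_fraction = as.numeric(bg), E = as.numeric(E),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify loci into the five chromatin-state groups
#'
#' For each locus the per-state enrichment is summarized as the median E
#' across samples (non-finite sentinels excluded).  State families:
#' Active = \{ActProm, StrEnh1, StrEnh2\}, Weak = \{WkProm, WkEnh\},
#' Transcribed = \{Txn_Trans, Txn_Elong, Wk_Txn\}.  Groups: (1) active
#' only, (2) active and transcribed, (3) weak only, (4) weak and
#' transcribed, (5) neither active nor weak (poised/inactive).  Active
#' takes precedence over weak.
#'
#' @param profiles Data frame from \code{\link{enrichment_profiles}}.
#' @return Data frame \code{sentinel, group}.
#' @export
classify_locus_groups <- function(profiles) {
  if (nrow(profiles) == 0) stop("empty enrichment profiles")
  fam <- list(active = active_states(),
              weak = c("WkProm", "WkEnh"),
              txn = c("Txn_Trans", "Txn_Elong", "Wk_Txn"))
  med_pos <- function(d, states) {
    e <- d$E[d$state %in% states]
    out <- vapply(split(d$E[d$state %in% states], d$state[d$state %in% states]),
                  function(v) {
                    v <- v[is.finite(v)]
                    if (length(v) == 0) -Inf else stats::median(v)
                  }, numeric(1))
    any(out > 0)
  }
  res <- lapply(split(profiles, profiles$sentinel), function(d) {
    a <- med_pos(d, fam$active)
    w <- med_pos(d, fam$weak)
    t <- med_pos(d, fam$txn)
    grp <- if (a) (if (t) 2L else 1L) else if (w) (if (t) 4L else 3L) else 5L
    data.frame(sentinel = d$sentinel[1], group = grp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[match(unique(profiles$sentinel), out$sentinel), ]
  rownames(out) <- NULL
  out
}

#' Permutation-based expected count over background regions
#'
#' Places the template interval set (length-matched, uniformly) into the
#' background regions \code{n_perm} times, applies a user-supplied counter
#' to each placement, and reports the mean permuted count, the
#' add-one-corrected empirical p-value of the observed count, and a Fisher
#' exact comparison of observed versus expected out of \code{total}.
#'
#' @param observed_count Observed count.
#' @param counter Function taking a data frame of intervals
#'   (\code{start}, \code{end}) and returning a count.
#' @param background A \code{"background_regions"} object.
#' @param template_lengths Integer vector of template interval lengths.
#' @param total Total units underlying the count (denominator of the
#'   Fisher comparison).
#' @param n_perm Number of permutations (default 1000).
#' @return List with \code{expected}, \code{empirical_p},
#'   \code{fisher} (a \code{\link{test_result}}) and \code{perm_counts}.
#' @export
permutation_expected <- function(observed_count, counter, background,
                                 template_lengths, total, n_perm = 1000) {
  iv <- background$intervals
  if (nrow(iv) == 0) stop("empty background")
  widths <- iv$end - iv$start
  if (any(max(widths) < template_lengths))
    stop("template interval longer than every background interval")
  perm_counts <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    st <- en <- integer(length(template_lengths))
    for (i in seq_along(template_lengths)) {
      len <- template_lengths[i]
      fit <- widths - len
      ok <- which(fit >= 0)
      # uniform over all valid placements: weight intervals by slack + 1
      w <- fit[ok] + 1
      j <- ok[sample.int(length(ok), 1, prob = w)]
      off <- sample.int(fit[j] + 1, 1) - 1L
      st[i] <- iv$start[j] + off
      en[i] <- st[i] + len
    }
    perm_counts[p] <- counter(data.frame(start = st, end = en))
  }
  expected <- mean(perm_counts)
  emp_p <- (1 + sum(perm_counts >= observed_count)) / (n_perm + 1)
  fisher <- fisher_exact_2x2(observed_count, total - observed_count,
                             round(expected), total - round(expected))
  list(expected = expected, empirical_p = emp_p, fisher = fisher,
       perm_counts = perm_counts)
}

#' Compare active-fraction distributions between traits
#'
#' All pairwise two-sided Wilcoxon rank-sum tests (normal approximation)
#' on per-sample active-locus fractions, Bonferroni-corrected over the
#' number of pairs.
#'
#' @param fractions_by_trait Named list of per-sample fraction vectors,
#'   one per trait; at least two traits of at least two samples each.
#' @return Data frame with one row per pair: traits, W, raw and corrected
#'   p, group medians and their difference.
#' @export
compare_active_fractions <- function(fractions_by_trait) {
  if (length(fractions_by_trait) < 2) stop("need at least two traits")
  if (any(vapply(fractions_by_trait, length, 0L) < 2))
    stop("each trait needs at least two samples")
  traits <- names(fractions_by_trait)
  pairs <- utils::combn(traits, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tr <- wilcoxon_rank_sum(fractions_by_trait[[a]],
                            fractions_by_trait[[b]], mode = "normal")
    data.frame(trait_a = a, trait_b = b, W = tr$statistic,
               p_value = tr$p_value,
               median_a = stats::median(fractions_by_trait[[a]]),
               median_b = stats::median(fractions_by_trait[[b]]),
               median_diff = tr$estimate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- adjust_pvalues(out$p_value, "bonferroni")
  out
}
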