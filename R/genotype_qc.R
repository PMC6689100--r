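# Genotype assignment and reconciliation.  Imputed probability triples are
# converted to hard calls under an uncertainty threshold, SNPs and samples
# pass standard quality control, copy-number-altered intervals are masked,
# and imputed calls are reconciled against WGS calls with concordance
# rules: discordant samples are excluded, discordant SNPs become WGS-only,
# remaining conflicts resolve to WGS, and WGS fills imputation gaps.

#' Call genotypes from imputation probability triples
#'
#' Uncertainty is \code{1 - max(triple)}; the argmax genotype is assigned
#' when the uncertainty does not exceed the threshold, otherwise the call
#' is missing.
#'
#' @param probs Numeric matrix with 3 columns (hom-ref, het, hom-alt) or a
#'   length-3 vector; rows must sum to 1 within 1e-6.
#' @param uncertainty_threshold Calls with uncertainty strictly above this
#'   are set missing (default 0.1).
#' @return Integer vector of dosages (0/1/2) with NA for no-calls.
#' @export
call_from_probabilities <- function(probs, uncertainty_threshold = 0.1) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  if (ncol(probs) != 3) stop("probability triples must have 3 columns")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("malformed probability triple: rows must sum to 1")
  mx <- apply(probs, 1, max)
  g <- max.col(probs, ties.method = "first") - 1L
  g[1 - mx > uncertainty_threshold] <- NA_integer_
  g
}

#' Per-SNP quality control
#'
#' Fails SNPs on call rate below 95 percent, minor allele frequency below
#' 1 percent, or exact Hardy-Weinberg p below 1e-6 (computed on
#' non-missing calls).  All failing reasons are accumulated.
#'
#' @param G Dosage matrix (samples x SNPs) with NA for missing calls.
#' @param call_rate_min,maf_min,hwe_p_min Thresholds (strict-less-than
#'   failures).
#' @return Data frame: snp, call_rate, maf, hwe_p, pass, reasons.
#' @export
snp_qc <- function(G, call_rate_min = 0.95, maf_min = 0.01,
                   hwe_p_min = 1e-6) {
  if (nrow(G) < 1) stop("need at least one sample")
  res <- lapply(colnames(G), function(s) {
    g <- G[, s]
    cr <- mean(!is.na(g))
    g <- g[!is.na(g)]
    if (length(g) == 0) {
      maf <- 0; hwe <- 1
    } else {
      af <- mean(g) / 2
      maf <- min(af, 1 - af)
      hwe <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))$p_value
    }
    reasons <- c(if (cr < call_rate_min) "call_rate",
                 if (maf < maf_min) "maf",
                 if (hwe < hwe_p_min) "hwe")
    data.frame(snp = s, call_rate = cr, maf = maf, hwe_p = hwe,
               pass = length(reasons) == 0,
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-sample quality control
#'
#' Excludes heterozygosity outliers (per-sample het rate more than 3 SD
#' from the cohort mean) and related pairs (genotype identity above 0.9
#' over shared non-missing SNPs; the member with the lower call rate is
#' excluded).
#'
#' @param G Dosage matrix (samples x SNPs).
#' @param het_sd Outlier threshold in SD units (default 3).
#' @param relatedness_max Identity-fraction threshold (default 0.9).
#' @return Data frame of excluded samples with reason codes (possibly
#'   empty).
#' @export
sample_qc <- function(G, het_sd = 3, relatedness_max = 0.9) {
  if (nrow(G) < 3) stop("need at least 3 samples")
  het <- apply(G, 1, function(g) mean(g[!is.na(g)] == 1))
  mu <- mean(het); sd_ <- stats::sd(het)
  out <- list()
  if (is.finite(sd_) && sd_ > 0) {
    for (s in rownames(G)[abs(het - mu) > het_sd * sd_])
      out[[length(out) + 1L]] <- data.frame(sample = s,
                                            reason = "excess_heterozygosity",
                                            stringsAsFactors = FALSE)
  }
  cr <- apply(G, 1, function(g) mean(!is.na(g)))
  ns <- nrow(G)
  for (i in 1:(ns - 1)) for (j in (i + 1):ns) {
    shared <- !is.na(G[i, ]) & !is.na(G[j, ])
    if (!any(shared)) next
    ident <- mean(G[i, shared] == G[j, shared])
    if (ident > relatedness_max) {
      drop <- if (cr[i] < cr[j]) rownames(G)[i] else rownames(G)[j]
      out[[length(out) + 1L]] <- data.frame(sample = drop,
                                            reason = "relatedness",
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(sample = character(), reason = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[!duplicated(res$sample), , drop = FALSE]
}

#' Reconcile imputed and WGS genotype calls
#'
#' Applies the assignment ledger in order: (1) imputed SNPs with
#' information measure below \code{info_min} are dropped; (2) probability
#' triples are converted to hard calls; (3) calls inside per-sample CNA
#' intervals are masked; (4) WGS calls are valid only when depth and
#' quality pass and normal equals tumor; (5) samples with imputed/WGS
#' concordance below \code{concordance_min} are excluded; (6) SNPs with
#' concordance below \code{concordance_min} become WGS-only; (7) remaining
#' conflicts resolve to the WGS call; (8) missing imputed calls are filled
#' from WGS.  Concordance is computed over calls non-missing in both
#' sources.
#'
#' @param imputed List with \code{info} (named per-SNP vector) and
#'   \code{probs} (samples x SNPs x 3 array).
#' @param wgs List with matrices \code{normal}, \code{tumor},
#'   \code{depth} and logical \code{qual_ok} (samples x SNPs); may cover a
#'   subset of samples/SNPs.
#' @param snp_pos Named vector of SNP positions (for CNA masking).
#' @param cna_mask Named list (by sample) of interval data frames
#'   (\code{start}, \code{end}, 0-based half-open).
#' @param sentinel_snps Optional SNP subset over which per-sample
#'   concordance is computed (the fidelity-check set); defaults to all
#'   SNPs.  Per-SNP concordance always uses the full universe.
#' @param info_min,uncertainty_threshold,depth_min,concordance_min
#'   Rule thresholds.
#' @return List with \code{genotypes} (reconciled matrix over retained
#'   samples), \code{provenance} (character matrix: imputed / wgs /
#'   filled / masked / conflict_resolved / missing) and \code{report}
#'   (exclusions, per-sample and per-SNP concordance, provenance counts,
#'   wgs_only_snps, n_conflicts).
#' @export
reconcile <- function(imputed, wgs, snp_pos, cna_mask = list(),
                      sentinel_snps = NULL, info_min = 0.85,
                      uncertainty_threshold = 0.1, depth_min = 10,
                      concordance_min = 0.9) {
  samples <- dimnames(imputed$probs)[[1]]
  snps <- dimnames(imputed$probs)[[2]]
  shared_samples <- intersect(samples, rownames(wgs$normal))
  shared_snps <- intersect(snps, colnames(wgs$normal))
  if (length(shared_samples) == 0 || length(shared_snps) == 0)
    stop("empty intersection of imputed and WGS universes")

  ns <- length(samples); np <- length(snps)
  # (1) + (2): imputed hard calls
  imp <- matrix(NA_integer_, ns, np, dimnames = list(samples, snps))
  for (j in seq_len(np)) {
    if (imputed$info[snps[j]] < info_min) next
    imp[, j] <- call_from_probabilities(imputed$probs[, j, ],
                                        uncertainty_threshold)
  }

  # (3) CNA masking (applies to the final output universe)
  masked <- matrix(FALSE, ns, np, dimnames = list(samples, snps))
  for (s in names(cna_mask)) {
    if (!s %in% samples) next
    iv <- cna_mask[[s]]
    for (r in seq_len(nrow(iv))) {
      hit <- snp_pos[snps] >= iv$start[r] & snp_pos[snps] < iv$end[r]
      masked[s, hit] <- TRUE
    }
  }
  imp[masked] <- NA_integer_

  # (4) valid WGS calls
  wgs_call <- matrix(NA_integer_, ns, np, dimnames = list(samples, snps))
  ok <- !is.na(wgs$normal) & !is.na(wgs$tumor) &
    wgs$normal == wgs$tumor & wgs$depth >= depth_min & wgs$qual_ok
  for (s in shared_samples) for (j in shared_snps) {
    if (isTRUE(ok[s, j])) wgs_call[s, j] <- wgs$normal[s, j]
  }
  wgs_call[masked] <- NA_integer_

  both <- !is.na(imp) & !is.na(wgs_call)
  agree <- both & (imp == wgs_call)

  # (5) per-sample concordance over the fidelity-check SNP set
  conc_snps <- if (is.null(sentinel_snps)) snps
  else intersect(sentinel_snps, snps)
  sample_conc <- vapply(samples, function(s) {
    n <- sum(both[s, conc_snps])
    if (n == 0) NA_real_ else sum(agree[s, conc_snps]) / n
  }, numeric(1))
  excluded <- names(sample_conc)[!is.na(sample_conc) &
                                   sample_conc < concordance_min]
  keep <- setdiff(samples, excluded)

  # (6) per-SNP concordance over the full sample universe (a SNP failing
  # imputation fidelity does so regardless of which samples survive)
  snp_conc <- vapply(snps, function(j) {
    n <- sum(both[, j])
    if (n == 0) NA_real_ else sum(agree[, j]) / n
  }, numeric(1))
  wgs_only <- names(snp_conc)[!is.na(snp_conc) &
                                snp_conc < concordance_min]

  # assemble output with provenance
  out <- matrix(NA_integer_, length(keep), np,
                dimnames = list(keep, snps))
  prov <- matrix("missing", length(keep), np,
                 dimnames = list(keep, snps))
  n_conflicts <- 0L
  for (s in keep) for (j in snps) {
    if (masked[s, j]) { prov[s, j] <- "masked"; next }
    iv <- imp[s, j]; wv <- wgs_call[s, j]
    if (j %in% wgs_only) {
      if (!is.na(wv)) { out[s, j] <- wv; prov[s, j] <- "wgs" }
      next
    }
    if (!is.na(iv) && !is.na(wv) && iv != wv) {
      out[s, j] <- wv; prov[s, j] <- "conflict_resolved"
      n_conflicts <- n_conflicts + 1L
    } else if (!is.na(iv)) {
      out[s, j] <- iv; prov[s, j] <- "imputed"
    } else if (!is.na(wv)) {
      out[s, j] <- wv; prov[s, j] <- "filled"
    }
  }

  report <- list(
    excluded_samples = data.frame(
      sample = excluded,
      reason = rep("imputed_wgs_discordance", length(excluded)),
      stringsAsFactors = FALSE),
    wgs_only_snps = wgs_only,
    sample_concordance = sample_conc,
    snp_concordance = snp_conc,
    provenance_counts = table(factor(prov, levels = c(
      "imputed", "wgs", "filled", "masked", "conflict_resolved",
      "missing"))),
    n_conflicts = n_conflicts)
  list(genotypes = out, provenance = prov, report = report)
}
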