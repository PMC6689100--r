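# Molecular QTL scan.  Eligible features are residualized against latent
# confounders (top principal components), inverse-normal transformed, and
# regressed on sentinel dosage one (sentinel, feature) pair at a time.
# Benjamini-Hochberg FDR is applied per layer; the candidate features for
# a locus are those intersecting the TAD window spanning its LD region.

default_k_factors <- c(accessibility = 10L, h3k27ac = 10L,
                       methylation = 45L, expression = 65L)

#' Feature eligibility by genotype subgroup presence
#'
#' A feature is eligible when it is present (peak called, or expression
#' above \code{expression_floor} for the expression layer) in at least
#' \code{max(min_count, ceiling(min_fraction * subgroup size))} patients
#' of at least one sentinel-genotype subgroup (homozygous non-risk,
#' heterozygous, homozygous risk).
#'
#' @param fm A \code{"feature_matrix"}.
#' @param genotypes Dosage matrix containing the sentinel column.
#' @param sentinel Sentinel SNP id.
#' @param min_fraction Presence fraction threshold (default 0.10).
#' @param min_count Minimum presence count (default 2).
#' @param expression_floor Expression presence threshold, strict greater
#'   than (default 4.5).
#' @return Character vector of eligible feature ids.
#' @export
feature_eligibility <- function(fm, genotypes, sentinel,
                                min_fraction = 0.10, min_count = 2,
                                expression_floor = 4.5) {
  if (!sentinel %in% colnames(genotypes))
    stop("sentinel '", sentinel, "' missing from genotypes")
  shared <- intersect(rownames(fm$values), rownames(genotypes))
  dos <- genotypes[shared, sentinel]
  pres <- if (fm$layer == "expression") {
    fm$values[shared, , drop = FALSE] > expression_floor
  } else {
    fm$presence[shared, , drop = FALSE]
  }
  eligible <- logical(ncol(pres))
  for (g in 0:2) {
    grp <- which(!is.na(dos) & dos == g)
    if (length(grp) == 0) next
    need <- max(min_count, ceiling(min_fraction * length(grp)))
    eligible <- eligible | colSums(pres[grp, , drop = FALSE]) >= need
  }
  colnames(pres)[eligible]
}

#' Remove latent confounders by principal-component residualization
#'
#' Standardizes each feature, removes the projection onto the top-k
#' principal components of the standardized matrix, and returns the
#' residuals (standardized scale).  \code{k = 0} returns the input
#' unchanged.
#'
#' @param M Samples x features numeric matrix.
#' @param k Number of components to remove; must be below the matrix
#'   rank.
#' @return Residual matrix with the input dimnames.
#' @export
residualize <- function(M, k) {
  if (k == 0) return(M)
  rk <- qr(scale(M))$rank
  if (k >= rk) stop("k must be below the matrix rank (", rk, ")")
  X <- scale(M)
  sv <- svd(X, nu = k, nv = 0)
  U <- sv$u
  res <- X - U %*% (t(U) %*% X)
  dimnames(res) <- dimnames(M)
  res
}

#' Per-layer default confounder counts
#'
#' 10 components for accessibility and H3K27ac, 45 for methylation, 65
#' for expression, capped at one below the matrix rank.
#'
#' @param layer Layer label.
#' @param M The feature matrix (for the rank cap).
#' @return Integer k.
#' @export
layer_k_factors <- function(layer, M) {
  k <- default_k_factors[[layer]]
  min(k, qr(scale(M))$rank - 1L)
}

#' Single-pair QTL test
#'
#' Simple linear regression of a (transformed) feature on dosage with a
#' two-sided t test on the slope at n - 2 degrees of freedom.  Pairs with
#' a missing dosage or value are dropped.
#'
#' @param values Feature values (already residualized and inverse-normal
#'   transformed in the scan pipeline).
#' @param dosages Risk-allele dosages (0/1/2), possibly with NA.
#' @return List: beta, se, t_statistic, p_value, n_used.
#' @export
qtl_test <- function(values, dosages) {
  keep <- !is.na(values) & !is.na(dosages)
  y <- values[keep]; x <- dosages[keep]
  n <- length(y)
  if (n < 3) stop("need at least 3 complete observations")
  if (stats::var(x) == 0) stop("zero dosage variance in analyzed samples")
  xc <- x - mean(x); yc <- y - mean(y)
  beta <- sum(xc * yc) / sum(xc^2)
  resid <- yc - beta * xc
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sum(xc^2))
  t <- beta / se
  p <- 2 * stats::pt(-abs(t), n - 2)
  list(beta = beta, se = se, t_statistic = t, p_value = p, n_used = n)
}

#' Candidate genes for a locus via TAD overlap
#'
#' The union of genes in every TAD intersecting the LD region (half-open
#' interval intersection; a gene abutting a TAD boundary is excluded).
#'
#' @param locus A \code{"risk_locus"}.
#' @param tads Data frame \code{tad, start, end}.
#' @param genes Data frame \code{gene, start, end}.
#' @return Character vector of gene ids (empty, with a warning, if no TAD
#'   overlaps the locus).
#' @export
tad_candidate_genes <- function(locus, tads, genes) {
  hit_tads <- tads[tads$start < locus$end & tads$end > locus$start, ,
                   drop = FALSE]
  if (nrow(hit_tads) == 0) {
    warning("no TAD overlaps locus ", locus$sentinel)
    return(character(0))
  }
  hits <- logical(nrow(genes))
  for (i in seq_len(nrow(hit_tads)))
    hits <- hits | (genes$start < hit_tads$end[i] &
                      genes$end > hit_tads$start[i])
  unique(genes$gene[hits])
}

tad_window <- function(locus, tads) {
  hit <- tads[tads$start < locus$end & tads$end > locus$start, ,
              drop = FALSE]
  if (nrow(hit) == 0) return(c(locus$start, locus$end))
  c(min(hit$start), max(hit$end))
}

#' Scan one molecular layer for QTLs
#'
#' For every locus, tests the sentinel dosage against each eligible
#' feature whose interval intersects the TAD window spanning the LD
#' region.  Feature values are residualized (top principal components,
#' per-layer default k) and inverse-normal transformed before testing.
#' Benjamini-Hochberg adjustment is applied across all tests in the
#' layer.
#'
#' @param fm A \code{"feature_matrix"}.
#' @param loci List of \code{"risk_locus"} objects.
#' @param genotypes Dosage matrix with sentinel columns.
#' @param tads TAD data frame (\code{tad, start, end}).
#' @param fdr_q Significance threshold on the FDR (default 0.05).
#' @param k_factors Number of confounder components; default per layer.
#' @return Data frame of QTL results (sentinel, feature, layer, beta,
#'   t_statistic, p_value, fdr, significant, n_used); empty with a
#'   warning when no testable pair exists.
#' @export
run_layer_scan <- function(fm, loci, genotypes, tads, fdr_q = 0.05,
                           k_factors = NULL) {
  if (is.null(k_factors)) k_factors <- layer_k_factors(fm$layer, fm$values)
  res <- residualize(fm$values, k_factors)
  trans <- apply(res, 2, inverse_normal_transform)
  rownames(trans) <- rownames(res)
  shared <- intersect(rownames(trans), rownames(genotypes))

  rows <- list()
  for (l in loci) {
    if (!l$sentinel %in% colnames(genotypes)) next
    eligible <- feature_eligibility(fm, genotypes, l$sentinel)
    win <- tad_window(l, tads)
    f <- fm$features
    in_win <- f$feature_id[f$start < win[2] & f$end > win[1]]
    test_feats <- intersect(eligible, in_win)
    dos <- genotypes[shared, l$sentinel]
    for (ft in test_feats) {
      r <- tryCatch(qtl_test(trans[shared, ft], dos),
                    error = function(e) NULL)
      if (is.null(r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sentinel = l$sentinel, feature = ft, layer = fm$layer,
        beta = r$beta, t_statistic = r$t_statistic, p_value = r$p_value,
        n_used = r$n_used, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    warning("empty QTL test set for layer ", fm$layer)
    return(data.frame(sentinel = character(), feature = character(),
                      layer = character(), beta = numeric(),
                      t_statistic = numeric(), p_value = numeric(),
                      n_used = integer(), fdr = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$fdr <- adjust_pvalues(out$p_value, "bh")
  out$significant <- out$fdr < fdr_q
  rownames(out) <- NULL
  out
}

#' Cross-layer direction concordance of overlapping QTLs
#'
#' For significant QTLs with intersecting feature intervals:
#' accessibility/H3K27ac pairs are concordant when their slopes share a
#' sign; methylation against either activity layer is concordant when the
#' signs are opposite.
#'
#' @param results Named list of per-layer QTL result data frames (from
#'   \code{\link{run_layer_scan}}).
#' @param feature_intervals Named list of per-layer feature data frames
#'   (\code{feature_id, start, end}).
#' @return Data frame: layer_a, layer_b, feature_a, feature_b, beta_a,
#'   beta_b, concordant — one row per overlapping significant pair
#'   (zero rows when none overlap).
#' @export
direction_concordance <- function(results, feature_intervals) {
  pairs <- list(c("accessibility", "h3k27ac", "same"),
                c("methylation", "accessibility", "opposite"),
                c("methylation", "h3k27ac", "opposite"))
  rows <- list()
  for (p in pairs) {
    la <- p[1]; lb <- p[2]; rule <- p[3]
    ra <- results[[la]]; rb <- results[[lb]]
    if (is.null(ra) || is.null(rb)) next
    ra <- ra[ra$significant, , drop = FALSE]
    rb <- rb[rb$significant, , drop = FALSE]
    if (nrow(ra) == 0 || nrow(rb) == 0) next
    fa <- feature_intervals[[la]]; fb <- feature_intervals[[lb]]
    for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(rb))) {
      ia <- fa[fa$feature_id == ra$feature[i], ]
      ib <- fb[fb$feature_id == rb$feature[j], ]
      if (nrow(ia) == 0 || nrow(ib) == 0) next
      if (!(ia$start < ib$end && ia$end > ib$start)) next
      conc <- if (rule == "same")
        sign(ra$beta[i]) == sign(rb$beta[j])
      else sign(ra$beta[i]) != sign(rb$beta[j])
      rows[[length(rows) + 1L]] <- data.frame(
        layer_a = la, layer_b = lb, feature_a = ra$feature[i],
        feature_b = rb$feature[j], beta_a = ra$beta[i],
        beta_b = rb$beta[j], concordant = conc,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(layer_a = character(), layer_b = character(),
                      feature_a = character(), feature_b = character(),
                      beta_a = numeric(), beta_b = numeric(),
                      concordant = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
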