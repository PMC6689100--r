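# Linkage-disequilibrium machinery: pairwise r-squared, LD0.2 proxy regions
# around sentinel SNPs, and the merged background-region set used as the
# denominator of chromatin-state enrichment.
#
# Coordinates are 0-based half-open (BED-native) throughout.

#' Pairwise linkage disequilibrium (r-squared)
#'
#' For phased haplotype input (a 0/1 matrix, haplotypes in rows), r-squared
#' is \code{D^2 / (pA pa pB pb)} with \code{D = pAB - pA pB}.  For unphased
#' genotype input (a 0/1/2 dosage matrix, samples in rows), it is the
#' squared Pearson correlation of dosages.
#'
#' @param x Matrix with SNPs in columns (haplotype 0/1 or dosage 0/1/2).
#' @param snp_a,snp_b Column names or indices of the two SNPs.
#' @param type \code{"haplotype"} or \code{"genotype"}.
#' @return r-squared in \[0, 1\].
#' @export
compute_r2 <- function(x, snp_a, snp_b, type = c("haplotype", "genotype")) {
  type <- match.arg(type)
  a <- x[, snp_a]; b <- x[, snp_b]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(unique(a)) < 2 || length(unique(b)) < 2)
    stop("monomorphic SNP: r-squared undefined")
  if (type == "haplotype") {
    pa <- mean(a); pb <- mean(b)
    D <- mean(a * b) - pa * pb
    r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  } else {
    r2 <- stats::cor(a, b)^2
  }
  min(1, max(0, r2))
}

#' Define the LD region of a sentinel SNP
#'
#' Proxies are all candidate SNPs with r-squared >= \code{r2_threshold} to
#' the sentinel (the comparison is inclusive; the sentinel itself always
#' qualifies with r-squared 1).  The LD region is the interval spanning the
#' minimum to the maximum proxy position, half-open at \code{max + 1}.
#'
#' @param sentinel Sentinel SNP identifier (must appear in \code{snps}).
#' @param snps Data frame with columns \code{snp} and \code{pos} describing
#'   the candidate SNPs.
#' @param data Haplotype or dosage matrix with the candidate SNPs in
#'   columns (see \code{\link{compute_r2}}).  Ignored when \code{r2} is
#'   supplied.
#' @param r2_threshold Proxy inclusion threshold, default 0.2.
#' @param type Passed to \code{\link{compute_r2}}.
#' @param r2 Optional precomputed vector of r-squared values to the
#'   sentinel, aligned with the rows of \code{snps}; allows use of external
#'   LD sources.
#' @return An object of class \code{"risk_locus"}: a list with
#'   \code{sentinel}, \code{sentinel_pos}, \code{proxies} (data frame
#'   \code{snp, pos, r2}), \code{start}, \code{end} (0-based half-open) and
#'   \code{size_kb}.
#' @export
define_ld_region <- function(sentinel, snps, data = NULL,
                             r2_threshold = 0.2,
                             type = c("haplotype", "genotype"), r2 = NULL) {
  type <- match.arg(type)
  idx <- match(sentinel, snps$snp)
  if (is.na(idx)) stop("sentinel '", sentinel, "' not in candidate set")
  if (is.null(r2)) {
    if (is.null(data)) stop("either 'data' or 'r2' must be supplied")
    r2 <- vapply(snps$snp, function(s) {
      if (s == sentinel) return(1)
      tryCatch(compute_r2(data, s, sentinel, type = type),
               error = function(e) 0)
    }, numeric(1))
  }
  if (length(r2) != nrow(snps)) stop("r2 must align with snps rows")
  r2[idx] <- 1
  keep <- r2 >= r2_threshold
  proxies <- data.frame(snp = snps$snp[keep], pos = snps$pos[keep],
                        r2 = r2[keep], stringsAsFactors = FALSE)
  proxies <- proxies[order(proxies$pos), , drop = FALSE]
  start <- min(proxies$pos)
  end <- max(proxies$pos) + 1L
  structure(
    list(sentinel = sentinel, sentinel_pos = snps$pos[idx],
         proxies = proxies, start = start, end = end,
         size_kb = (end - start) / 1000),
    class = "risk_locus")
}

#' @export
print.risk_locus <- function(x, ...) {
  cat(sprintf("Risk locus %s @ %d: %d proxies, region [%d, %d) (%.1f kb)\n",
              x$sentinel, x$sentinel_pos, nrow(x$proxies),
              x$start, x$end, x$size_kb))
  invisible(x)
}

#' Summarize a list of risk loci as a table
#'
#' @param loci List of \code{"risk_locus"} objects.
#' @return Data frame with one row per locus (sentinel, position, region
#'   bounds, proxy count, size in kb).
#' @export
loci_table <- function(loci) {
  do.call(rbind, lapply(loci, function(l) {
    data.frame(sentinel = l$sentinel, sentinel_pos = l$sentinel_pos,
               start = l$start, end = l$end, n_proxies = nrow(l$proxies),
               size_kb = l$size_kb, stringsAsFactors = FALSE)
  }))
}

merge_intervals <- function(start, end) {
  if (length(start) == 0) return(data.frame(start = integer(), end = integer()))
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

intervals_overlap <- function(a, b) {
  # logical vector over rows of a: does the interval overlap any row of b?
  if (nrow(a) == 0 || nrow(b) == 0) return(rep(FALSE, nrow(a)))
  ia <- IRanges::IRanges(start = a$start + 1L, end = a$end)
  ib <- IRanges::IRanges(start = b$start + 1L, end = b$end)
  IRanges::overlapsAny(ia, ib)
}

#' Build the background-region set
#'
#' The union of the LD regions of all panel SNPs is merged into maximal
#' non-overlapping intervals; any merged interval that overlaps an
#' exclusion interval (a risk-locus region) is then removed entirely.
#' Removal is region-level rather than base-level: a background interval
#' touching a risk locus is dropped, keeping the background conservative.
#'
#' @param snp_regions Data frame of per-SNP LD regions with \code{start}
#'   and \code{end} columns (0-based half-open).
#' @param exclusions Data frame of exclusion intervals (\code{start},
#'   \code{end}); typically \code{loci_table} output.
#' @return An object of class \code{"background_regions"}: a list with
#'   \code{intervals} (merged, sorted data frame) and \code{excluded}.
#' @export
build_background_regions <- function(snp_regions, exclusions = NULL) {
  if (is.null(snp_regions) || nrow(snp_regions) == 0)
    stop("empty SNP panel: cannot build background regions")
  merged <- merge_intervals(snp_regions$start, snp_regions$end)
  if (is.null(exclusions))
    exclusions <- data.frame(start = integer(), end = integer())
  hit <- intervals_overlap(merged, exclusions)
  structure(
    list(intervals = merged[!hit, , drop = FALSE],
         excluded = exclusions[, c("start", "end"), drop = FALSE]),
    class = "background_regions")
}

#' @export
print.background_regions <- function(x, ...) {
  cat(sprintf("Background regions: %d intervals, %.1f kb total (%d excluded intervals)\n",
              nrow(x$intervals),
              sum(x$intervals$end - x$intervals$start) / 1000,
              nrow(x$excluded)))
  invisible(x)
}

#' LD regions of every SNP in a haplotype panel
#'
#' For each SNP, computes the interval spanning all SNPs in the same LD
#' block with r-squared >= \code{r2_threshold} to it.  Used to construct
#' the genome-wide background-region set.
#'
#' @param panel A \code{"haplotype_panel"} (see
#'   \code{\link{make_haplotype_panel}}).
#' @param r2_threshold Inclusion threshold, default 0.2.
#' @return Data frame with \code{snp}, \code{start}, \code{end}.
#' @export
snp_ld_regions <- function(panel, r2_threshold = 0.2) {
  snps <- panel$snps
  out <- vector("list", length(unique(snps$block)))
  bi <- 0L
  for (blk in unique(snps$block)) {
    bi <- bi + 1L
    in_blk <- snps$block == blk
    ids <- snps$snp[in_blk]; pos <- snps$pos[in_blk]
    H <- panel$haplotypes[, ids, drop = FALSE]
    m <- length(ids)
    r2m <- diag(1, m)
    if (m > 1) {
      for (i in 1:(m - 1)) for (j in (i + 1):m) {
        r2m[i, j] <- r2m[j, i] <-
          tryCatch(compute_r2(H, ids[i], ids[j]), error = function(e) 0)
      }
    }
    st <- en <- integer(m)
    for (i in seq_len(m)) {
      prox <- pos[r2m[i, ] >= r2_threshold]
      st[i] <- min(prox); en[i] <- max(prox) + 1L
    }
    out[[bi]] <- data.frame(snp = ids, start = st, end = en,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
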