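# PWM-based transcription-factor motif disruption scoring.  Each allele's
# flanking sequence is scanned over every motif window covering the SNP on
# both strands; the per-window score is an information-content-weighted
# log-likelihood ratio against the background base distribution, and score
# p-values come from the exact score distribution of a background-random
# sequence (position-wise convolution).

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param mat 4 x L matrix of per-position base probabilities (rows
#'   A, C, G, T); columns must sum to 1 within 1e-6.
#' @param id,name Identifiers.
#' @param bg Background base distribution (default uniform).
#' @return An object of class \code{"pwm"}.
#' @export
pwm <- function(mat, id = "pwm", name = id, bg = rep(0.25, 4)) {
  if (nrow(mat) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (any(abs(colSums(mat) - 1) > 1e-6))
    stop("PWM columns must sum to 1")
  if (any(mat < 0)) stop("PWM probabilities must be non-negative")
  rownames(mat) <- BASES
  structure(list(id = id, name = name, mat = mat, bg = bg),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cons <- paste(BASES[apply(x$mat, 2, which.max)], collapse = "")
  cat(sprintf("PWM %s (%s): %d positions, consensus %s\n",
              x$id, x$name, ncol(x$mat), cons))
  invisible(x)
}

# per-position score contributions: IC-weighted log2 likelihood ratio,
# with pseudocount 1e-3 applied before the log
pwm_contributions <- function(p, pseudo = 1e-3) {
  q <- sweep(p$mat + pseudo, 2, colSums(p$mat + pseudo), "/")
  ic <- 2 + colSums(q * log2(q))
  sweep(log2(sweep(q, 1, p$bg, "/")), 2, ic, "*")
}

#' Score a sequence against a PWM
#'
#' \code{score = sum over positions of IC_p * log2(q_p(base) / bg(base))},
#' where IC_p is the information content of position p and q_p the
#' pseudocounted base probabilities.  Higher scores mean a better motif
#' match; a uniform PWM scores 0 everywhere.
#'
#' @param seq Character string of length equal to the motif width, bases
#'   in A/C/G/T.
#' @param p A \code{"pwm"}.
#' @param pseudo Pseudocount added to probabilities before the log
#'   (default 1e-3).
#' @return Numeric score.
#' @export
score_sequence <- function(seq, p, pseudo = 1e-3) {
  b <- strsplit(toupper(seq), "")[[1]]
  L <- ncol(p$mat)
  if (length(b) != L) stop("sequence length must equal motif width")
  if (!all(b %in% BASES)) stop("ambiguous base in sequence")
  contrib <- pwm_contributions(p, pseudo)
  sum(contrib[cbind(match(b, BASES), seq_len(L))])
}

revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(toupper(seq), "")[[1]]]), collapse = "")
}

pwm_score_range <- function(p, pseudo = 1e-3) {
  contrib <- pwm_contributions(p, pseudo)
  c(min = sum(apply(contrib, 2, min)), max = sum(apply(contrib, 2, max)))
}

#' Best motif-window scores for both alleles of a SNP
#'
#' Substitutes each allele into the flanking context, scans every motif
#' window covering the SNP position on both strands, and records the
#' maximum score (and its window and strand) per allele.  Scores are also
#' reported normalized to the PWM's achievable score range so deltas are
#' comparable across motifs.
#'
#' @param context Flanking sequence containing the SNP.
#' @param offset 0-based position of the SNP within \code{context}.
#' @param ref,alt Reference and alternative alleles (single bases).
#' @param p A \code{"pwm"}.
#' @return List with per-allele score, normalized score, window start
#'   (0-based in context) and strand, plus \code{delta} (normalized
#'   alt - ref).
#' @export
best_window_scores <- function(context, offset, ref, alt, p) {
  L <- ncol(p$mat)
  n <- nchar(context)
  if (n < L) stop("context shorter than motif")
  if (offset < L - 1 || n - offset < L)
    stop("context does not cover every motif window over the SNP")
  rng <- pwm_score_range(p)
  scan_allele <- function(allele) {
    s <- context
    substr(s, offset + 1L, offset + 1L) <- allele
    best <- -Inf; best_win <- NA_integer_; best_strand <- NA_character_
    for (st in (offset - L + 1L):offset) {
      win <- substr(s, st + 1L, st + L)
      for (strand in c("+", "-")) {
        sc <- score_sequence(if (strand == "+") win else revcomp(win), p)
        if (sc > best) {
          best <- sc; best_win <- st; best_strand <- strand
        }
      }
    }
    list(score = best,
         norm = (best - rng["min"]) / (rng["max"] - rng["min"]),
         window = best_win, strand = best_strand)
  }
  r <- scan_allele(ref)
  a <- scan_allele(alt)
  list(score_ref = r$score, score_alt = a$score,
       norm_ref = unname(r$norm), norm_alt = unname(a$norm),
       window_ref = r$window, strand_ref = r$strand,
       window_alt = a$window, strand_alt = a$strand,
       delta = unname(a$norm - r$norm))
}

#' Exact p-value of a PWM score
#'
#' \code{P(S >= score)} where S is the score of a sequence drawn from the
#' background base distribution.  The score distribution is built by
#' position-wise convolution: exhaustive (exact) for motifs up to 8
#' positions, on a discretized grid with step 1e-3 beyond that.
#'
#' @param score Observed score.
#' @param p A \code{"pwm"}.
#' @return Tail probability in \[0, 1\].
#' @export
score_pvalue <- function(score, p) {
  contrib <- pwm_contributions(p)
  L <- ncol(contrib)
  if (L <= 8) {
    # exhaustive position-wise convolution (at most 4^8 values, exact)
    vals <- 0; probs <- 1
    for (pos in seq_len(L)) {
      vals <- as.vector(outer(contrib[, pos], vals, "+"))
      probs <- as.vector(outer(p$bg, probs, "*"))
    }
    min(1, sum(probs[vals >= score - 1e-9]))
  } else {
    # discretized convolution on an integer grid of step 1e-3
    step <- 1e-3
    grid <- round(contrib / step)
    lo <- sum(pmin(0, apply(grid, 2, min)))
    hi <- sum(pmax(0, apply(grid, 2, max)))
    width <- hi - lo + 1L
    dist <- numeric(width)
    dist[1L - lo] <- 1   # running sum 0 sits at index 1 - lo
    for (pos in seq_len(L)) {
      nd <- numeric(width)
      for (b in 1:4) {
        sh <- grid[b, pos]
        src <- seq_len(width) - sh
        ok <- src >= 1 & src <= width
        nd[ok] <- nd[ok] + dist[src[ok]] * p$bg[b]
      }
      dist <- nd
    }
    vals <- (seq_len(width) - 1L + lo) * step
    min(1, sum(dist[vals >= score - step / 2]))
  }
}

#' Classify a disruption call by its normalized score delta
#'
#' @param delta Normalized score difference (alt - ref).
#' @param strong_delta,weak_delta Absolute-delta thresholds (defaults 0.7
#'   and 0.4; the boundary is assigned the stronger label).
#' @return \code{"strong"}, \code{"weak"} or \code{"neutral"}.
#' @export
classify_disruption <- function(delta, strong_delta = 0.7,
                                weak_delta = 0.4) {
  d <- abs(delta)
  if (d >= strong_delta) "strong" else if (d >= weak_delta) "weak"
  else "neutral"
}

#' Score SNPs against PWMs and classify disruption
#'
#' Runs \code{\link{best_window_scores}}, \code{\link{score_pvalue}} and
#' \code{\link{classify_disruption}} over each SNP x PWM combination.
#'
#' @param snps Data frame \code{snp, context, offset, ref, alt}.
#' @param pwms List of \code{"pwm"} objects.
#' @param strong_delta,weak_delta Classification thresholds.
#' @return Data frame: snp, motif, score_ref, score_alt, p_ref, p_alt,
#'   delta, effect.
#' @export
scan_disruptions <- function(snps, pwms, strong_delta = 0.7,
                             weak_delta = 0.4) {
  rows <- list()
  for (i in seq_len(nrow(snps))) {
    for (p in pwms) {
      bw <- best_window_scores(snps$context[i], snps$offset[i],
                               snps$ref[i], snps$alt[i], p)
      rows[[length(rows) + 1L]] <- data.frame(
        snp = snps$snp[i], motif = p$id,
        score_ref = bw$score_ref, score_alt = bw$score_alt,
        norm_ref = bw$norm_ref, norm_alt = bw$norm_alt,
        p_ref = score_pvalue(bw$score_ref, p),
        p_alt = score_pvalue(bw$score_alt, p),
        delta = bw$delta,
        effect = classify_disruption(bw$delta, strong_delta, weak_delta),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
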