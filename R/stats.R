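# Self-contained statistical primitives shared by every analysis stage:
# exact tests (Fisher 2x2, Hardy-Weinberg, beta-binomial), the Wilcoxon
# rank-sum test, multiple-testing adjustment and the rank-based inverse
# normal transform.  All two-sided exact tests use the minimum-likelihood
# rule: the two-sided p-value is the total probability of all outcomes no
# more likely than the observed one.

#' Construct a test-result record
#'
#' Lightweight container for the output of the package's hypothesis tests.
#'
#' @param statistic Test statistic.
#' @param p_value Two-sided p-value in \[0, 1\].
#' @param method Character label naming the test.
#' @param estimate Optional effect estimate (odds ratio, median difference,
#'   allele ratio, ...).
#' @param ci_low,ci_high Optional confidence bounds for \code{estimate}.
#' @return An object of class \code{"test_result"}: a list with the fields
#'   above, serializable to a flat table row via \code{as.data.frame}.
#' @export
test_result <- function(statistic, p_value, method,
                        estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_) {
  stopifnot(is.numeric(p_value), length(p_value) == 1L)
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value outside [0, 1]")
  structure(
    list(statistic = as.numeric(statistic), p_value = as.numeric(p_value),
         method = method, estimate = as.numeric(estimate),
         ci_low = as.numeric(ci_low), ci_high = as.numeric(ci_high)),
    class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", format(x$statistic), "  p =",
      format.pval(x$p_value, digits = 4), "\n")
  if (!is.na(x$estimate)) {
    cat("  estimate  =", format(x$estimate))
    if (!is.na(x$ci_low)) cat("  [", format(x$ci_low), ",",
                              format(x$ci_high), "]")
    cat("\n")
  }
  invisible(x)
}

#' @export
as.data.frame.test_result <- function(x, ...) {
  data.frame(statistic = x$statistic, p_value = x$p_value,
             estimate = x$estimate, ci_low = x$ci_low, ci_high = x$ci_high,
             method = x$method, stringsAsFactors = FALSE)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact conditional test of independence in a 2x2 contingency table
#' \code{[[a, b], [c, d]]}.  The two-sided p-value follows the
#' minimum-likelihood rule: it sums hypergeometric probabilities of all
#' tables (with the observed margins) whose probability does not exceed
#' that of the observed table.  The reported estimate is the sample odds
#' ratio \code{(a d)/(b c)}, infinite when the denominator is zero.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise.
#' @return A \code{\link{test_result}} with the odds ratio as estimate.
#' @examples
#' fisher_exact_2x2(8, 1, 35, 145)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) == 0) stop("all-zero table")
  m <- a + b        # row 1 total
  n <- c + d        # row 2 total
  k <- a + c        # column 1 total
  support <- max(0L, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  test_result(statistic = a, p_value = p,
              method = "Fisher exact test (two-sided)", estimate = or)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' The statistic is the Mann-Whitney U for \code{x}: the number of
#' \code{(x, y)} pairs with \code{x > y} plus half the tied pairs.  The
#' exact mode enumerates the full permutation distribution (ties are not
#' supported and each group must have at most 10 observations); the normal
#' mode uses the tie-corrected normal approximation with a 0.5 continuity
#' correction.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param mode \code{"normal"} (default) or \code{"exact"}.
#' @return A \code{\link{test_result}}; \code{estimate} holds the difference
#'   of group medians \code{median(x) - median(y)}.
#' @examples
#' wilcoxon_rank_sum(8:14, 1:7)   # complete separation, W = 49
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("normal", "exact")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)

  if (mode == "exact") {
    if (has_ties)
      stop("exact mode does not support ties; use mode = \"normal\"")
    if (n1 > 10 || n2 > 10)
      stop("exact mode limited to 10 observations per group")
    # enumerate all labelings of the pooled ranks
    sel <- utils::combn(n1 + n2, n1)
    u <- colSums(matrix(r[sel], nrow = n1)) - n1 * (n1 + 1) / 2
    lo <- min(W, n1 * n2 - W)
    hi <- max(W, n1 * n2 - W)
    p <- (sum(u <= lo) + sum(u >= hi)) / ncol(sel)
    p <- min(1, p)
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      cc <- sign(W - mu) * 0.5
      z <- (W - mu - cc) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  test_result(statistic = W, p_value = p,
              method = sprintf("Wilcoxon rank-sum (%s)", mode),
              estimate = stats::median(x) - stats::median(y))
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up adjustment or Bonferroni correction,
#' implemented directly.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method \code{"bh"} (default) or \code{"bonferroni"}.
#' @return Adjusted p-values in the input order, capped at 1.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (method == "bonferroni") return(pmin(1, m * p))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Rank-based inverse normal transform
#'
#' Maps the value with average rank r (ties receive the average rank) to
#' \code{qnorm((r - 0.5) / n)}.  The transform is monotone in the input and
#' produces approximately standard-normal scores.
#'
#' @param values Numeric vector, length >= 2, not constant.
#' @return Transformed vector in the input order.
#' @export
inverse_normal_transform <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (length(unique(values)) == 1L)
    stop("constant input: inverse normal transform is undefined")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 0.5) / length(values))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional (Levene) test on the heterozygote count given the
#' allele counts.  The two-sided p-value sums the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that
#' of the observed count.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return A \code{\link{test_result}}; the statistic is the observed
#'   heterozygote count.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  cnt <- c(n_AA, n_Aa, n_aa)
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("genotype counts must be non-negative integers")
  n <- sum(cnt)
  if (n == 0) stop("total genotype count must be positive")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  n_minor <- min(nA, na)
  # possible heterozygote counts share the parity of the minor allele count
  het <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(nAa = h | nA, na) = log[ n! / (nAA! nAa! naa!) * 2^h / C(2n, nA) ]
  logp <- lfactorial(n) - lfactorial((nA - het) / 2) - lfactorial(het) -
    lfactorial((na - het) / 2) + het * log(2) -
    (lfactorial(2 * n) - lfactorial(nA) - lfactorial(na))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, het)]
  p <- min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  test_result(statistic = n_Aa, p_value = p,
              method = "Hardy-Weinberg exact test")
}

#' Beta-binomial log-likelihood
#'
#' Sum over count records of
#' \code{log[ C(n, k) B(k + alpha, n - k + beta) / B(alpha, beta) ]}.
#' Records with \code{n = 0} contribute zero.
#'
#' @param alpha,beta Positive shape parameters.
#' @param k Successes (reference-allele reads) per record.
#' @param n Trials (total reads) per record.
#' @return The log-likelihood (a single number).
#' @export
betabinom_loglik <- function(alpha, beta, k, n) {
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0)
    stop("alpha and beta must be positive and finite")
  if (length(k) != length(n)) stop("k and n must have equal length")
  if (any(k < 0) || any(n < 0) || any(k > n)) stop("need 0 <= k <= n")
  sum(lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta))
}

#' Fit the beta-binomial null by maximum likelihood
#'
#' Maximizes \code{\link{betabinom_loglik}} over \code{(log alpha, log beta)}
#' starting from a method-of-moments estimate.  Parameters are capped at
#' 1e6 (at the cap the distribution is numerically binomial with
#' p = alpha / (alpha + beta)).
#'
#' @param k,n Count records as in \code{\link{betabinom_loglik}}; records
#'   with \code{n = 0} are dropped.  At least 10 informative records are
#'   required.
#' @return An object of class \code{"betabinom_null"}: a list with
#'   \code{alpha}, \code{beta}, \code{log_likelihood}, \code{n_snps_used}
#'   and \code{gradient_norm} (norm of the numeric log-scale gradient at
#'   the optimum).
#' @examples
#' set.seed(1)
#' p <- rbeta(200, 20, 20)
#' k <- rbinom(200, 40, p)
#' fit_betabinom(k, rep(40, 200))
#' @export
fit_betabinom <- function(k, n) {
  keep <- n > 0
  k <- k[keep]; n <- n[keep]
  if (length(n) < 10) stop("need at least 10 informative (n > 0) records")
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n")
  cap <- 1e6

  # method-of-moments start on the per-record ratios
  ph <- k / n
  m <- mean(ph); v <- stats::var(ph)
  nu <- if (is.finite(v) && v > 0) m * (1 - m) / v - 1 else 100
  if (!is.finite(nu) || nu <= 0) nu <- 100
  start <- log(pmin(cap, pmax(1e-3, c(m, 1 - m) * nu)))

  negll <- function(par) {
    ab <- pmin(exp(par), cap)
    -betabinom_loglik(ab[1], ab[2], k, n)
  }
  fit <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  # polish with Nelder-Mead if BFGS stalled
  fit2 <- stats::optim(fit$par, negll,
                       control = list(maxit = 2000, reltol = 1e-14))
  if (fit2$value < fit$value) fit <- fit2
  ab <- pmin(exp(fit$par), cap)

  eps <- 1e-6
  g <- vapply(1:2, function(i) {
    e <- c(0, 0); e[i] <- eps
    (negll(fit$par + e) - negll(fit$par - e)) / (2 * eps)
  }, numeric(1))

  structure(
    list(alpha = ab[1], beta = ab[2], log_likelihood = -fit$value,
         n_snps_used = length(n), gradient_norm = sqrt(sum(g^2)),
         at_cap = any(ab >= cap)),
    class = "betabinom_null")
}

#' @export
print.betabinom_null <- function(x, ...) {
  cat("Beta-binomial null model\n")
  cat(sprintf("  alpha = %.4g, beta = %.4g  (mean ratio %.4f)\n",
              x$alpha, x$beta, x$alpha / (x$alpha + x$beta)))
  cat(sprintf("  log-likelihood %.3f over %d SNPs\n",
              x$log_likelihood, x$n_snps_used))
  if (isTRUE(x$at_cap)) cat("  note: estimate at the parameter cap\n")
  invisible(x)
}

#' @export
coef.betabinom_null <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' @export
logLik.betabinom_null <- function(object, ...) {
  structure(object$log_likelihood, df = 2L, class = "logLik")
}

#' Two-sided beta-binomial test
#'
#' Tests an observed count \code{k} of \code{n} against a fitted
#' beta-binomial null.  The two-sided p-value sums \code{pmf(j | n)} over
#' all outcomes j whose probability does not exceed \code{pmf(k | n)}
#' (minimum-likelihood rule, mirroring \code{\link{fisher_exact_2x2}}).
#'
#' @param k Observed successes, \code{0 <= k <= n}.
#' @param n Total trials, \code{n >= 1}.
#' @param null A \code{"betabinom_null"} object (or any list with
#'   \code{alpha} and \code{beta}).
#' @return A \code{\link{test_result}} with the observed ratio \code{k/n}
#'   as estimate.
#' @export
betabinom_test <- function(k, n, null) {
  if (!is.finite(k) || !is.finite(n) || n < 1 || k < 0 || k > n ||
      k != round(k) || n != round(n))
    stop("need integer counts with 0 <= k <= n and n >= 1")
  j <- 0:n
  logpmf <- lchoose(n, j) + lbeta(j + null$alpha, n - j + null$beta) -
    lbeta(null$alpha, null$beta)
  pmf <- exp(logpmf)
  p <- min(1, sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-9)]))
  test_result(statistic = k, p_value = p,
              method = "beta-binomial test (two-sided)", estimate = k / n)
}
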