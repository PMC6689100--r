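# Statistical primitives: exact tests, multiple-testing adjustment and
# the inverse normal transform, each checked against an independent
# oracle (base-R implementations or direct enumeration).

test_that("Fisher exact test reproduces known two-sided p-values", {
  # worked example: 8/9 imbalanced SNPs in QTLs vs 35/180 without
  r <- fisher_exact_2x2(8, 1, 35, 145)
  expect_lt(abs(r$p_value - 3.1e-5) / 3.1e-5, 0.05)
  expect_equal(r$estimate, 8 * 145 / 35, tolerance = 1e-12)

  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_value, 1.0)
  # margins (3,3)/(3,3): only tables k=0 and k=3 are as unlikely -> 2/20
  expect_equal(fisher_exact_2x2(3, 0, 0, 3)$p_value, 0.1, tolerance = 1e-12)

  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher exact test matches fisher.test over random tables", {
  set.seed(101)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 8), 2)
    if (sum(tab) == 0) next
    ours <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- stats::fisher.test(tab)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Wilcoxon rank-sum statistic and p-values behave as specified", {
  # complete separation of two groups of 7: W = n1 * n2
  r <- wilcoxon_rank_sum(8:14, 1:7)
  expect_equal(r$statistic, 49)

  r <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3), mode = "normal")
  expect_equal(r$statistic, 4.5)
  expect_equal(r$p_value, 1)

  # exact: only U = 4 and U = 0 are as extreme among C(4,2) labelings
  r <- wilcoxon_rank_sum(c(3, 4), c(1, 2), mode = "exact")
  expect_equal(r$statistic, 4)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)

  expect_error(wilcoxon_rank_sum(c(1, 1), c(1, 2), mode = "exact"), "ties")
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("Wilcoxon agrees with wilcox.test in both modes", {
  set.seed(7)
  for (i in 1:50) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1))
    ours <- wilcoxon_rank_sum(x, y, mode = "exact")
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
    # normal approximation with ties induced by rounding
    xr <- round(rnorm(15), 1); yr <- round(rnorm(12), 1)
    ours_n <- wilcoxon_rank_sum(xr, yr, mode = "normal")
    ref_n <- stats::wilcox.test(xr, yr, exact = FALSE, correct = TRUE)
    expect_equal(ours_n$p_value, ref_n$p.value, tolerance = 1e-9)
  }
})

test_that("exact Wilcoxon permutation p-values are valid and exhaustive", {
  # over all labelings of 8 distinct values into 4 + 4, the fraction with
  # p <= alpha never exceeds alpha (exactness of the permutation test)
  vals <- c(0.3, 1.2, 2.8, 3.1, 4.9, 5.2, 6.6, 7.4)
  sel <- utils::combn(8, 4)
  ps <- apply(sel, 2, function(ix) {
    wilcoxon_rank_sum(vals[ix], vals[-ix], mode = "exact")$p_value
  })
  for (alpha in c(0.05, 0.1, 0.2, 0.5))
    expect_lte(sum(ps <= alpha), alpha * ncol(sel) + 1)
})

test_that("p-value adjustment matches p.adjust and worked examples", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  bh <- adjust_pvalues(p, "bh")
  expect_equal(bh, stats::p.adjust(p, "BH"))
  expect_equal(sum(bh < 0.05), 3)

  expect_equal(adjust_pvalues(rep(1, 5), "bh"), rep(1, 5))
  expect_equal(adjust_pvalues(0.002, "bonferroni"), 0.002)
  expect_equal(adjust_pvalues(c(0.002, 0.5, 0.9), "bonferroni"),
               stats::p.adjust(c(0.002, 0.5, 0.9), "bonferroni"))
  set.seed(5)
  pr <- runif(200)
  expect_equal(adjust_pvalues(pr, "bh"), stats::p.adjust(pr, "BH"))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH controls the empirical false discovery rate on null data", {
  set.seed(17)
  q <- 0.1
  fdp <- replicate(10000, {
    p <- runif(20)
    r <- sum(adjust_pvalues(p, "bh") < q)
    if (r == 0) 0 else 1   # all null: any discovery is false
  })
  expect_lte(mean(fdp), q + 0.01)
})

test_that("inverse normal transform maps ranks to normal scores", {
  out <- inverse_normal_transform(c(10, 20, 30))
  expect_equal(out, stats::qnorm(c(1, 3, 5) / 6), tolerance = 1e-12)
  expect_equal(sum(inverse_normal_transform(c(5, 1, 9, 2, 7))), 0,
               tolerance = 1e-12)
  # monotone permutation invariance: same multiset of outputs
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(sort(inverse_normal_transform(x)),
               sort(inverse_normal_transform(sort(x))))
  expect_error(inverse_normal_transform(rep(2, 4)), "constant")
  expect_error(inverse_normal_transform(1), "at least 2")
})

test_that("Hardy-Weinberg exact test follows the Levene distribution", {
  # (2,0,2): P(nAa = 0) = 6/70, the only outcome at most as likely
  expect_equal(hwe_exact_test(2, 0, 2)$p_value, 6 / 70, tolerance = 1e-12)
  # (1,2,1): modal outcome, every outcome included
  expect_equal(hwe_exact_test(1, 2, 1)$p_value, 1.0)
  expect_equal(hwe_exact_test(10, 0, 0)$p_value, 1.0)  # monomorphic
  expect_error(hwe_exact_test(-1, 2, 1), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), "positive")
})

test_that("beta-binomial log-likelihood has the closed Beta-function form", {
  expect_equal(betabinom_loglik(1, 1, 1, 2), log(1 / 3), tolerance = 1e-12)
  expect_equal(exp(betabinom_loglik(2, 2, 1, 2)), 0.4, tolerance = 1e-12)
  # n = 0 records contribute nothing
  expect_equal(betabinom_loglik(3, 4, c(2, 0), c(5, 0)),
               betabinom_loglik(3, 4, 2, 5))
  # matches the integral representation
  expect_equal(exp(betabinom_loglik(5.5, 2.2, 7, 20)),
               bb_pmf_integrate(7, 20, 5.5, 2.2), tolerance = 1e-9)
  expect_error(betabinom_loglik(1, 1, 5, 3), "k <= n")
  expect_error(betabinom_loglik(-1, 1, 1, 2), "positive")
})

test_that("beta-binomial MLE agrees with a log-grid search on a toy set", {
  set.seed(23)
  n <- rep(40L, 50)
  k <- rbetabinom_oracle(50, n, 8, 12)
  fit <- fit_betabinom(k, n)
  # 200 x 200 grid over log alpha, log beta
  la <- seq(log(0.5), log(200), length.out = 200)
  ll <- outer(la, la, Vectorize(function(x, y) {
    betabinom_loglik(exp(x), exp(y), k, n)
  }))
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  cell <- diff(la)[1]
  expect_lt(abs(log(fit$alpha) - la[best[1]]), cell * 1.5)
  expect_lt(abs(log(fit$beta) - la[best[2]]), cell * 1.5)
  expect_lt(fit$gradient_norm, 1e-4)
})

test_that("beta-binomial MLE recovers the generating parameters", {
  set.seed(31)
  n <- rpois(5000, 40)
  k <- rbetabinom_oracle(5000, n, 20.5, 20.3)
  fit <- fit_betabinom(k, n)
  expect_lt(abs(fit$alpha - 20.5) / 20.5, 0.15)
  expect_lt(abs(fit$beta - 20.3) / 20.3, 0.15)
  expect_error(fit_betabinom(c(1, 2), c(4, 4)), "at least 10")
})

test_that("degenerate all-0/all-n ratios drive the MLE to the boundary", {
  n <- rep(20L, 30)
  k <- rep(c(0L, 20L), 15)
  fit <- fit_betabinom(k, n)
  expect_true(fit$at_cap || fit$alpha < 1e-2 || fit$beta < 1e-2)
})

test_that("beta-binomial test applies the minimum-likelihood rule", {
  null <- list(alpha = 20.5, beta = 20.3)
  # modal count -> every outcome is at most as likely -> p = 1
  mode_k <- which.max(exp(vapply(0:40, function(j)
    betabinom_loglik(20.5, 20.3, j, 40), numeric(1)))) - 1L
  expect_equal(betabinom_test(mode_k, 40, null)$p_value, 1)
  # uniform pmf: alpha = beta = 1
  expect_equal(betabinom_test(3, 10, list(alpha = 1, beta = 1))$p_value, 1)
  expect_error(betabinom_test(11, 10, null), "0 <= k <= n")

  # exhaustive-enumeration oracle via numeric integration
  pmf <- bb_pmf_integrate(0:100, 100, 20, 20)
  p_oracle <- sum(pmf[pmf <= pmf[91] * (1 + 1e-9)])
  expect_equal(betabinom_test(90, 100, list(alpha = 20, beta = 20))$p_value,
               p_oracle, tolerance = 1e-10)
})

test_that("beta-binomial test converges to the exact binomial test", {
  null <- list(alpha = 1e5, beta = 1e5)
  for (k in c(0, 5, 12, 15, 22, 30)) {
    pmf <- dbinom(0:30, 30, 0.5)
    p_binom <- sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-9)])
    expect_lt(abs(betabinom_test(k, 30, null)$p_value - p_binom), 0.01)
  }
})
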