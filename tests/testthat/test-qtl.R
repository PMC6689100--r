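# QTL scan machinery: subgroup-presence eligibility, PCA residualization,
# the per-pair linear test against the closed form, TAD-restricted
# candidate genes and cross-layer direction concordance.

mk_fm <- function(values, layer = "accessibility", presence = NULL,
                  features = NULL) {
  if (is.null(presence)) presence <- matrix(TRUE, nrow(values), ncol(values),
                                            dimnames = dimnames(values))
  if (is.null(features))
    features <- data.frame(feature_id = colnames(values),
                           start = seq_len(ncol(values)) * 100L,
                           end = seq_len(ncol(values)) * 100L + 50L)
  structure(list(layer = layer, values = values, features = features,
                 presence = presence), class = "feature_matrix")
}

test_that("eligibility needs both the fraction and the minimum count", {
  n <- 30
  G <- matrix(c(rep(0L, 10), rep(1L, 10), rep(2L, 10)), ncol = 1,
              dimnames = list(sprintf("S%02d", 1:n), "rs1"))
  v <- matrix(rnorm(n * 2), n, dimnames = list(rownames(G), c("f1", "f2")))
  pres <- matrix(FALSE, n, 2, dimnames = dimnames(v))
  pres[1, "f1"] <- TRUE                 # 1 of 10 in one subgroup: fails
  pres[11:12, "f2"] <- TRUE             # 2 of 10 heterozygotes: passes
  fm <- mk_fm(v, presence = pres)
  expect_equal(feature_eligibility(fm, G, "rs1"), "f2")
  expect_error(feature_eligibility(fm, G, "rs9"), "missing")

  # expression: strict > 4.5 on values
  ve <- matrix(4.5, n, 1, dimnames = list(rownames(G), "g1"))
  expect_length(feature_eligibility(mk_fm(ve, layer = "expression"),
                                    G, "rs1"), 0)
  ve[1:3, 1] <- 4.500001
  expect_equal(feature_eligibility(mk_fm(ve, layer = "expression"),
                                   G, "rs1"), "g1")
})

test_that("residualization removes exactly the top components", {
  set.seed(61)
  M <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(NULL, letters[1:8]))
  expect_identical(residualize(M, 0), M)

  # rank-1 structure vanishes at k = 1
  u <- rnorm(50); v <- rnorm(8)
  R1 <- u %*% t(v) + matrix(rnorm(400, sd = 1e-8), 50)
  expect_lt(max(abs(residualize(R1, 1))), 1e-4)

  # residuals orthogonal to the removed components
  X <- scale(M)
  sv <- svd(X, nu = 3)
  res <- residualize(M, 3)
  expect_lt(max(abs(t(res) %*% sv$u[, 1:3])), 1e-8)

  expect_error(residualize(M, 8), "rank")
})

test_that("single-pair test equals lm and reacts to duplication as expected", {
  set.seed(62)
  for (i in 1:20) {
    x <- sample(0:2, 30, replace = TRUE)
    y <- 0.5 * x + rnorm(30)
    r <- qtl_test(y, x)
    ref <- summary(lm(y ~ x))$coefficients
    expect_equal(r$beta, ref[2, 1], tolerance = 1e-10)
    expect_equal(r$t_statistic, ref[2, 3], tolerance = 1e-10)
    expect_equal(r$p_value, ref[2, 4], tolerance = 1e-10)
  }
  x <- sample(0:2, 30, replace = TRUE)
  y <- inverse_normal_transform(x + rnorm(30, sd = 1e-6))
  expect_lt(qtl_test(y, x)$p_value, 1e-6)

  # duplicated dataset: same slope, smaller p
  y <- 0.4 * x + rnorm(30)
  r1 <- qtl_test(y, x)
  r2 <- qtl_test(rep(y, 2), rep(x, 2))
  expect_equal(r2$beta, r1$beta, tolerance = 1e-12)
  expect_lt(r2$p_value, r1$p_value)

  # missing dosages are dropped pairwise
  x[1:3] <- NA
  expect_equal(qtl_test(y, x)$n_used, 27)

  expect_error(qtl_test(rnorm(10), rep(1, 10)), "zero dosage variance")
  expect_error(qtl_test(rnorm(2), c(0, 1)), "at least 3")
})

test_that("TAD candidate genes use half-open interval intersection", {
  tads <- data.frame(tad = c("T1", "T2"), start = c(0L, 1000L),
                     end = c(1000L, 2000L))
  genes <- data.frame(gene = c("A", "B", "C", "D"),
                      start = c(100L, 500L, 1000L, 1500L),
                      end = c(200L, 900L, 1100L, 1600L))
  locus_in_t1 <- list(sentinel = "rs1", start = 300L, end = 400L)
  expect_setequal(tad_candidate_genes(locus_in_t1, tads, genes),
                  c("A", "B"))   # C lies in [1000, 1100), entirely in T2
  # spanning both TADs: union of gene sets
  locus_span <- list(sentinel = "rs2", start = 900L, end = 1100L)
  expect_setequal(tad_candidate_genes(locus_span, tads, genes),
                  c("A", "B", "C", "D"))
  # gene abutting the TAD boundary exactly is excluded
  genes2 <- data.frame(gene = "E", start = 1000L, end = 1100L)
  locus_t1 <- list(sentinel = "rs3", start = 10L, end = 20L)
  expect_length(tad_candidate_genes(locus_t1, tads[1, ], genes2), 0)
  expect_warning(
    out <- tad_candidate_genes(list(sentinel = "rs4", start = 5000L,
                                    end = 5100L), tads, genes),
    "no TAD")
  expect_length(out, 0)
})

test_that("layer scan recovers planted QTLs on the small fixture", {
  b <- cached_small_bundle()
  loci <- cached_small_loci()
  q <- run_layer_scan(b$layers$accessibility, loci, b$genotypes, b$tads,
                      k_factors = b$config$n_latent_factors)
  truth <- b$truth$qtl[b$truth$qtl$layer == "accessibility", ]
  found <- paste(q$sentinel, q$feature)[q$significant]
  expect_true(all(paste(truth$sentinel, truth$feature) %in% found))
  expect_true(all(q$fdr >= q$p_value))

  # invariance to feature and sample ordering
  fm <- b$layers$accessibility
  perm_f <- sample(ncol(fm$values))
  perm_s <- sample(nrow(fm$values))
  fm2 <- mk_fm(fm$values[perm_s, perm_f],
               presence = fm$presence[perm_s, perm_f],
               features = fm$features[perm_f, ])
  q2 <- run_layer_scan(fm2, loci, b$genotypes, b$tads,
                       k_factors = b$config$n_latent_factors)
  m <- merge(q, q2, by = c("sentinel", "feature"))
  expect_equal(nrow(m), nrow(q))
  expect_equal(m$p_value.x, m$p_value.y, tolerance = 1e-9)

  # determinism
  q3 <- run_layer_scan(b$layers$accessibility, loci, b$genotypes, b$tads,
                       k_factors = b$config$n_latent_factors)
  expect_identical(q, q3)
})

test_that("direction concordance applies the sign rules", {
  feats <- list(
    accessibility = data.frame(feature_id = "pA", start = 0L, end = 100L),
    h3k27ac = data.frame(feature_id = "pH", start = 50L, end = 150L),
    methylation = data.frame(feature_id = "pM", start = 0L, end = 80L))
  res <- function(layer, feature, beta) {
    data.frame(sentinel = "rs1", feature = feature, layer = layer,
               beta = beta, t_statistic = 3, p_value = 0.001,
               n_used = 40L, fdr = 0.01, significant = TRUE,
               stringsAsFactors = FALSE)
  }
  r <- direction_concordance(
    list(accessibility = res("accessibility", "pA", 1),
         h3k27ac = res("h3k27ac", "pH", 0.8),
         methylation = res("methylation", "pM", -0.5)), feats)
  expect_equal(nrow(r), 3)
  expect_true(all(r$concordant))

  # flipped methylation: its pairs discordant
  r2 <- direction_concordance(
    list(accessibility = res("accessibility", "pA", 1),
         h3k27ac = res("h3k27ac", "pH", 0.8),
         methylation = res("methylation", "pM", +0.5)), feats)
  expect_false(any(r2$concordant[r2$layer_a == "methylation"]))

  # no overlap: empty table
  feats$h3k27ac$start <- 500L; feats$h3k27ac$end <- 600L
  feats$methylation$start <- 700L; feats$methylation$end <- 800L
  r3 <- direction_concordance(
    list(accessibility = res("accessibility", "pA", 1),
         h3k27ac = res("h3k27ac", "pH", 0.8)), feats)
  expect_equal(nrow(r3), 0)
})

test_that("planted cross-layer fixture is fully sign-concordant", {
  b <- cached_small_bundle()
  loci <- cached_small_loci()
  k <- b$config$n_latent_factors
  res <- lapply(b$layers[c("accessibility", "h3k27ac", "methylation")],
                function(fm) run_layer_scan(fm, loci, b$genotypes,
                                            b$tads, k_factors = k))
  conc <- direction_concordance(
    res, lapply(b$layers, `[[`, "features"))
  # only consider pairs where both members are planted truths
  truth_feats <- b$truth$qtl$feature
  planted <- conc[conc$feature_a %in% truth_feats &
                    conc$feature_b %in% truth_feats, ]
  expect_gt(nrow(planted), 0)
  expect_true(all(planted$concordant))
})
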