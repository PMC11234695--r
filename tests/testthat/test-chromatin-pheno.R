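test_that("depth normalisation divides by relative depth factors", {
  # worked example: t = (6, 12), f = (2/3, 4/3)
  cm <- matrix(c(2, 4, 4, 8), 2, byrow = TRUE,
               dimnames = list(c("p1", "p2"), c("s1", "s2")))
  dn <- depth_normalize(cm)
  expect_equal(unname(dn$depth$f), c(2 / 3, 4 / 3))
  expect_equal(unname(dn$normalized), rbind(c(3, 3), c(6, 6)))
  # per-sample totals all equal mean(t) afterwards
  set.seed(4)
  cm2 <- matrix(rpois(200, 30), 20,
                dimnames = list(paste0("p", 1:20), paste0("s", 1:10)))
  dn2 <- depth_normalize(cm2)
  expect_lt(diff(range(colSums(dn2$normalized))), 1e-9)
  # equal totals leave counts untouched
  cm3 <- matrix(5, 4, 3, dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
  expect_equal(depth_normalize(cm3)$normalized, cm3)
  cm4 <- cm3; cm4[, 2] <- 0
  expect_error(depth_normalize(cm4), "s2")
})

test_that("peak filters match a two-pass brute-force oracle", {
  make_ps <- function(len) peak_set(data.frame(
    name = names(len), chrom = "22",
    start = seq_along(len) * 10000,
    end = seq_along(len) * 10000 + len - 1), assay = "ATAC")

  # identical peaks: nothing strictly below an all-equal percentile, none 5x
  cm <- matrix(10, 8, 4, dimnames = list(paste0("p", 1:8), paste0("s", 1:4)))
  ps <- make_ps(setNames(rep(100, 8), paste0("p", 1:8)))
  expect_equal(filter_peaks(cm, cm, ps), paste0("p", 1:8))

  # planted input pile-up is removed by the input rule alone
  set.seed(21)
  n <- 200
  len <- setNames(sample(300:900, n, TRUE), paste0("p", 1:n))
  cm <- matrix(rpois(n * 6, 50), n, dimnames = list(names(len), paste0("s", 1:6)))
  icm <- matrix(rpois(n * 6, 30), n, dimnames = list(names(len), paste0("s", 1:6)))
  icm["p77", ] <- icm["p77", ] * 20
  kept <- filter_peaks(cm, icm, make_ps(len))
  expect_false("p77" %in% kept)
  dropped_by_input <- setdiff(rownames(cm), kept)
  # the low-count rule removes ~1% as well; p77 must be among removals
  expect_lte(length(dropped_by_input), 1 + ceiling(0.02 * n))

  # randomized instances against an independent re-implementation
  set.seed(22)
  for (rep in 1:1000) {
    k <- sample(5:15, 1)
    len <- setNames(sample(50:500, k, TRUE), paste0("q", 1:k))
    cm <- matrix(rpois(k * 3, 40), k, dimnames = list(names(len), paste0("s", 1:3)))
    icm <- matrix(rpois(k * 3, sample(c(5, 30), 1)), k,
                  dimnames = list(names(len), paste0("s", 1:3)))
    kept <- filter_peaks(cm, icm, make_ps(len))
    adj <- rowSums(cm) / len
    adj_in <- rowSums(icm) / len
    oracle <- names(len)[!(adj < quantile(adj, 0.01) |
                             adj_in > 5 * mean(adj_in))]
    if (!identical(kept, oracle)) break
  }
  expect_identical(kept, oracle)
  expect_equal(rep, 1000L)
})

test_that("residual phenotypes agree with per-peak least squares", {
  set.seed(8)
  cN <- matrix(rlnorm(50 * 30, 4, 0.5), 50,
               dimnames = list(paste0("p", 1:50), paste0("s", 1:30)))
  iN <- matrix(rlnorm(50 * 30, 3, 0.5), 50, dimnames = dimnames(cN))
  ph <- residual_phenotype(cN, iN)
  for (i in c(1, 17, 50)) {
    fit <- lm(log(cN[i, ] + 1) ~ log(iN[i, ] + 1))
    expect_equal(unname(ph$residuals[i, ]), unname(residuals(fit)),
                 tolerance = 1e-10)
    expect_equal(unname(ph$slope[i]), unname(coef(fit)[2]), tolerance = 1e-10)
  }
  expect_true(all(abs(rowMeans(ph$residuals)) < 1e-9))

  # y exactly linear in x: residuals vanish
  iN2 <- iN[1:3, ]
  cN2 <- exp(2 + 0.5 * log(iN2 + 1)) - 1
  expect_lt(max(abs(residual_phenotype(cN2, iN2)$residuals)), 1e-10)

  # constant input: intercept-only fallback = centred log counts
  iN3 <- matrix(5, 3, 30, dimnames = list(rownames(iN2), colnames(iN)))
  ph3 <- residual_phenotype(cN[1:3, ], iN3)
  expect_equal(ph3$residuals,
               log(cN[1:3, ] + 1) - rowMeans(log(cN[1:3, ] + 1)))
  expect_setequal(ph3$flagged, rownames(cN)[1:3])

  # consensus input: single column broadcast behaves the same way
  ph4 <- residual_phenotype(cN[1:3, ], matrix(5, 3, 1))
  expect_equal(ph4$residuals, ph3$residuals)
})

test_that("chromatin phenotype is invariant to per-sample depth rescaling", {
  set.seed(14)
  cm <- matrix(rpois(40 * 8, 60), 40,
               dimnames = list(paste0("p", 1:40), paste0("s", 1:8)))
  icm <- matrix(rpois(40 * 8, 40), 40, dimnames = dimnames(cm))
  base <- residual_phenotype(depth_normalize(cm)$normalized,
                             depth_normalize(icm)$normalized)
  # per-sample factors preserving the mean total depth cancel exactly
  sc_c <- runif(8, 0.4, 2.5)
  sc_c <- sc_c * sum(colSums(cm)) / sum(colSums(cm) * sc_c)
  sc_i <- runif(8, 0.4, 2.5)
  sc_i <- sc_i * sum(colSums(icm)) / sum(colSums(icm) * sc_i)
  scaled <- residual_phenotype(
    depth_normalize(sweep(cm, 2, sc_c, "*"))$normalized,
    depth_normalize(sweep(icm, 2, sc_i, "*"))$normalized)
  expect_lt(max(abs(scaled$residuals - base$residuals)), 1e-8)
  # unconstrained scaling of one sample perturbs only at the 1/count level
  cm2 <- cm; icm2 <- icm
  cm2[, 3] <- cm2[, 3] * 4
  icm2[, 3] <- icm2[, 3] * 4
  scaled2 <- residual_phenotype(depth_normalize(cm2)$normalized,
                                depth_normalize(icm2)$normalized)
  expect_lt(max(abs(scaled2$residuals - base$residuals)), 0.02)
})

test_that("PCA outlier detection flags planted outliers only", {
  set.seed(33)
  m <- matrix(rnorm(30 * 50), 30, dimnames = list(paste0("s", 1:30), NULL))
  expect_length(pca_outliers(m, n_pcs = 7, sd_threshold = 4), 0)
  # displace one sample far along the top-variance direction
  dir <- svd(scale(m, scale = FALSE))$v[, 1]
  m2 <- m
  m2[13, ] <- m[13, ] + 40 * dir
  expect_identical(pca_outliers(m2, 7, 4), "s13")
  # scaling all features by a constant changes nothing
  expect_identical(pca_outliers(m2 * 3.7, 7, 4), "s13")
  # identical rows: no exclusions
  m3 <- matrix(1, 5, 4, dimnames = list(paste0("s", 1:5), NULL))
  expect_length(pca_outliers(m3, 3, 4), 0)
  expect_error(pca_outliers(m[1:2, ], 2, 4), "at least 3")
})

test_that("expression normalisation uses median-of-ratios size factors", {
  cm <- matrix(7, 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  en <- expression_normalize(cm)
  expect_equal(unname(en$size_factors), rep(1, 4))
  expect_equal(en$normalized, log2(cm + 1))

  set.seed(55)
  counts <- matrix(rnbinom(200 * 10, mu = 80, size = 8), 200,
                   dimnames = list(paste0("g", 1:200), paste0("s", 1:10)))
  counts[counts == 0] <- 1
  doubled <- counts; doubled[, 4] <- doubled[, 4] * 2
  en2 <- expression_normalize(doubled)
  expect_equal(en2$size_factors[["s4"]] /
                 mean(en2$size_factors[-4]), 2, tolerance = 0.1)

  bad <- counts; bad[3, ] <- 0
  expect_error(expression_normalize(bad), "g3")

  # TPM: equal rates give equal column sums of 1e6
  en3 <- expression_normalize(counts,
                              gene_lengths = setNames(rep(500, 200),
                                                      rownames(counts)))
  expect_equal(unname(colSums(en3$tpm)), rep(1e6, 10))
})

test_that("expression normalisation agrees with the DESeq size-factor oracle", {
  skip_if_no("DESeq2")
  set.seed(66)
  counts <- matrix(rnbinom(300 * 8, mu = 60, size = 5) + 1, 300,
                   dimnames = list(paste0("g", 1:300), paste0("s", 1:8)))
  sf <- expression_normalize(counts)$size_factors
  sf_ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(sf), unname(sf_ref), tolerance = 1e-8)
})

test_that("normalisation reduces the skew of simulated expression", {
  cfg <- sim_config(seed = 19, n_animals = 200, n_variants = 200,
                    ld_block_size = 10, core_haplotype_size = 6, n_peaks = 20)
  sim <- simulate_genotypes(cfg)
  cas <- simulate_molecular_cascade(sim$genotypes, sim$truth, cfg)
  raw <- cas$expression["target_gene", ]
  norm <- expression_normalize(cas$expression)$normalized["target_gene", ]
  expect_lt(abs(sample_skewness(norm)), abs(sample_skewness(raw)))
})
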