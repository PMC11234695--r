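test_that("GRM matches a two-loop brute-force computation", {
  set.seed(3)
  dos <- sapply(runif(100, 0.1, 0.9), function(p) rbinom(20, 2, p))
  g <- make_genotypes(dos)
  grm <- compute_grm(g)
  p <- colMeans(dos) / 2
  z <- sweep(sweep(dos, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  oracle <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20)
    oracle[i, j] <- sum(z[i, ] * z[j, ]) / ncol(z)
  expect_equal(unname(grm$matrix), oracle, tolerance = 1e-12)
  expect_lt(max(abs(grm$matrix - t(grm$matrix))), 1e-10)
})

test_that("identical samples share identical relationships", {
  set.seed(4)
  dos <- sapply(runif(50, 0.2, 0.8), function(p) rbinom(6, 2, p))
  dos[2, ] <- dos[1, ]
  grm <- compute_grm(make_genotypes(dos))
  expect_equal(grm$matrix[1, 2], grm$matrix[1, 1])
  expect_equal(grm$matrix[1, 2], grm$matrix[2, 2])
})

test_that("region exclusion equals recomputation from the complement", {
  set.seed(5)
  dos <- sapply(runif(60, 0.1, 0.9), function(p) rbinom(30, 2, p))
  g <- make_genotypes(dos, chrom = rep(c("1", "2"), each = 30),
                      pos = rep(seq_len(30) * 100L, 2))
  loco <- compute_grm(g, exclude = "2")
  manual <- compute_grm(subset_genotypes(g, variants = g$variants$chrom == "1"))
  expect_equal(loco$matrix, manual$matrix)
  expect_identical(attr(mlma(rnorm(30), g, loco), "grm_mode"), "loco")
  loso <- compute_grm(g, exclude = "1:100-1500")
  manual2 <- compute_grm(subset_genotypes(
    g, variants = !(g$variants$chrom == "1" & g$variants$pos <= 1500)))
  expect_equal(loso$matrix, manual2$matrix)
  # missing dosages are mean-imputed at the point of use
  dos_na <- dos; dos_na[1, 3] <- NA
  expect_silent(compute_grm(make_genotypes(dos_na)))
})

test_that("REML detects absent and present genetic variance", {
  set.seed(6)
  n <- 300
  dos <- sapply(runif(800, 0.1, 0.9), function(p) rbinom(n, 2, p))
  g <- make_genotypes(dos)
  grm <- compute_grm(g)
  # null: no genetic signal
  vc0 <- reml_variance_components(rnorm(n), grm)
  expect_lt(vc0$h2, 0.25)
  expect_gt(vc0$lrt_p, 0.001)
  # strong signal generated through the GRM
  p <- colMeans(dos) / 2
  z <- sweep(sweep(dos, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  a <- drop(z %*% rnorm(800)) / sqrt(800)
  y <- a * sqrt(0.5 / var(a)) + rnorm(n, 0, sqrt(0.5))
  vc1 <- reml_variance_components(y, grm)
  expect_equal(vc1$h2, 0.5, tolerance = 0.15)
  expect_lt(vc1$lrt_p, 1e-3)
  expect_lt(vc1$lrt_p, vc0$lrt_p)
  # scale invariance of h2
  vc2 <- reml_variance_components(3 * y, grm)
  expect_equal(vc2$h2, vc1$h2, tolerance = 1e-4)
  expect_equal(vc2$sigma2_g, 9 * vc1$sigma2_g, tolerance = 1e-3)
  expect_error(reml_variance_components(rep(1, n), grm), "variance")
})

test_that("MLMA collapses to ordinary least squares when V is spherical", {
  set.seed(7)
  n <- 80
  dos <- sapply(runif(40, 0.2, 0.8), function(p) rbinom(n, 2, p))
  g <- make_genotypes(dos)
  eye <- structure(list(matrix = diag(n) * 1.0, n_variants_used = 40L,
                        n_monomorphic = 0L, excluded_region = NULL),
                   class = "Grm")
  dimnames(eye$matrix) <- list(rownames(dos), rownames(dos))
  y <- rnorm(n)
  qs <- mlma(y, g, eye)
  for (j in c(1, 20, 40)) {
    slope <- unname(coef(lm(y ~ dos[, j]))[2])
    expect_equal(qs$beta[j], slope, tolerance = 1e-8)
  }
  # invariances: shifting y; swapping ref/alt (dosage 2 - x)
  qs_shift <- mlma(y + 100, g, eye)
  expect_equal(qs_shift$beta, qs$beta, tolerance = 1e-8)
  expect_equal(qs_shift$p, qs$p, tolerance = 1e-8)
  g_flip <- make_genotypes(2 - dos)
  qs_flip <- mlma(y, g_flip, eye)
  expect_equal(qs_flip$beta, -qs$beta, tolerance = 1e-8)
  expect_equal(qs_flip$p, qs$p, tolerance = 1e-8)
})

test_that("monomorphic variants are flagged, not dropped", {
  set.seed(8)
  dos <- sapply(runif(10, 0.2, 0.8), function(p) rbinom(50, 2, p))
  dos[, 4] <- 2
  g <- make_genotypes(dos)
  qs <- mlma(rnorm(50), g, compute_grm(g))
  expect_equal(nrow(qs), 10)
  expect_identical(qs$status[4], "monomorphic")
  expect_true(is.na(qs$beta[4]))
  # Wald relation holds for tested variants
  ok <- qs$status == "ok"
  expect_equal(qs$p[ok], 2 * pnorm(-abs(qs$beta[ok] / qs$se[ok])),
               tolerance = 1e-12)
})

test_that("conditioning absorbs the signal of linked variants", {
  cfg <- sim_config(seed = 31, n_animals = 400, n_variants = 500,
                    ld_block_size = 25, core_haplotype_size = 8)
  sim <- simulate_genotypes(cfg)
  g <- sim$genotypes; tr <- sim$truth
  cas <- simulate_molecular_cascade(g, tr, cfg)
  grm <- compute_grm(g, exclude = tr$focal_window)
  y <- prepare_log_phenotypes(cas$protein)$peak
  ids <- intersect(rownames(g$dosage), names(y))
  gk <- subset_genotypes(g, samples = ids)
  grmk <- structure(list(matrix = grm$matrix[ids, ids],
                         n_variants_used = grm$n_variants_used,
                         n_monomorphic = 0L, excluded_region = NULL),
                    class = "Grm")
  yv <- unname(y[ids])
  causal <- tr$causal_variant_ids[1]
  base <- mlma(yv, gk, grmk)

  cond <- conditional_scan(yv, gk, grmk, condition_on = causal)
  expect_identical(cond$status[cond$id == causal], "conditioned")
  core <- cond[cond$id %in% setdiff(tr$core_haplotype_ids, causal), ]
  # perfect-LD copies are collinear with the covariate; any testable
  # remainder must be non-significant
  expect_true(all(core$status %in% c("collinear", "ok")))
  expect_true(all(core$p[core$status == "ok"] > 1e-3, na.rm = TRUE))

  # conditioning on an unlinked variant barely moves the top signal
  far <- g$variants$id[10]
  expect_lt(ld_r2(g, far, causal), 0.05)
  cond2 <- conditional_scan(yv, gk, grmk, condition_on = far)
  lp0 <- -log10(base$p[base$id == causal])
  lp1 <- -log10(cond2$p[cond2$id == causal])
  expect_lt(abs(lp1 - lp0) / lp0, 0.1)

  expect_error(conditional_scan(yv, gk, grmk, condition_on = "nope"),
               "unknown conditioning variant")
})

test_that("Bonferroni thresholds reproduce conventional reporting", {
  expect_equal(attr(bonferroni_threshold(0.05, 631896), "signif2"), 7.9e-8)
  expect_equal(as.numeric(bonferroni_threshold(0.05, 1)), 0.05)
  expect_equal(attr(bonferroni_threshold(0.05, 1e6), "signif2"), 5.0e-8)
})
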