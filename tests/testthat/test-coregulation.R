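test_that("QTL correlations behave under identity, negation and harmonisation", {
  set.seed(9)
  ids <- sprintf("v%03d", 1:50)
  a <- make_summary(ids, rnorm(50), runif(50), "a")
  self <- qtl_correlation(a, a)
  expect_equal(self$pearson_beta, 1)
  expect_equal(self$spearman_beta, 1)
  expect_equal(self$pearson_logp, 1)
  expect_equal(self$spearman_logp, 1)
  expect_equal(self$n_shared_variants, 50)

  b <- a; b$beta <- -b$beta
  neg <- qtl_correlation(a, b)
  expect_equal(neg$pearson_beta, -1)
  expect_equal(neg$pearson_logp, 1)

  # swapped ref/alt alleles are re-oriented (beta sign flipped back)
  c_ <- a
  c_$ref <- "G"; c_$alt <- "A"
  c_$beta <- -c_$beta
  expect_equal(qtl_correlation(a, c_)$pearson_beta, 1)

  expect_error(qtl_correlation(a[1:2, ], a[1:2, ]), "shared variants")
})

test_that("correlations match an independent rank-then-correlate oracle", {
  set.seed(10)
  ids <- sprintf("v%03d", 1:80)
  a <- make_summary(ids, rnorm(80), runif(80), "a")
  b <- make_summary(ids, 0.6 * a$beta + rnorm(80, 0, 0.5), runif(80), "b")
  res <- qtl_correlation(a, b)
  pearson <- function(x, y)
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$pearson_beta, pearson(a$beta, b$beta), tolerance = 1e-12)
  expect_equal(res$spearman_beta, pearson(rank(a$beta), rank(b$beta)),
               tolerance = 1e-12)
  expect_equal(res$pearson_logp, pearson(-log10(a$p), -log10(b$p)),
               tolerance = 1e-12)
  # window restriction really restricts
  res2 <- qtl_correlation(a, b, window = "22:100-2000")
  expect_equal(res2$n_shared_variants, 20)
})

test_that("pseudo-R2 equals the leading-eigenvalue fraction", {
  set.seed(11)
  ids <- sprintf("v%03d", 1:60)
  # rank-1: three identical vectors
  beta <- rnorm(60)
  ss <- lapply(c("a", "b", "c"), function(n)
    make_summary(ids, beta, runif(60), n))
  expect_equal(pseudo_r2(ss)$beta, 1)

  # exactly uncorrelated vectors (orthogonal and orthogonal to the
  # constant, hence centred): 1/3 in correlation mode
  q <- qr.Q(qr(cbind(1, matrix(rnorm(60 * 3), 60))))[, 2:4]
  so <- lapply(1:3, function(j)
    make_summary(ids, q[, j], runif(60), paste0("o", j)))
  expect_equal(pseudo_r2(so)$beta, 1 / 3, tolerance = 1e-12)

  # random data vs an independent eigen computation
  M <- sapply(1:3, function(j) rnorm(60))
  M[, 2] <- M[, 1] * 0.7 + M[, 2] * 0.3
  sr <- lapply(1:3, function(j)
    make_summary(ids, M[, j], runif(60), paste0("r", j)))
  got <- pseudo_r2(sr)
  ev <- eigen(cor(M))$values
  expect_equal(got$beta, ev[1] / sum(ev), tolerance = 1e-10)
  evc <- eigen(cov(M))$values
  expect_equal(pseudo_r2(sr, mode = "covariance")$beta,
               evc[1] / sum(evc), tolerance = 1e-10)

  # a pair degenerates to (1 + |r|) / 2: check consistency with the
  # correlation module on a pseudo-triplet built from two distinct vectors
  r <- qtl_correlation(sr[[1]], sr[[2]])$pearson_beta
  pair_cor <- cor(cbind(M[, 1], M[, 2]))
  evp <- eigen(pair_cor)$values
  expect_equal(evp[1] / sum(evp), (1 + abs(r)) / 2, tolerance = 1e-10)

  szero <- sr
  szero[[2]]$beta <- 1
  expect_error(pseudo_r2(szero), "zero-variance")
})

test_that("core haplotype is the intersection of per-layer top fractions", {
  ids <- sprintf("v%03d", 1:100)
  beta <- seq(1, 0.01, length.out = 100)
  p <- seq(1e-10, 0.9, length.out = 100)
  s1 <- make_summary(ids, beta, p, "s1")
  s2 <- make_summary(ids, beta * 2, p, "s2")
  ch <- core_haplotype(list(s1, s2), q = 0.05)
  expect_identical(ch$variant_ids, ids[1:5])
  expect_equal(ch$top_n, 5)

  # reversed ranking: empty intersection
  s3 <- make_summary(ids, rev(beta), p, "s3")
  expect_length(core_haplotype(list(s1, s3), q = 0.05)$variant_ids, 0)

  # q = 1 returns the whole universe; size non-decreasing in q
  expect_setequal(core_haplotype(list(s1, s3), q = 1)$variant_ids, ids)
  sizes <- vapply(c(0.05, 0.2, 0.5, 1), function(q)
    length(core_haplotype(list(s1, s3), q = q)$variant_ids), numeric(1))
  expect_true(all(diff(sizes) >= 0))

  # ties broken by smaller p then id
  tied <- make_summary(ids, rep(1, 100), p, "tied")
  ch2 <- core_haplotype(list(tied, tied), q = 0.05)
  expect_identical(ch2$variant_ids, ids[1:5])

  expect_error(core_haplotype(list(s1, s2), q = 0.05, universe = character(0)),
               "empty")
})

test_that("LD R2 is symmetric in sign and near zero for independent variants", {
  set.seed(12)
  x <- rbinom(200, 2, 0.4)
  dos <- cbind(x, x, 2 - x, rbinom(200, 2, 0.4), rep(1, 200))
  g <- make_genotypes(dos)
  expect_equal(ld_r2(g, "v001", "v002"), 1)
  expect_equal(ld_r2(g, "v001", "v003"), 1)   # perfect repulsion
  expect_lt(ld_r2(g, "v001", "v004"), 0.1)
  expect_error(ld_r2(g, "v001", "v005"), "monomorphic")

  r2 <- replicate(500, {
    d <- cbind(rbinom(700, 2, 0.5), rbinom(700, 2, 0.5))
    cor(d[, 1], d[, 2])^2
  })
  expect_gt(mean(r2 < 0.01), 0.9)
})

test_that("variant-peak containment matches a quadratic scan", {
  set.seed(13)
  n_pk <- 60
  starts <- sample(1:100000, n_pk)
  ps <- peak_set(data.frame(name = paste0("pk", 1:n_pk), chrom = "22",
                            start = starts, end = starts + sample(50:2000, n_pk)),
                 assay = "ATAC")
  vars <- data.frame(id = paste0("v", 1:2000), chrom = "22",
                     pos = sample(1:102000, 2000))
  got <- variant_peak_overlap(vars, ps)
  for (i in sample(2000, 200)) {
    inside <- ps$name[vars$pos[i] >= ps$start & vars$pos[i] <= ps$end]
    want <- if (length(inside) == 0) character(0) else paste0("ATAC:", inside)
    expect_setequal(got[[vars$id[i]]], want)
  }
  # boundary inclusivity
  ps1 <- peak_set(data.frame(name = "pk", chrom = "22", start = 500,
                             end = 600), assay = "H3K4Me1")
  vb <- data.frame(id = c("at_start", "at_end", "past_end"), chrom = "22",
                   pos = c(500, 600, 601))
  ov <- variant_peak_overlap(vb, ps1)
  expect_identical(ov$at_start, "H3K4Me1:pk")
  expect_identical(ov$at_end, "H3K4Me1:pk")
  expect_length(ov$past_end, 0)
})

test_that("variant-density percentile ranks against the genome distribution", {
  # equal density everywhere: no window strictly lower
  expect_equal(variant_density_percentile(
    positions = seq(1, 1000, by = 10), focus_window = "22:1-1000",
    genome_window_counts = rep(100, 50), window_size = 1000), 0)
  # denser than every genome window
  expect_equal(variant_density_percentile(
    positions = 1:500, focus_window = "22:1-500",
    genome_window_counts = rep(10, 50), window_size = 1000), 100)
  # empty focus window: density zero, percentile still defined
  expect_equal(variant_density_percentile(
    positions = numeric(0), focus_window = "22:1-500",
    genome_window_counts = c(0, 5, 10), window_size = 1000),
    0)
  # uniform positions land mid-distribution most of the time
  set.seed(14)
  mid <- replicate(100, {
    pos <- sort(sample(1:1e6, 5000))
    counts <- tabulate(ceiling(pos / 1e4), nbins = 100)
    variant_density_percentile(pos, "22:400001-410000", counts, 1e4)
  })
  expect_gt(mean(mid >= 5 & mid <= 95), 0.9)
})
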