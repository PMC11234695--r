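test_that("VCF round trip preserves dosages, ids and DR2", {
  set.seed(101)
  dos <- matrix(sample(0:2, 60, replace = TRUE), 10)
  g <- make_genotypes(dos, dr2 = round(runif(6, 0.91, 1), 3))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, f)
  g2 <- read_vcf(f)
  expect_equal(unname(g2$dosage), unname(g$dosage))
  expect_equal(g2$variants$id, g$variants$id)
  expect_equal(g2$variants$dr2, g$variants$dr2)
  expect_equal(g2$variants$maf, g$variants$maf)
  # and a second write/read is a fixed point
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g2, f2)
  expect_equal(read_vcf(f2)$dosage, g2$dosage)
})

test_that("GT and DS fields convert to dosage as defined", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"d\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("22", "101", "va", "A", "G", ".", "PASS", ".", "GT",
          "0/1", "1|1", sep = "\t"),
    paste("22", "105", "vb", "C", "T", ".", "PASS", ".", "GT:DS",
          "0/1:1.7", "./.:.", sep = "\t"),
    paste("22", "110", "vc", "G", "A", ".", "PASS", ".", "GT",
          "./.", "0/0", sep = "\t")), f)
  g <- read_vcf(f)
  expect_equal(unname(g$dosage[, "va"]), c(1, 2))     # GT heterozygote = 1
  expect_equal(unname(g$dosage[, "vb"]), c(1.7, NA))  # DS passthrough wins
  expect_equal(unname(g$dosage[, "vc"]), c(NA, 0))    # missing call -> NA
  # region with no variants: empty matrix, not an error
  empty <- read_vcf(f, region = "22:900-999")
  expect_equal(ncol(empty$dosage), 0L)
  expect_equal(nrow(empty$dosage), 2L)
  # region subsetting keeps coordinates 1-based inclusive
  sub <- read_vcf(f, region = "22:105-110")
  expect_equal(sub$variants$id, c("vb", "vc"))
})

test_that("BED-family coordinates convert to 1-based inclusive and back", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("22\t100\t200\tpk1\t13\t.", f)
  ps <- read_peaks(f, dialect = "bed", assay = "ATAC")
  expect_equal(ps$start, 101)
  expect_equal(ps$end, 200)
  expect_equal(peak_lengths(ps)[["pk1"]], 100)

  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("22\t100\t200\tpk1\t50\t.\t3.5\t2.1\t1.8\t40",
               "22\t300\t450\tpk2\t60\t.\t4.5\t3.1\t2.8\t10"), np)
  ps2 <- read_peaks(np, dialect = "narrowPeak", assay = "H3K4Me3")
  expect_equal(ps2$signal_value, c(3.5, 4.5))
  expect_equal(ps2$q_value, c(1.8, 2.8))
  expect_identical(attr(ps2, "assay"), "H3K4Me3")

  # write/read round trip preserves all fields
  out <- withr::local_tempfile(fileext = ".narrowPeak")
  write_peaks(ps2, out, dialect = "narrowPeak")
  ps3 <- read_peaks(out, dialect = "narrowPeak", assay = "H3K4Me3")
  expect_equal(as.data.frame(ps3), as.data.frame(ps2))

  # unnamed BED records get autogenerated names
  f4 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("22\t0\t10", "22\t20\t25"), f4)
  ps4 <- read_peaks(f4, dialect = "bed", assay = "H3K27ac")
  expect_equal(ps4$name, c("H3K27ac-1", "H3K27ac-2"))
})

test_that("variant filtering applies strict MAF and DR2 thresholds", {
  # boundary: maf exactly at the threshold is removed
  dos <- cbind(rep(c(0, 1), c(199, 1)),            # maf = 1/400 = 0.0025
               rep(c(0, 1), c(198, 2)),            # maf = 0.005 exactly
               rep(c(0, 1), c(100, 100)))          # maf = 0.25
  g <- make_genotypes(dos)
  kept <- filter_variants(g, maf_min = 0.005, dr2_min = 0.9)
  expect_equal(kept$variants$id, "v003")

  # absent DR2 never filters
  g2 <- make_genotypes(matrix(rep(c(0, 1, 2), 4), 3))
  expect_equal(ncol(filter_variants(g2)$dosage), 4L)

  # brute-force oracle over simulated variants, and order invariance
  set.seed(7)
  m <- 100
  p <- runif(m, 0.001, 0.5)
  dos <- sapply(p, function(pp) rbinom(400, 2, pp))
  dr2 <- round(runif(m, 0.85, 1), 3)
  g3 <- make_genotypes(dos, dr2 = dr2)
  kept3 <- filter_variants(g3)$variants$id
  oracle <- character(0)
  for (j in seq_len(m)) {
    maf <- min(mean(dos[, j]) / 2, 1 - mean(dos[, j]) / 2)
    if (maf > 0.005 && dr2[j] > 0.9)
      oracle <- c(oracle, g3$variants$id[j])
  }
  expect_identical(kept3, oracle)
  perm <- sample(m)
  g4 <- genotype_matrix(g3$dosage[, perm], g3$variants[perm, ])
  expect_setequal(filter_variants(g4)$variants$id, oracle)
})

test_that("JASPAR PFM parsing and round trip", {
  f <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M1 TFA",
               "A [ 1 1 1 1 ]", "C [ 1 1 1 1 ]",
               "G [ 1 1 1 1 ]", "T [ 1 1 1 1 ]",
               ">M2 TFB",
               "A [ 10 0 ]", "C [ 0 10 ]", "G [ 0 0 ]", "T [ 0 0 ]"), f)
  pfms <- read_jaspar_pfm(f)
  expect_length(pfms, 2)
  expect_equal(ncol(pfms[[1]]$counts), 4)
  expect_equal(pfms[[2]]$tf_name, "TFB")
  out <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar_pfm(pfms, out)
  expect_equal(read_jaspar_pfm(out), pfms)

  bad <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M3 TFC", "A [ 1 2 ]", "C [ 1 ]", "G [ 1 2 ]", "T [ 1 2 ]"),
             bad)
  expect_error(read_jaspar_pfm(bad), "unequal length")
})

test_that("count matrices and QTL summaries survive a TSV round trip", {
  set.seed(5)
  cm <- matrix(rpois(20, 10), 4,
               dimnames = list(paste0("pk", 1:4), paste0("s", 1:5)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cm, f, feature_col = "peak")
  expect_equal(read_counts(f), cm)

  qs <- make_summary(paste0("v", 1:5), rnorm(5), runif(5), "pheno1")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_qtl_summary(qs, f2)
  qs2 <- read_qtl_summary(f2, phenotype = "pheno1")
  expect_equal(qs2$beta, qs$beta)
  expect_equal(qs2$p, qs$p)
})
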