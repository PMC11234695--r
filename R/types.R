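#' coregQTL: multi-layer molecular QTL co-regulation analysis
#'
#' Links protein, expression, histone-modification and chromatin-accessibility
#' QTL at a locus: bespoke phenotype construction, mixed-linear-model
#' association with genomic relationship matrices, QTL correlation and PCA
#' pseudo-R2 statistics, core-haplotype extraction, and allele-aware
#' transcription-factor binding-site scanning. A seeded synthetic-data
#' generator emulates the causal cascade so everything is testable offline.
#'
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# internal helpers

#' Run code with a temporary RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a base seed, staying inside 32-bit integer range.
#' @noRd
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}

#' Parse a "chrom:start-end" string (or pass through a list) into a region.
#' @noRd
parse_region <- function(region) {
  if (is.null(region)) return(NULL)
  if (is.list(region)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(region)))
    return(region)
  }
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) == 4) {
    return(list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4])))
  }
  # bare chromosome name
  list(chrom = region, start = -Inf, end = Inf)
}

#' @noRd
in_region <- function(chrom, pos, region) {
  chrom == region$chrom & pos >= region$start & pos <= region$end
}

# ---------------------------------------------------------------------------
# GenotypeMatrix

#' Construct a genotype matrix of allele dosages
#'
#' Bundles a samples x variants matrix of alt-allele dosages (values in
#' \[0, 2\], `NA` allowed for missing calls) with per-variant metadata.
#' Minor allele frequency is always recomputed from the non-missing dosages,
#' so the stored `maf` column is consistent with the data by construction.
#'
#' @param dosage Numeric matrix, samples in rows, variants in columns.
#'   Row names are sample ids, column names variant ids.
#' @param variants `data.frame` with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, and optionally `dr2` (imputation dosage R2; `NA` when the
#'   source had none). One row per dosage column, same order.
#' @return An object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(dosage, variants) {
  dosage <- as.matrix(dosage)
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)),
            nrow(variants) == ncol(dosage))
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  if (any(variants$pos < 1)) stop("positions must be >= 1 (1-based)")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  if (!"dr2" %in% names(variants)) variants$dr2 <- NA_real_
  colnames(dosage) <- variants$id
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("sample_%03d", seq_len(nrow(dosage)))
  variants$maf <- variant_maf(dosage)
  structure(list(dosage = dosage, variants = variants),
            class = "GenotypeMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Minor allele frequencies from a dosage matrix
#'
#' `min(p, 1 - p)` of the alt-allele frequency, from non-missing dosages.
#' @param dosage samples x variants numeric matrix.
#' @return Numeric vector of MAFs (NaN for all-missing columns).
#' @export
variant_maf <- function(dosage) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d samples x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("  chrom(s): %s\n",
              paste(unique(x$variants$chrom), collapse = ", ")))
  nmiss <- sum(is.na(x$dosage))
  if (nmiss > 0) cat(sprintf("  missing dosages: %d\n", nmiss))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$dosage)

#' Subset a GenotypeMatrix by variant and/or sample
#'
#' @param g `GenotypeMatrix`.
#' @param variants Variant ids or logical/integer index over variants.
#' @param samples Sample ids or index over samples.
#' @return A `GenotypeMatrix`.
#' @export
subset_genotypes <- function(g, variants = NULL, samples = NULL) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  vi <- if (is.null(variants)) seq_len(ncol(g$dosage)) else {
    if (is.character(variants)) match(variants, g$variants$id) else which(
      if (is.logical(variants)) variants else seq_len(ncol(g$dosage)) %in% variants)
  }
  if (anyNA(vi)) stop("unknown variant id(s): ",
                      paste(variants[is.na(vi)], collapse = ", "))
  si <- if (is.null(samples)) seq_len(nrow(g$dosage)) else {
    if (is.character(samples)) match(samples, rownames(g$dosage)) else samples
  }
  genotype_matrix(g$dosage[si, vi, drop = FALSE],
                  g$variants[vi, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# PeakSet

#' Construct a set of named genomic peak intervals
#'
#' Internal coordinates are 1-based inclusive (`start <= end`); conversion
#' from BED-family 0-based half-open files happens in [read_peaks()].
#'
#' @param peaks `data.frame` with columns `name`, `chrom`, `start`, `end`
#'   and optionally `score`, `signal_value`, `q_value`.
#' @param assay One of `"H3K27ac"`, `"H3K4Me1"`, `"H3K4Me3"`, `"ATAC"`.
#' @return A `data.frame` of class `PeakSet` with an `assay` attribute.
#' @export
peak_set <- function(peaks, assay = c("ATAC", "H3K27ac", "H3K4Me1", "H3K4Me3")) {
  assay <- match.arg(assay)
  stopifnot(is.data.frame(peaks),
            all(c("name", "chrom", "start", "end") %in% names(peaks)))
  if (any(peaks$start > peaks$end)) stop("peak start > end")
  if (anyDuplicated(peaks$name)) stop("peak names must be unique")
  for (col in c("score", "signal_value", "q_value"))
    if (!col %in% names(peaks)) peaks[[col]] <- NA_real_
  peaks <- peaks[, c("name", "chrom", "start", "end",
                     "score", "signal_value", "q_value")]
  structure(peaks, assay = assay, class = c("PeakSet", "data.frame"))
}

#' Peak lengths in bases (1-based inclusive intervals)
#' @param peaks A `PeakSet`.
#' @return Named numeric vector of lengths.
#' @export
peak_lengths <- function(peaks) {
  stats::setNames(peaks$end - peaks$start + 1, peaks$name)
}

# ---------------------------------------------------------------------------
# CountMatrix

#' Validate a peaks/genes x samples count matrix
#'
#' @param counts Non-negative matrix; row names are feature (peak/gene)
#'   names, column names sample ids.
#' @return The validated matrix (invisibly classed as used throughout).
#' @export
count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs row (feature) and column (sample) names")
  if (any(counts < 0)) stop("counts must be non-negative")
  counts
}

# ---------------------------------------------------------------------------
# QtlSummary

#' Construct a per-variant QTL summary table
#'
#' The currency exchanged between the association and co-regulation stages:
#' one row per tested variant with effect (`beta`, per alt-allele dose),
#' standard error, Wald p-value, MAF and sample count.
#'
#' @param df `data.frame` with columns `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `maf`, `n`, `beta`, `se`, `p` (and optionally `status`).
#' @param phenotype Phenotype name (metadata).
#' @param covariates Character vector of covariate names (metadata).
#' @param grm_mode `"full"`, `"loco"` or `"loso"` (metadata).
#' @return A `data.frame` of class `QtlSummary`.
#' @export
qtl_summary <- function(df, phenotype = NA_character_,
                        covariates = character(), grm_mode = "full") {
  need <- c("id", "chrom", "pos", "ref", "alt", "maf", "n", "beta", "se", "p")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  if (!"status" %in% names(df)) df$status <- "ok"
  ok <- df$status == "ok"
  if (any(ok & (is.na(df$p) | df$p <= 0 | df$p > 1)))
    stop("p-values of tested variants must lie in (0, 1]")
  structure(df, phenotype = phenotype, covariates = covariates,
            grm_mode = grm_mode, class = c("QtlSummary", "data.frame"))
}

#' @export
print.QtlSummary <- function(x, ...) {
  ok <- x$status == "ok"
  cat(sprintf("QtlSummary '%s': %d variants (%d tested), grm mode %s\n",
              attr(x, "phenotype"), nrow(x), sum(ok), attr(x, "grm_mode")))
  if (any(ok)) {
    top <- x[ok, ][which.min(x$p[ok]), ]
    cat(sprintf("  top variant: %s (%s:%d)  beta=%.3f  p=%.3g\n",
                top$id, top$chrom, top$pos, top$beta, top$p))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Grm

#' @export
print.Grm <- function(x, ...) {
  cat(sprintf("GRM: %d samples, %d variants used", nrow(x$matrix),
              x$n_variants_used))
  if (!is.null(x$excluded_region)) cat("  (region excluded)")
  cat("\n")
  invisible(x)
}
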