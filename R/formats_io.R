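# Readers/writers for external formats. All coordinate conversion from the
# BED family's 0-based half-open convention to the internal 1-based inclusive
# convention happens here, so downstream modules never see file coordinates.

#' Read a VCF into a GenotypeMatrix
#'
#' Dosages come from the `DS` FORMAT field where present, otherwise from `GT`
#' (count of alt alleles; `/` or `|` separated). Missing calls become `NA`.
#' MAF is recomputed from the dosages; imputation `DR2` is taken from the
#' INFO field when present and treated as data (never recomputed).
#'
#' @param path Path to a VCF 4.x file (plain text or gzipped).
#' @param region Optional `"chrom:start-end"` string (or list with `chrom`,
#'   `start`, `end`) restricting the variants returned. A region with no
#'   variants yields an empty matrix, not an error.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  nvar <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  if (nvar == 0) {
    return(genotype_matrix(
      matrix(numeric(0), nrow = length(samples), ncol = 0,
             dimnames = list(samples, NULL)),
      data.frame(id = character(0), chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0), dr2 = numeric(0))))
  }
  id <- fix[, "ID"]
  auto <- is.na(id) | id == "."
  id[auto] <- paste0(fix[auto, "CHROM"], ":", fix[auto, "POS"])
  dr2 <- suppressWarnings(vcfR::extract.info(v, "DR2", as.numeric = TRUE))
  if (is.null(dr2)) dr2 <- rep(NA_real_, nvar)

  ds <- tryCatch(
    suppressWarnings(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)),
    error = function(e) NULL)
  gt <- tryCatch(vcfR::extract.gt(v, element = "GT"), error = function(e) NULL)
  dosage <- matrix(NA_real_, nrow = nvar, ncol = length(samples))
  if (!is.null(ds)) dosage <- ds
  if (!is.null(gt)) {
    from_gt <- gt_to_dosage(gt)
    use <- is.na(dosage) & !is.na(from_gt)   # DS preferred, GT fallback
    dosage[use] <- from_gt[use]
  }
  dosage <- t(dosage)
  rownames(dosage) <- samples

  variants <- data.frame(id = id, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         dr2 = dr2, stringsAsFactors = FALSE)
  g <- genotype_matrix(dosage, variants)
  region <- parse_region(region)
  if (!is.null(region)) {
    keep <- in_region(g$variants$chrom, g$variants$pos, region)
    g <- genotype_matrix(g$dosage[, keep, drop = FALSE],
                         g$variants[keep, , drop = FALSE])
  }
  g
}

#' @noRd
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  lut <- vapply(u, function(s) {
    if (is.na(s)) return(NA_real_)
    a <- strsplit(s, "[/|]")[[1]]
    if (any(a == "." | a == "")) return(NA_real_)
    sum(as.numeric(a) > 0)
  }, numeric(1))
  out <- lut[match(as.vector(gt), u)]
  matrix(out, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Write a GenotypeMatrix as a plain-text VCF 4.2 file
#'
#' Dosages are written in the `DS` field (full precision), with hard calls in
#' `GT` when every dosage is 0/1/2. `DR2` is emitted into INFO when present,
#' so `read_vcf(write_vcf(g))` reproduces `g`.
#'
#' @param g A `GenotypeMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DR2,Number=1,Type=Float,Description=\"Imputation dosage R2\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(g$dosage)), collapse = "\t")), con)
  v <- g$variants
  d <- g$dosage
  hard <- d %in% c(0, 1, 2) | is.na(d)
  info <- ifelse(is.na(v$dr2), ".", sprintf("DR2=%s", format(v$dr2, digits = 6)))
  gt_of <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    dj <- d[, j]
    gt <- ifelse(is.na(dj), "./.",
                 ifelse(dj %in% c(0, 1, 2), gt_of[round(dj) + 1], "./."))
    dss <- ifelse(is.na(dj), ".", format(dj, digits = 15, trim = TRUE,
                                         scientific = FALSE))
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", info[j], "GT:DS",
                       paste(gt, dss, sep = ":")), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read peak intervals (BED, narrowPeak or broadPeak) into a PeakSet
#'
#' File coordinates (0-based half-open) are converted to the internal 1-based
#' inclusive convention. Unnamed peaks get names `"<assay>-<index>"`.
#'
#' @param path Path to the interval file.
#' @param dialect `"narrowPeak"` (10 columns), `"broadPeak"` (9) or `"bed"`
#'   (>= 3 columns).
#' @param assay Assay label, see [peak_set()].
#' @return A `PeakSet`.
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "broadPeak", "bed"),
                       assay = "ATAC") {
  dialect <- match.arg(dialect)
  extra <- switch(dialect,
    narrowPeak = c(signalValue = "numeric", pValue = "numeric",
                   qValue = "numeric", peak = "integer"),
    broadPeak  = c(signalValue = "numeric", pValue = "numeric",
                   qValue = "numeric"),
    bed        = NULL)
  gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
  df <- data.frame(
    name = if (!is.null(gr$name)) as.character(gr$name) else NA_character_,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),   # already 1-based inclusive in GRanges
    end = GenomicRanges::end(gr),
    score = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_,
    signal_value = if (!is.null(gr$signalValue)) gr$signalValue else NA_real_,
    q_value = if (!is.null(gr$qValue)) gr$qValue else NA_real_,
    stringsAsFactors = FALSE)
  fix <- is.na(df$name) | df$name == "."
  df$name[fix] <- paste0(assay, "-", which(fix))
  if (any(df$start > df$end)) stop("malformed interval: start > end")
  peak_set(df, assay = assay)
}

#' Write a PeakSet in BED / narrowPeak / broadPeak layout
#'
#' Internal 1-based inclusive intervals are converted back to the file
#' convention (0-based half-open), making write/read a round trip.
#'
#' @param peaks A `PeakSet`.
#' @param path Output path.
#' @param dialect Output dialect as in [read_peaks()].
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path,
                        dialect = c("narrowPeak", "broadPeak", "bed")) {
  dialect <- match.arg(dialect)
  na0 <- function(x, r = 0) ifelse(is.na(x), r, x)
  out <- data.frame(chrom = peaks$chrom, start = peaks$start - 1,
                    end = peaks$end, name = peaks$name,
                    score = na0(peaks$score), strand = ".")
  if (dialect != "bed") {
    out$signalValue <- na0(peaks$signal_value)
    out$pValue <- -1
    out$qValue <- na0(peaks$q_value, -1)
    if (dialect == "narrowPeak") out$peak <- -1
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter variants on MAF and imputation quality
#'
#' Keeps variants with `maf > maf_min` and (`dr2` absent or `dr2 > dr2_min`);
#' both inequalities strict, matching the convention of keeping variants that
#' exceed the stated thresholds.
#'
#' @param g `GenotypeMatrix`.
#' @param maf_min Minimum (exclusive) minor allele frequency; default 0.005.
#' @param dr2_min Minimum (exclusive) dosage R2; default 0.9.
#' @return Filtered `GenotypeMatrix`.
#' @export
filter_variants <- function(g, maf_min = 0.005, dr2_min = 0.9) {
  stopifnot(inherits(g, "GenotypeMatrix"),
            maf_min >= 0, maf_min <= 1, dr2_min >= 0, dr2_min <= 1)
  maf <- g$variants$maf
  dr2 <- g$variants$dr2
  keep <- !is.na(maf) & maf > maf_min & (is.na(dr2) | dr2 > dr2_min)
  genotype_matrix(g$dosage[, keep, drop = FALSE],
                  g$variants[keep, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# count matrices / phenotype tables / QTL summaries as TSV

#' Read a feature x sample count matrix from TSV
#'
#' First column holds feature (peak/gene) names; the header row holds sample
#' ids.
#' @param path TSV path.
#' @return A numeric matrix (features x samples).
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  count_matrix(m)
}

#' Read a feature x sample numeric matrix from TSV
#'
#' Like [read_counts()] but without the non-negativity constraint; used for
#' phenotype matrices such as chromatin residuals.
#' @param path TSV path.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' Write a count matrix as TSV (first column feature name)
#' @param counts Matrix with dimnames.
#' @param path Output path.
#' @param feature_col Name of the first column in the file.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, feature_col = "feature") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE)
  names(df)[1] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a QTL summary TSV (id, chrom, pos, ref, alt, maf, n, beta, se, p)
#' @param path TSV path.
#' @param phenotype Optional phenotype name to attach.
#' @return A `QtlSummary`.
#' @export
read_qtl_summary <- function(path, phenotype = NA_character_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$chrom <- as.character(df$chrom)
  qtl_summary(df, phenotype = phenotype)
}

#' Write a QTL summary as TSV
#' @param qs A `QtlSummary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qtl_summary <- function(qs, path) {
  utils::write.table(as.data.frame(qs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a GRM as a plain TSV (sample ids in first row/column)
#' @param grm A `Grm` from [compute_grm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grm_tsv <- function(grm, path) {
  df <- data.frame(sample = rownames(grm$matrix), grm$matrix,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# JASPAR PFM text format

#' Read position frequency matrices in JASPAR text format
#'
#' Parses the JASPAR 2016+ format: a `>ID NAME` header followed by four
#' bracketed count rows (`A [ ... ]`, `C`, `G`, `T`).
#'
#' @param path Path to a JASPAR `.pfm`/`.jaspar` text file.
#' @return List of PFMs; each a list with `tf_id`, `tf_name` and `counts`
#'   (4 x width numeric matrix, rows A/C/G/T).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no '>' record headers found in ", path)
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1)
  for (k in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[k]])
    toks <- strsplit(trimws(hdr), "\\s+")[[1]]
    body <- lines[(heads[k] + 1):(bounds[k + 1] - 1)]
    if (length(body) != 4)
      stop("record ", toks[1], ": expected 4 count rows, got ", length(body))
    rows <- lapply(body, function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    w <- lengths(rows)
    if (length(unique(w)) != 1)
      stop("record ", toks[1], ": count rows of unequal length")
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0)) stop("record ", toks[1], ": negative counts")
    out[[k]] <- list(tf_id = toks[1],
                     tf_name = if (length(toks) > 1) toks[2] else toks[1],
                     counts = counts)
  }
  out
}

#' Write PFMs in JASPAR text format
#' @param pfms List of PFMs as returned by [read_jaspar_pfm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    writeLines(sprintf(">%s %s", p$tf_id, p$tf_name), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' Read DNA sequences from FASTA
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' Write DNA sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
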