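# Chromatin-openness phenotypes from ChIP-seq/ATAC-seq count matrices:
# read-depth normalisation, peak quality filters, per-peak input-residual
# phenotypes, PCA-based sample exclusion, and the expression-normalisation
# surrogate used for the eQTL phenotype.

#' Read-depth normalisation of a count matrix
#'
#' Per-sample totals `t_j = sum_i C[i, j]` give depth factors
#' `f_j = t_j / mean(t)`; the normalised matrix is `C[i, j] / f_j`, so every
#' sample's total equals `mean(t)` afterwards.
#'
#' @param cm Peaks x samples count matrix.
#' @return List with `normalized` (same shape) and `depth` (data.frame
#'   `sample`, `t`, `f`).
#' @export
depth_normalize <- function(cm) {
  cm <- count_matrix(cm)
  t_ <- colSums(cm)
  if (any(t_ == 0))
    stop("sample(s) with zero total reads: ",
         paste(colnames(cm)[t_ == 0], collapse = ", "))
  f <- t_ / mean(t_)
  list(normalized = sweep(cm, 2, f, "/"),
       depth = data.frame(sample = colnames(cm), t = t_, f = f,
                          row.names = NULL))
}

#' Peak quality filters on length-adjusted read counts
#'
#' The length-adjusted count of a peak is its total reads divided by its
#' length in bases. Two removal rules are applied simultaneously to the
#' unfiltered set: (i) peaks whose length-adjusted ChIP/ATAC count falls
#' strictly below the first percentile of all peaks (linear-interpolation
#' quantile), and (ii) peaks whose length-adjusted *input* count exceeds
#' five times the mean across peaks, which flags reference-assembly
#' artefact pile-ups.
#'
#' @param cm Peaks x samples signal count matrix.
#' @param input_cm Matching input count matrix (same peak names; may have a
#'   single consensus-input column).
#' @param peaks `PeakSet` supplying peak lengths.
#' @param low_percentile Percentile for the low-signal rule (default 1).
#' @param input_fold Fold-over-mean threshold for the input rule (default 5).
#' @return Character vector of surviving peak names, in original order.
#' @export
filter_peaks <- function(cm, input_cm, peaks, low_percentile = 1,
                         input_fold = 5) {
  cm <- count_matrix(cm); input_cm <- count_matrix(input_cm)
  len <- peak_lengths(peaks)
  missing <- setdiff(rownames(cm), names(len))
  if (length(missing) > 0)
    stop("peak length unknown for: ", paste(missing, collapse = ", "))
  if (!setequal(rownames(cm), rownames(input_cm)))
    stop("signal and input matrices must share peak names")
  input_cm <- input_cm[rownames(cm), , drop = FALSE]
  len <- len[rownames(cm)]
  adj <- rowSums(cm) / len
  adj_in <- rowSums(input_cm) / len
  cutoff <- stats::quantile(adj, low_percentile / 100, type = 7, names = FALSE)
  drop_low <- adj < cutoff
  drop_input <- adj_in > input_fold * mean(adj_in)
  rownames(cm)[!(drop_low | drop_input)]
}

#' Per-peak input-residual chromatin phenotype
#'
#' For each peak, fits `log(C_N + 1) = a + b * log(I_N + 1) + e` by ordinary
#' least squares across samples (natural logs, depth-normalised counts) and
#' returns the residuals as the phenotype for hQTL/caQTL discovery. A peak
#' whose input has zero variance (including the consensus-input case, where
#' `iN` has a single column broadcast to all samples) falls back to an
#' intercept-only fit, i.e. centred log counts, and is flagged.
#'
#' @param cN Depth-normalised signal matrix (peaks x samples).
#' @param iN Depth-normalised input matrix; either the same shape or a
#'   single column used for every sample.
#' @return A `ChromPhenotype` list: `residuals` (peaks x samples, each row
#'   mean 0), `intercept`, `slope`, `flagged` (names of intercept-only
#'   peaks).
#' @export
residual_phenotype <- function(cN, iN) {
  cN <- as.matrix(cN); iN <- as.matrix(iN)
  if (ncol(iN) == 1 && ncol(cN) > 1)
    iN <- iN[, rep(1, ncol(cN)), drop = FALSE]
  stopifnot(nrow(iN) == nrow(cN), ncol(iN) == ncol(cN))
  if (ncol(cN) < 3) stop("need at least 3 samples")
  y <- log(cN + 1)
  x <- log(iN + 1)
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  sxx <- rowSums(xc^2)
  flagged <- sxx <= .Machine$double.eps * ncol(cN)
  b <- ifelse(flagged, 0, rowSums(xc * yc) / ifelse(flagged, 1, sxx))
  res <- yc - b * xc
  a <- rowMeans(y) - b * rowMeans(x)
  structure(list(residuals = res, intercept = a, slope = b,
                 flagged = rownames(cN)[flagged]),
            class = "ChromPhenotype")
}

#' PCA-based outlier sample detection
#'
#' Single pass: principal-component scores are computed on the centred
#' (unscaled) data and a sample is flagged when its score lies more than
#' `sd_threshold` standard deviations from the mean on any of the first
#' `n_pcs` components. Zero-variance components are ignored.
#'
#' @param m Samples x features numeric matrix (row names are sample ids).
#' @param n_pcs Number of leading components to inspect (default 7, the
#'   convention for chromatin phenotypes; use 6 for expression).
#' @param sd_threshold Exclusion threshold in SD units (default 4).
#' @return Character vector of excluded sample ids (possibly empty).
#' @export
pca_outliers <- function(m, n_pcs = 7, sd_threshold = 4) {
  m <- as.matrix(m)
  if (nrow(m) < 3) stop("need at least 3 samples for PCA outlier detection")
  n_pcs <- min(n_pcs, nrow(m) - 1, ncol(m))
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  sds <- apply(scores, 2, stats::sd)
  out <- rep(FALSE, nrow(m))
  for (j in which(sds > 0))
    out <- out | abs(scores[, j] - mean(scores[, j])) > sd_threshold * sds[j]
  rownames(m)[out] %||% character(0)
}

#' Normalise expression counts (variance-stabilising surrogate)
#'
#' Median-of-ratios size factors (the DESeq convention: per-sample median of
#' count / geometric-mean-reference over genes with all-positive counts),
#' then `log2(count / size_factor + 1)`. This is a documented surrogate for
#' a full variance-stabilising transformation, isolated here so an alternate
#' backend can be swapped in. TPM is also provided when gene lengths are
#' given.
#'
#' @param counts Genes x samples count matrix.
#' @param gene_lengths Optional named vector of gene lengths in bases for
#'   the TPM computation.
#' @return List with `normalized` (log2 scale), `size_factors`, and `tpm`
#'   (or NULL).
#' @export
expression_normalize <- function(counts, gene_lengths = NULL) {
  counts <- count_matrix(counts)
  zero <- rowSums(counts) == 0
  if (any(zero))
    stop("all-zero gene(s) across samples: ",
         paste(rownames(counts)[zero], collapse = ", "))
  allpos <- rowSums(counts == 0) == 0
  if (!any(allpos))
    stop("no gene with positive counts in every sample; cannot form the ",
         "median-of-ratios reference")
  logref <- rowMeans(log(counts[allpos, , drop = FALSE]))
  sf <- apply(counts[allpos, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - logref)))
  norm <- log2(sweep(counts, 2, sf, "/") + 1)
  tpm <- NULL
  if (!is.null(gene_lengths)) {
    len <- gene_lengths[rownames(counts)]
    if (anyNA(len)) stop("gene length missing for some genes")
    rate <- sweep(counts, 1, len / 1e3, "/")
    tpm <- sweep(rate, 2, colSums(rate) / 1e6, "/")
  }
  list(normalized = norm, size_factors = sf, tpm = tpm)
}
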