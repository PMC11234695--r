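# Co-localisation layer: correlations between QTL summary statistics across
# molecular layers, the PCA pseudo-R2, core-haplotype extraction, LD R2,
# variant-peak overlap and variant-density percentiles.

# Inner-join two (or more) summaries on variant id with allele orientation
# harmonised to the first: when ref/alt are swapped relative to the first
# summary, the effect sign is flipped; variants with incompatible alleles or
# NA statistics are dropped.
#' @noRd
align_summaries <- function(summaries, window = NULL) {
  stopifnot(length(summaries) >= 2)
  region <- parse_region(window)
  base <- summaries[[1]]
  ids <- Reduce(intersect, lapply(summaries, function(s) s$id))
  if (!is.null(region)) {
    b <- base[match(ids, base$id), ]
    ids <- ids[in_region(b$chrom, b$pos, region)]
  }
  mats <- lapply(summaries, function(s) s[match(ids, s$id), , drop = FALSE])
  b0 <- mats[[1]]
  keep <- rep(TRUE, length(ids))
  for (k in seq_along(mats)[-1]) {
    same <- mats[[k]]$ref == b0$ref & mats[[k]]$alt == b0$alt
    swap <- mats[[k]]$ref == b0$alt & mats[[k]]$alt == b0$ref
    mats[[k]]$beta[swap] <- -mats[[k]]$beta[swap]
    keep <- keep & (same | swap)
  }
  for (k in seq_along(mats))
    keep <- keep & !is.na(mats[[k]]$beta) & !is.na(mats[[k]]$p)
  lapply(mats, function(m) m[keep, , drop = FALSE])
}

#' Correlate two QTL summaries across shared variants
#'
#' Pearson and Spearman correlations of the allele effects and of the
#' -log10(p) values across variants shared by the two summaries (inner join
#' on variant id, allele orientation harmonised, NA rows dropped). Strong
#' correlations are the signature of shared genetic regulation between the
#' two molecular layers.
#'
#' @param a,b `QtlSummary` objects.
#' @param window Optional `"chrom:start-end"` restriction.
#' @return List of class `CoregResult`: `pair`, `n_shared_variants`,
#'   `pearson_beta`, `spearman_beta`, `pearson_logp`, `spearman_logp`.
#' @export
qtl_correlation <- function(a, b, window = NULL) {
  al <- align_summaries(list(a, b), window)
  n <- nrow(al[[1]])
  if (n < 3)
    stop("only ", n, " shared variants in window; need at least 3")
  lp <- lapply(al, function(m) -log10(m$p))
  structure(list(
    pair = c(attr(a, "phenotype"), attr(b, "phenotype")),
    window = window,
    n_shared_variants = n,
    pearson_beta = stats::cor(al[[1]]$beta, al[[2]]$beta),
    spearman_beta = stats::cor(al[[1]]$beta, al[[2]]$beta, method = "spearman"),
    pearson_logp = stats::cor(lp[[1]], lp[[2]]),
    spearman_logp = stats::cor(lp[[1]], lp[[2]], method = "spearman")),
    class = "CoregResult")
}

#' PCA pseudo-R2 of a QTL triplet
#'
#' Principal-components analysis of the three aligned vectors of allele
#' effects (and of -log10 p): the fraction of total variance carried by the
#' first principal component, `lambda_1 / sum(lambda)`, a three-dimensional
#' analogue of R2. With `mode = "correlation"` (default) the variables are
#' standardised first, so the value lies in \[1/3, 1\].
#'
#' @param summaries List of exactly 3 `QtlSummary` objects.
#' @param window Optional `"chrom:start-end"` restriction.
#' @param mode `"correlation"` (standardised; default) or `"covariance"`.
#' @return List with `beta` and `logp` pseudo-R2 fractions plus
#'   `n_shared_variants`.
#' @export
pseudo_r2 <- function(summaries, window = NULL,
                      mode = c("correlation", "covariance")) {
  mode <- match.arg(mode)
  stopifnot(length(summaries) == 3)
  al <- align_summaries(summaries, window)
  n <- nrow(al[[1]])
  if (n < 4) stop("only ", n, " shared variants; need at least 4")
  pev <- function(M) {
    v <- apply(M, 2, stats::var)
    if (any(v == 0))
      stop("zero-variance column (summary ",
           which(v == 0)[1], ") in pseudo-R2 input")
    C <- if (mode == "correlation") stats::cor(M) else stats::cov(M)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    ev[1] / sum(ev)
  }
  list(beta = pev(sapply(al, function(m) m$beta)),
       logp = pev(sapply(al, function(m) -log10(m$p))),
       n_shared_variants = n, mode = mode)
}

#' Extract the core haplotype shared by several QTL
#'
#' For each summary, ranks variants of the universe by absolute allele
#' effect (ties broken by smaller p, then variant id) and takes the top
#' `ceiling(q * |universe|)`; the core haplotype is the intersection across
#' all summaries — the variant set simultaneously in the top fraction of
#' every molecular layer.
#'
#' @param summaries List of >= 2 `QtlSummary` objects.
#' @param q Top fraction per layer, in (0, 1\]; default 0.05.
#' @param universe Optional character vector of variant ids; defaults to the
#'   variants shared by all summaries (after harmonisation).
#' @return A `CoreHaplotype` list: `variant_ids` (the intersection),
#'   `membership` (universe x summaries logical matrix), `q`, `top_n`,
#'   `universe`.
#' @export
core_haplotype <- function(summaries, q = 0.05, universe = NULL) {
  stopifnot(length(summaries) >= 2, q > 0, q <= 1)
  al <- align_summaries(summaries)
  shared <- al[[1]]$id
  if (is.null(universe)) universe <- shared
  if (length(universe) == 0) stop("empty variant universe")
  if (!all(universe %in% shared))
    stop("universe contains variants absent from some summary: ",
         paste(utils::head(setdiff(universe, shared), 5), collapse = ", "))
  k <- ceiling(q * length(universe))
  membership <- matrix(FALSE, length(universe), length(summaries),
                       dimnames = list(universe, vapply(summaries, function(s)
                         attr(s, "phenotype") %||% NA_character_, character(1))))
  for (j in seq_along(al)) {
    m <- al[[j]][match(universe, al[[j]]$id), ]
    ord <- order(-abs(m$beta), m$p, m$id)
    membership[ord[seq_len(k)], j] <- TRUE
  }
  core <- universe[rowSums(membership) == length(summaries)]
  structure(list(variant_ids = core, membership = membership, q = q,
                 top_n = k, universe = universe),
            class = "CoreHaplotype")
}

#' @export
print.CoreHaplotype <- function(x, ...) {
  cat(sprintf("CoreHaplotype: %d of %d variants in the top %.1f%% of all %d QTL\n",
              length(x$variant_ids), length(x$universe), 100 * x$q,
              ncol(x$membership)))
  invisible(x)
}

#' Pairwise linkage disequilibrium R2
#'
#' Squared Pearson correlation of allele dosages at two variants across the
#' samples non-missing at both.
#'
#' @param g `GenotypeMatrix`.
#' @param v1,v2 Variant ids.
#' @return LD R2 in \[0, 1\].
#' @export
ld_r2 <- function(g, v1, v2) {
  i <- match(c(v1, v2), g$variants$id)
  if (anyNA(i)) stop("unknown variant id(s): ",
                     paste(c(v1, v2)[is.na(i)], collapse = ", "))
  x <- g$dosage[, i[1]]; y <- g$dosage[, i[2]]
  ok <- !is.na(x) & !is.na(y)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("LD undefined: monomorphic variant among ", v1, ", ", v2)
  stats::cor(x[ok], y[ok])^2
}

#' Which peaks contain each variant?
#'
#' Containment on 1-based inclusive intervals (a variant at a peak's start
#' or end coordinate is contained). A variant may hit peaks from several
#' assays.
#'
#' @param variants `data.frame` with `id`, `chrom`, `pos` (e.g. a
#'   `GenotypeMatrix`'s `$variants`).
#' @param peaksets A `PeakSet` or list of `PeakSet`s.
#' @return Named list (by variant id) of character vectors
#'   `"<assay>:<peak name>"`.
#' @export
variant_peak_overlap <- function(variants, peaksets) {
  if (inherits(peaksets, "PeakSet")) peaksets <- list(peaksets)
  pk <- do.call(rbind, lapply(peaksets, function(ps)
    data.frame(label = paste0(attr(ps, "assay"), ":", ps$name),
               chrom = ps$chrom, start = ps$start, end = ps$end)))
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, variants$pos))
  pgr <- GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(pk$start, pk$end))
  ov <- GenomicRanges::findOverlaps(vgr, pgr)
  out <- stats::setNames(vector("list", nrow(variants)), variants$id)
  for (i in seq_along(out)) out[[i]] <- character(0)
  hits <- split(pk$label[S4Vectors::subjectHits(ov)],
                variants$id[S4Vectors::queryHits(ov)])
  out[names(hits)] <- hits
  out
}

#' Variant-density percentile of a focus window
#'
#' Ranks the per-base variant density of a focus window against a
#' genome-wide distribution of per-window variant counts: the percentile is
#' the fraction of genome windows with strictly lower density, times 100.
#' Singleton variants should be excluded by the caller before counting.
#'
#' @param positions Variant positions on the focus chromosome.
#' @param focus_window `"chrom:start-end"` string or list; only variants
#'   inside it are counted (an empty window gives density 0).
#' @param genome_window_counts Integer vector of variant counts in
#'   equal-sized genome-wide windows.
#' @param window_size Size in bases of each genome window.
#' @return Percentile in \[0, 100\].
#' @export
variant_density_percentile <- function(positions, focus_window,
                                       genome_window_counts, window_size) {
  stopifnot(window_size > 0, length(genome_window_counts) > 0)
  region <- parse_region(focus_window)
  width <- region$end - region$start + 1
  focus_density <- sum(positions >= region$start & positions <= region$end) /
    width
  genome_density <- genome_window_counts / window_size
  100 * mean(genome_density < focus_density)
}
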