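# PWM-based transcription-factor binding-site prediction: log-odds matrix
# construction from position frequency matrices, both-strand scanning with
# relative-score thresholding, exact score-distribution (TFM) p-values by
# dynamic programming, and allele-aware disruption scoring at variants.

BASES <- c("A", "C", "G", "T")

#' Convert a position frequency matrix to a log-odds PWM
#'
#' Per cell: `log2((count + pseudocount * background) / (column_total +
#' pseudocount) / background)`, the JASPAR/TFBSTools convention with default
#' pseudocount 0.8 and uniform background.
#'
#' @param pfm A PFM as returned by [read_jaspar_pfm()] (list with `tf_id`,
#'   `tf_name`, `counts`), or a bare 4 x width count matrix (rows A/C/G/T).
#' @param background Background base probabilities (A, C, G, T); must sum
#'   to 1.
#' @param pseudocount Pseudocount mass (default 0.8).
#' @return An object of class `Pwm`: `tf_id`, `tf_name`, `width`, `scores`
#'   (4 x width log2 odds), `background`, `pseudocount`, `min_score`,
#'   `max_score`.
#' @export
pfm_to_pwm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.8) {
  if (is.matrix(pfm)) pfm <- list(tf_id = "PFM", tf_name = "PFM", counts = pfm)
  counts <- pfm$counts
  stopifnot(nrow(counts) == 4, all(counts >= 0),
            abs(sum(background) - 1) < 1e-9)
  if (any(colSums(counts) <= 0)) stop("PFM column with zero total count")
  rownames(counts) <- BASES
  tot <- colSums(counts)
  freq <- sweep(counts + pseudocount * background,
                2, tot + pseudocount, "/")
  scores <- log2(freq / background)
  structure(list(tf_id = pfm$tf_id, tf_name = pfm$tf_name,
                 width = ncol(counts), scores = scores,
                 background = stats::setNames(background, BASES),
                 pseudocount = pseudocount,
                 min_score = sum(apply(scores, 2, min)),
                 max_score = sum(apply(scores, 2, max))),
            class = "Pwm")
}

#' @export
print.Pwm <- function(x, ...) {
  cat(sprintf("Pwm %s (%s): width %d, score range [%.2f, %.2f]\n",
              x$tf_id, x$tf_name, x$width, x$min_score, x$max_score))
  invisible(x)
}

#' @noRd
reverse_complement_pwm <- function(pwm) {
  sc <- pwm$scores[c("T", "G", "C", "A"), rev(seq_len(pwm$width)), drop = FALSE]
  rownames(sc) <- BASES
  pwm2 <- pwm
  pwm2$scores <- sc
  pwm2$background <- pwm$background[c("T", "G", "C", "A")]
  names(pwm2$background) <- BASES
  pwm2
}

#' @noRd
encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], BASES)   # N etc. -> NA
}

# score every offset of an encoded sequence with a PWM; windows containing
# non-ACGT bases give NA
#' @noRd
pwm_window_scores <- function(pwm, enc) {
  W <- pwm$width
  L <- length(enc)
  if (L < W) return(numeric(0))
  nwin <- L - W + 1
  s <- numeric(nwin)
  for (j in seq_len(W)) {
    col <- pwm$scores[, j]
    s <- s + col[enc[j:(j + nwin - 1)]]
  }
  unname(s)
}

#' Scan a sequence for PWM matches on both strands
#'
#' Scores every offset on the forward strand and, via the
#' reverse-complemented matrix, on the reverse strand; windows containing
#' `N` are skipped. The relative score rescales the raw score between the
#' matrix's minimum and maximum attainable scores, and hits at or above
#' `rel_threshold` are returned sorted by start then strand, each annotated
#' with its exact tail probability ([tfm_pvalue()]).
#'
#' @param pwm A `Pwm`.
#' @param seq DNA string over A/C/G/T/N.
#' @param rel_threshold Minimum relative score in \[0, 1\] (default 0.9).
#' @param granularity Discretisation step for the TFM p-value.
#' @return `data.frame` of class `TfbsHit`: `tf_id`, `strand`, `start`,
#'   `end` (1-based, + strand coordinates of the covered window), `score`,
#'   `rel_score`, `tfm_p`.
#' @export
scan_sequence <- function(pwm, seq, rel_threshold = 0.9, granularity = 1e-4) {
  stopifnot(inherits(pwm, "Pwm"), rel_threshold >= 0, rel_threshold <= 1)
  enc <- encode_dna(seq)
  rng <- pwm$max_score - pwm$min_score
  hits <- list()
  for (strand in c("+", "-")) {
    p <- if (strand == "+") pwm else reverse_complement_pwm(pwm)
    s <- pwm_window_scores(p, enc)
    rel <- (s - pwm$min_score) / rng
    keep <- which(!is.na(rel) & rel >= rel_threshold)
    if (length(keep) > 0)
      hits[[strand]] <- data.frame(
        tf_id = pwm$tf_id, strand = strand, start = keep,
        end = keep + pwm$width - 1, score = s[keep], rel_score = rel[keep],
        stringsAsFactors = FALSE)
  }
  out <- if (length(hits) > 0) do.call(rbind, hits) else
    data.frame(tf_id = character(0), strand = character(0),
               start = integer(0), end = integer(0), score = numeric(0),
               rel_score = numeric(0))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$tfm_p <- if (nrow(out) > 0)
    tfm_pvalue(pwm, out$score, granularity = granularity) else numeric(0)
  class(out) <- c("TfbsHit", "data.frame")
  out
}

#' Exact PWM score tail probability (TFM p-value)
#'
#' The probability, under the i.i.d. background base distribution, that a
#' random word of the matrix width scores at least `score`. Computed by
#' dynamic programming over the per-column score distribution after
#' discretising scores to a fixed step of `granularity * (max - min)`
#' (score-distribution convolution across columns). The discretisation
#' makes the reported tail conservative by at most `width * step / 2` in
#' score units: every word with true score >= `score` is counted.
#'
#' @param pwm A `Pwm`.
#' @param score Numeric vector of query scores.
#' @param granularity Relative discretisation step (default 1e-4 of the
#'   score range).
#' @return Tail probabilities in \[0, 1\]; 1 for `score <= min_score`, 0 for
#'   `score > max_score`. Non-increasing in `score`.
#' @export
tfm_pvalue <- function(pwm, score, granularity = 1e-4) {
  stopifnot(inherits(pwm, "Pwm"), granularity > 0)
  rng <- pwm$max_score - pwm$min_score
  step <- if (rng > 0) granularity * rng else granularity
  si <- round(pwm$scores / step)               # 4 x W integer grid
  W <- pwm$width
  # dense DP: distribution of the integer word score, one convolution per
  # column (4 shifted adds), indexed from the running minimum
  cur_lo <- 0
  vec <- 1
  for (j in seq_len(W)) {
    cj <- si[, j]
    new_lo <- cur_lo + min(cj)
    new_hi <- cur_lo + length(vec) - 1 + max(cj)
    nv <- numeric(new_hi - new_lo + 1)
    for (b in 1:4) {
      sh <- cur_lo + cj[b] - new_lo
      idx <- seq_along(vec) + sh
      nv[idx] <- nv[idx] + vec * pwm$background[b]
    }
    vec <- nv; cur_lo <- new_lo
  }
  cum <- rev(cumsum(rev(vec)))                 # tail sums from each int score
  ints <- cur_lo + seq_along(vec) - 1
  vapply(score, function(s) {
    if (s <= pwm$min_score) return(1)
    if (s > pwm$max_score) return(0)
    ti <- ceiling((s - W * step / 2) / step)
    k <- ti - cur_lo + 1
    if (k <= 1) 1 else if (k > length(cum)) 0 else cum[k]
  }, numeric(1))
}

#' Allele-aware TFBS disruption scoring at a variant
#'
#' Scans both the reference and the alternate version of a sequence with a
#' set of PWMs and reports every binding site overlapping the variant
#' position that passes the relative-score and TFM p-value thresholds in
#' either allele, together with per-allele raw scores and their difference
#' (`delta = alt - ref`; negative delta means the alt allele weakens the
#' site).
#'
#' @param pwms A `Pwm` or list of `Pwm`s.
#' @param seq Reference DNA string.
#' @param variant List with `ref`, `alt` (single bases) and `offset`
#'   (1-based position of the variant within `seq`); a `VariantRecord`-style
#'   list with `pos` relative to the sequence works too.
#' @param rel_threshold Relative-score threshold (default 0.9).
#' @param p_threshold TFM p-value threshold (default 1e-5).
#' @param granularity Passed to [tfm_pvalue()].
#' @return `data.frame`: `tf_id`, `strand`, `start`, `end`, `ref_score`,
#'   `alt_score`, `delta`, `rel_score_ref`, `rel_score_alt`, `tfm_p_ref`,
#'   `tfm_p_alt`.
#' @export
allele_aware_sites <- function(pwms, seq, variant, rel_threshold = 0.9,
                               p_threshold = 1e-5, granularity = 1e-4) {
  if (inherits(pwms, "Pwm")) pwms <- list(pwms)
  off <- variant$offset %||% variant$pos
  stopifnot(!is.null(off), off >= 1, off <= nchar(seq),
            nchar(variant$ref) == 1, nchar(variant$alt) == 1)
  have <- toupper(substr(seq, off, off))
  if (have != toupper(variant$ref))
    stop("reference base mismatch at offset ", off, ": sequence has ", have,
         ", variant says ", variant$ref)
  alt_seq <- seq
  substr(alt_seq, off, off) <- toupper(variant$alt)

  rows <- list()
  for (pwm in pwms) {
    h_ref <- scan_sequence(pwm, seq, rel_threshold = 0, granularity = granularity)
    h_alt <- scan_sequence(pwm, alt_seq, rel_threshold = 0, granularity = granularity)
    key <- paste(h_ref$strand, h_ref$start)
    stopifnot(identical(key, paste(h_alt$strand, h_alt$start)))
    over <- h_ref$start <= off & h_ref$end >= off
    pass <- (h_ref$rel_score >= rel_threshold & h_ref$tfm_p <= p_threshold) |
            (h_alt$rel_score >= rel_threshold & h_alt$tfm_p <= p_threshold)
    sel <- which(over & pass)
    if (length(sel) > 0)
      rows[[pwm$tf_id]] <- data.frame(
        tf_id = pwm$tf_id, strand = h_ref$strand[sel],
        start = h_ref$start[sel], end = h_ref$end[sel],
        ref_score = h_ref$score[sel], alt_score = h_alt$score[sel],
        delta = h_alt$score[sel] - h_ref$score[sel],
        rel_score_ref = h_ref$rel_score[sel],
        rel_score_alt = h_alt$rel_score[sel],
        tfm_p_ref = h_ref$tfm_p[sel], tfm_p_alt = h_alt$tfm_p[sel],
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(tf_id = character(0), strand = character(0),
               start = integer(0), end = integer(0), ref_score = numeric(0),
               alt_score = numeric(0), delta = numeric(0),
               rel_score_ref = numeric(0), rel_score_alt = numeric(0),
               tfm_p_ref = numeric(0), tfm_p_alt = numeric(0))
  rownames(out) <- NULL
  out
}
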