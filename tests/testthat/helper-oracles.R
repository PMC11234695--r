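# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles are deliberately naive (loops, enumeration) so they
# cannot share code paths with the implementation they check.

# tiny genotype matrix from an explicit dosage matrix
make_genotypes <- function(dosage, chrom = "22", pos = NULL, dr2 = NA_real_) {
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("s%02d", seq_len(nrow(dosage)))
  genotype_matrix(dosage, data.frame(
    id = sprintf("v%03d", seq_len(m)), chrom = chrom, pos = pos,
    ref = "A", alt = "G", dr2 = dr2, stringsAsFactors = FALSE))
}

# random QTL summary over a fixed variant panel
make_summary <- function(ids, beta, p, phenotype = "x", chrom = "22",
                         pos = NULL, ref = "A", alt = "G") {
  if (is.null(pos)) pos <- seq_along(ids) * 100L
  qtl_summary(data.frame(
    id = ids, chrom = chrom, pos = pos, ref = ref, alt = alt,
    maf = 0.3, n = 100L, beta = beta, se = abs(beta) / 2 + 0.1, p = p,
    stringsAsFactors = FALSE), phenotype = phenotype)
}

# exhaustive PWM tail probability (enumeration over all 4^w words)
enum_tfm_tail <- function(pwm, s) {
  W <- pwm$width
  words <- as.matrix(expand.grid(rep(list(1:4), W)))
  sc <- rowSums(matrix(pwm$scores[cbind(as.vector(words),
                                        rep(1:W, each = nrow(words)))],
                       nrow(words)))
  pr <- apply(matrix(pwm$background[as.vector(words)], nrow(words)), 1, prod)
  sum(pr[sc >= s])
}

# all distinct exact word scores of a PWM (for picking safe query points)
enum_word_scores <- function(pwm) {
  W <- pwm$width
  words <- as.matrix(expand.grid(rep(list(1:4), W)))
  sort(unique(rowSums(matrix(pwm$scores[cbind(as.vector(words),
                                              rep(1:W, each = nrow(words)))],
                             nrow(words)))))
}

random_pwm <- function(width, background = rep(0.25, 4)) {
  counts <- matrix(stats::rpois(4 * width, 15) + 1, 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pfm_to_pwm(counts, background = background)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# random Dirichlet-ish background bounded away from zero
random_background <- function() {
  g <- stats::rgamma(4, 5, 1) + 0.5
  g / sum(g)
}

# per-offset, per-strand PWM scan oracle
brute_scan <- function(pwm, seq, rel_threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(seq, "")[[1]]
  W <- pwm$width
  out <- list()
  for (start in seq_len(nchar(seq) - W + 1)) {
    win <- chars[start:(start + W - 1)]
    if (any(!win %in% names(comp))) next
    for (strand in c("+", "-")) {
      w2 <- if (strand == "+") win else rev(unname(comp[win]))
      s <- sum(vapply(seq_len(W), function(j) pwm$scores[w2[j], j],
                      numeric(1)))
      rel <- (s - pwm$min_score) / (pwm$max_score - pwm$min_score)
      if (rel >= rel_threshold)
        out[[length(out) + 1]] <- data.frame(strand = strand, start = start,
                                             score = s)
    }
  }
  if (length(out) == 0)
    return(data.frame(strand = character(0), start = integer(0),
                      score = numeric(0)))
  df <- do.call(rbind, out)
  df[order(df$start, df$strand), ]
}

skip_if_no <- function(pkg) testthat::skip_if_not_installed(pkg)
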