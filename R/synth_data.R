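# Seeded synthetic-data generator emulating the causal cascade the analysis
# assumes: an F2 cross between two founder pools with LD-blocked genotypes, a
# high-frequency core haplotype of perfectly linked variants, negative-
# binomial chromatin counts with paired input, log-scale expression effects,
# and repeated protein measures over three lactation periods.

#' Simulation configuration
#'
#' Defaults encode the study conditions the package is designed around: an
#' F2 population of 700 animals, a common causal haplotype (MAF 0.45) of 20
#' tightly linked variants, a per-allele protein effect of 0.56 natural-log
#' units, and log-scale polygenic heritability 0.4 with three lactation
#' periods whose means are lowest at peak and highest at mid lactation.
#'
#' @param n_animals Number of F2 animals.
#' @param n_variants Number of variants on the simulated chromosome.
#' @param n_peaks Number of chromatin peaks.
#' @param ld_block_size Variants per LD block (1 gives independent variants).
#' @param core_haplotype_size Number of perfectly linked core variants.
#' @param core_haplotype_r2_min Required pairwise dosage R2 within the core.
#' @param causal_maf Target causal-haplotype frequency, in (0, 0.5].
#' @param founders_per_pool Founder haplotypes per breed pool.
#' @param switch_rate Per-interval probability of switching founder
#'   haplotype along a gamete (recombination analogue).
#' @param founder_autocorr Within-founder probability that a variant copies
#'   its left neighbour's allele (drives LD decay with distance).
#' @param mean_depth_chip,mean_depth_input Mean reads per peak per sample.
#' @param nb_dispersion Negative-binomial size parameter for all counts.
#' @param n_periods Number of protein collection periods (default 3).
#' @param alpha_chromatin Per-allele effect on the log mean count of target
#'   peaks.
#' @param alpha_expression Per-allele effect on log expression of the target
#'   gene.
#' @param alpha_protein Per-allele natural-log effect on protein
#'   concentration (default 0.56).
#' @param h2_protein Polygenic log-scale heritability of protein
#'   concentration, in \[0, 1).
#' @param sigma_total2 Total non-fixed log-scale variance of protein
#'   (additive + permanent environment + residual).
#' @param n_background_genes Background genes for the expression matrix.
#' @param chrom,pos_start,pos_spacing Chromosome label and variant
#'   coordinates.
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(n_animals = 700, n_variants = 2000, n_peaks = 150,
                       ld_block_size = 50, core_haplotype_size = 20,
                       core_haplotype_r2_min = 0.99, causal_maf = 0.45,
                       founders_per_pool = 40, switch_rate = 0.02,
                       founder_autocorr = 0.9,
                       mean_depth_chip = 100, mean_depth_input = 60,
                       nb_dispersion = 10, n_periods = 3,
                       alpha_chromatin = 0.4, alpha_expression = 0.5,
                       alpha_protein = 0.56, h2_protein = 0.4,
                       sigma_total2 = 0.36, n_background_genes = 60,
                       chrom = "1", pos_start = 1000000, pos_spacing = 1000,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_animals > 0, n_variants > 0, n_peaks > 0, ld_block_size > 0,
            core_haplotype_size > 0, causal_maf > 0, causal_maf <= 0.5,
            core_haplotype_r2_min > 0, core_haplotype_r2_min <= 1,
            h2_protein >= 0, h2_protein < 1, n_periods >= 1)
  if (core_haplotype_size > n_variants)
    stop("core_haplotype_size exceeds n_variants")
  structure(cfg, class = "SimConfig")
}

#' Simulate F2 genotypes with an embedded core haplotype
#'
#' Haplotype-pool model: two founder pools ("breeds") with divergent allele
#' frequencies; founder haplotypes are Markov chains along each LD block so
#' adjacent-variant LD decays with distance; each F2 gamete is a founder
#' mosaic with per-interval switch probability `switch_rate`. The core
#' haplotype is engineered as its own LD unit: a carrier indicator (carrier
#' fraction `causal_maf` in each pool) is copied across a span of
#' consecutive variants inside which recombination is suppressed, so the
#' core variants' dosages are identical (pairwise R2 = 1 >= any
#' `core_haplotype_r2_min`) while their LD with flanking variants stays at
#' background level. The middle core variant is designated causal.
#'
#' @param cfg A [sim_config()].
#' @return List with `genotypes` (a `GenotypeMatrix`) and `truth` (a
#'   `SimTruth` list: `causal_variant_ids`, `core_haplotype_ids`,
#'   `focal_window` (the segment around the core that a LOSO design should
#'   exclude from the GRM; the polygenic background is drawn from variants
#'   outside it), `alpha_chromatin`, `alpha_expression`, `alpha_protein`,
#'   `h2_protein`, `seed`).
#' @export
simulate_genotypes <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_seed(child_seed(cfg$seed, 1), {
    m <- cfg$n_variants; n <- cfg$n_animals
    K <- cfg$founders_per_pool
    block <- (seq_len(m) - 1) %/% cfg$ld_block_size

    # divergent pool allele frequencies around a shared ancestral frequency
    p_anc <- stats::runif(m, 0.05, 0.95)
    nu <- 6
    pool_p <- cbind(stats::rbeta(m, nu * p_anc, nu * (1 - p_anc)),
                    stats::rbeta(m, nu * p_anc, nu * (1 - p_anc)))

    # founder haplotypes: Markov chains within blocks (2K x m)
    founders <- matrix(0L, 2 * K, m)
    for (pool in 1:2) {
      rows <- (pool - 1) * K + seq_len(K)
      H <- matrix(0L, K, m)
      H[, 1] <- stats::rbinom(K, 1, pool_p[1, pool])
      for (v in 2:m) {
        fresh <- stats::rbinom(K, 1, pool_p[v, pool])
        if (block[v] == block[v - 1]) {
          copy <- stats::runif(K) < cfg$founder_autocorr
          H[, v] <- ifelse(copy, H[, v - 1], fresh)
        } else H[, v] <- fresh
      }
      founders[rows, ] <- H
    }

    # core haplotype: consecutive span mid-chromosome, carrier indicator
    # copied across the span on every founder
    core_start <- max(1, floor(m / 2) - floor(cfg$core_haplotype_size / 2))
    core_idx <- core_start:(core_start + cfg$core_haplotype_size - 1)
    n_carrier <- max(1, round(K * cfg$causal_maf))
    carrier <- logical(2 * K)
    for (pool in 1:2)
      carrier[(pool - 1) * K + sample.int(K, n_carrier)] <- TRUE
    founders[, core_idx] <- matrix(as.integer(carrier), 2 * K,
                                   length(core_idx))

    # gametes: founder mosaics; no switching inside the core span
    sw_ok <- rep(TRUE, m - 1)
    sw_ok[core_idx[-length(core_idx)]] <- FALSE
    n_gam <- 2 * n
    hap <- matrix(0L, n_gam, m)
    sw <- matrix(stats::runif(n_gam * (m - 1)) < cfg$switch_rate, n_gam)
    sw <- sweep(sw, 2, sw_ok, "&")
    n_seg <- rowSums(sw) + 1
    draws_all <- sample.int(2 * K, sum(n_seg), replace = TRUE)
    ptr <- c(0, cumsum(n_seg))
    fid <- matrix(0L, n_gam, m)
    for (gam in seq_len(n_gam)) {
      seg <- cumsum(c(FALSE, sw[gam, ])) + 1
      fid[gam, ] <- draws_all[ptr[gam] + seg]
    }
    for (v in seq_len(m)) hap[, v] <- founders[fid[, v], v]

    dosage <- hap[seq(1, n_gam, by = 2), ] + hap[seq(2, n_gam, by = 2), ]
    rownames(dosage) <- sprintf("animal_%04d", seq_len(n))

    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")
    variants <- data.frame(
      id = sprintf("v%05d", seq_len(m)), chrom = cfg$chrom,
      pos = cfg$pos_start + (seq_len(m) - 1L) * cfg$pos_spacing,
      ref = ref, alt = alt,
      dr2 = round(stats::runif(m, 0.95, 1), 4), stringsAsFactors = FALSE)
    g <- genotype_matrix(dosage, variants)

    core_pos <- variants$pos[core_idx]
    margin <- 50 * cfg$pos_spacing
    truth <- structure(list(
      causal_variant_ids = variants$id[core_idx[ceiling(length(core_idx) / 2)]],
      core_haplotype_ids = variants$id[core_idx],
      focal_window = sprintf("%s:%d-%d", cfg$chrom,
                             max(1, min(core_pos) - margin),
                             max(core_pos) + margin),
      alpha_chromatin = cfg$alpha_chromatin,
      alpha_expression = cfg$alpha_expression,
      alpha_protein = cfg$alpha_protein,
      h2_protein = cfg$h2_protein, seed = cfg$seed), class = "SimTruth")
    list(genotypes = g, truth = truth)
  })
}

#' Simulate the molecular cascade downstream of the causal variant
#'
#' Generates, deterministically given the seed: a peak annotation with two
#' designated target peaks covering the core haplotype (one ChIP-style with
#' per-sample input, one ATAC-style scored against a single consensus
#' input); negative-binomial ChIP and input count matrices sharing
#' per-sample depth factors, with the genetic effect
#' (`alpha_chromatin` x dosage on the log mean) confined to the target
#' peaks and absent from the input; an expression count matrix whose target
#' gene carries `alpha_expression` x dosage on its log mean; and a
#' repeated-measures protein table
#' `exp(mu_t + alpha_protein * dosage + a_i + pe_i + e_it)` with the
#' GRM-structured polygenic effect `a` scaled to heritability `h2_protein`
#' on the log scale and period means ordered peak < late < mid.
#'
#' @param g `GenotypeMatrix` from [simulate_genotypes()].
#' @param truth Matching `SimTruth`.
#' @param cfg The same [sim_config()].
#' @return List: `chip`, `input` (peak x sample count matrices),
#'   `consensus_input` (single-column matrix), `expression` (gene x sample
#'   counts, target gene `"target_gene"`), `protein` (data.frame
#'   `animal_id`, `period`, `value` in mg/L), `peaks` (a `PeakSet`),
#'   `target_peaks` (named character: `chip`, `atac`), `varcomp_truth`.
#' @export
simulate_molecular_cascade <- function(g, truth, cfg) {
  stopifnot(inherits(g, "GenotypeMatrix"), inherits(truth, "SimTruth"))
  if (!all(truth$causal_variant_ids %in% g$variants$id))
    stop("causal variant(s) absent from genotype matrix")
  with_seed(child_seed(cfg$seed, 2), {
    n <- nrow(g$dosage)
    samples <- rownames(g$dosage)
    d <- g$dosage[, truth$causal_variant_ids[1]]

    # --- peak annotation: random intervals plus two targets on the core
    core_pos <- g$variants$pos[match(truth$core_haplotype_ids, g$variants$id)]
    span <- range(g$variants$pos)
    n_bg <- cfg$n_peaks - 2
    starts <- sort(sample(seq(span[1], span[2] - 2000), n_bg))
    lens <- pmax(200, round(stats::rlnorm(n_bg, log(600), 0.5)))
    peaks <- data.frame(
      name = sprintf("peak_%03d", seq_len(cfg$n_peaks)),
      chrom = cfg$chrom,
      start = c(starts, min(core_pos) - 200, min(core_pos) - 100),
      end = c(starts + lens - 1, max(core_pos) + 200, max(core_pos) + 300),
      score = round(stats::runif(cfg$n_peaks, 20, 2000), 1),
      signal_value = round(stats::runif(cfg$n_peaks, 2, 40), 2),
      q_value = round(stats::runif(cfg$n_peaks, 3, 300), 2))
    target_chip <- peaks$name[cfg$n_peaks - 1]
    target_atac <- peaks$name[cfg$n_peaks]
    ps <- peak_set(peaks, assay = "ATAC")
    len <- peak_lengths(ps)

    # --- chromatin counts: shared depth, peak-length and baseline terms;
    #     genetic effect only on the target peaks, never on the input
    depth_chip <- stats::rlnorm(n, 0, 0.35)
    depth_input <- stats::rlnorm(n, 0, 0.35)
    base_pk <- stats::rlnorm(cfg$n_peaks, 0, 0.4)
    len_term <- len / mean(len)
    eff <- matrix(0, cfg$n_peaks, n)
    tgt <- peaks$name %in% c(target_chip, target_atac)
    eff[tgt, ] <- matrix(truth$alpha_chromatin * d, sum(tgt), n, byrow = TRUE)
    mu_chip <- (cfg$mean_depth_chip * base_pk * len_term) %o% depth_chip *
      exp(eff)
    mu_input <- (cfg$mean_depth_input * len_term) %o% depth_input
    rnb <- function(mu) matrix(
      stats::rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion),
      nrow(mu), dimnames = list(peaks$name, samples))
    chip <- rnb(mu_chip)
    input <- rnb(mu_input)
    consensus_input <- matrix(
      stats::rnbinom(cfg$n_peaks, mu = cfg$mean_depth_input * len_term * n / 10,
                     size = cfg$nb_dispersion),
      dimnames = list(peaks$name, "consensus_input"))

    # --- expression: background genes + one target gene
    ng <- cfg$n_background_genes
    depth_rna <- stats::rlnorm(n, 0, 0.3)
    base_g <- stats::rlnorm(ng, log(200), 1)
    mu_bg <- base_g %o% depth_rna
    mu_tg <- 300 * depth_rna * exp(truth$alpha_expression * d)
    expr <- rbind(
      matrix(stats::rnbinom(length(mu_bg), mu = mu_bg,
                            size = cfg$nb_dispersion), ng),
      stats::rnbinom(n, mu = mu_tg, size = cfg$nb_dispersion))
    dimnames(expr) <- list(c(sprintf("gene_%03d", seq_len(ng)), "target_gene"),
                           samples)

    # --- protein over periods; polygenic effect drawn through the GRM of
    #     the background variants (outside the focal window, whose genetic
    #     contribution is the explicit alpha_protein effect)
    region <- parse_region(truth$focal_window)
    bg <- !in_region(g$variants$chrom, g$variants$pos, region)
    x <- impute_mean(g$dosage[, bg, drop = FALSE])
    p <- colMeans(x) / 2
    poly <- p > 0 & p < 1
    z <- sweep(x[, poly, drop = FALSE], 2, 2 * p[poly], "-")
    z <- sweep(z, 2, sqrt(2 * p[poly] * (1 - p[poly])), "/")
    a_raw <- drop(z %*% stats::rnorm(ncol(z))) / sqrt(ncol(z))
    s2a <- cfg$h2_protein * cfg$sigma_total2
    s2pe <- 0.2 * (1 - cfg$h2_protein) * cfg$sigma_total2
    s2e <- 0.8 * (1 - cfg$h2_protein) * cfg$sigma_total2
    a <- if (s2a > 0) a_raw * sqrt(s2a) / stats::sd(a_raw) else numeric(n)
    pe <- stats::rnorm(n, 0, sqrt(s2pe))
    mu_t <- c(peak = 4.4, mid = 5.2, late = 5.1)[seq_len(cfg$n_periods)]
    periods <- names(mu_t)
    present <- matrix(stats::runif(n * length(periods)) < 0.92, n)
    none <- rowSums(present) == 0
    present[none, 1] <- TRUE
    rows <- which(present, arr.ind = TRUE)
    e <- stats::rnorm(nrow(rows), 0, sqrt(s2e))
    protein <- data.frame(
      animal_id = samples[rows[, 1]],
      period = periods[rows[, 2]],
      value = exp(mu_t[rows[, 2]] + truth$alpha_protein * d[rows[, 1]] +
                    a[rows[, 1]] + pe[rows[, 1]] + e),
      stringsAsFactors = FALSE)
    protein <- protein[order(protein$animal_id, protein$period), ]
    rownames(protein) <- NULL

    list(chip = chip, input = input, consensus_input = consensus_input,
         expression = expr, protein = protein, peaks = ps,
         target_peaks = c(chip = target_chip, atac = target_atac),
         varcomp_truth = list(sigma2_a = s2a, sigma2_pe = s2pe,
                              sigma2_e = s2e))
  })
}

#' Plant a motif (and a disrupting variant) in a random background sequence
#'
#' Background bases are drawn i.i.d. from the PWM's background
#' distribution; the PWM's consensus word is written at `offset`, and the
#' returned variant sits at `variant_offset` within the motif with the
#' planted consensus base as reference and the base minimising that
#' column's score as alternate — a maximal binding-site disruption.
#'
#' @param seq_len Total sequence length.
#' @param pwm A `Pwm`.
#' @param offset 1-based motif start; `offset + width - 1 <= seq_len`.
#' @param variant_offset 1-based position within the motif.
#' @param seed Integer seed.
#' @return List with `sequence` (character), `variant` (list `id`, `offset`
#'   in the sequence, `ref`, `alt`).
#' @export
plant_motif <- function(seq_len, pwm, offset, variant_offset, seed = 1) {
  stopifnot(inherits(pwm, "Pwm"), offset >= 1,
            offset + pwm$width - 1 <= seq_len)
  if (variant_offset < 1 || variant_offset > pwm$width)
    stop("variant_offset must fall within the motif (1..", pwm$width, ")")
  with_seed(child_seed(seed, 3), {
    bases <- strsplit("ACGT", "")[[1]]
    s <- sample(bases, seq_len, replace = TRUE, prob = pwm$background)
    consensus <- bases[apply(pwm$scores, 2, which.max)]
    s[offset:(offset + pwm$width - 1)] <- consensus
    col <- pwm$scores[, variant_offset]
    worst <- bases[which.min(col)]
    pos <- offset + variant_offset - 1
    list(sequence = paste(s, collapse = ""),
         variant = list(id = paste0("planted_", pos), offset = pos,
                        ref = s[pos], alt = worst))
  })
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Simulates genotypes and the molecular cascade, plants a motif fixture,
#' and writes every artefact in the formats the package reads back: VCF,
#' narrowPeak, ChIP/input/expression count TSVs, protein TSV, JASPAR PFM,
#' FASTA and a truth JSON, plus a manifest with MD5 checksums (stable for a
#' fixed seed).
#'
#' @param outdir Writable output directory (created if needed).
#' @param cfg A [sim_config()].
#' @return `data.frame` manifest (`file`, `md5`), invisibly the paths.
#' @export
write_fixture_bundle <- function(outdir, cfg = sim_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) stop("directory not writable: ", outdir)
  sim <- simulate_genotypes(cfg)
  cas <- simulate_molecular_cascade(sim$genotypes, sim$truth, cfg)
  pfm <- demo_pfm()
  pwm <- pfm_to_pwm(pfm)
  planted <- plant_motif(400, pwm, offset = 180,
                         variant_offset = ceiling(pwm$width / 2),
                         seed = cfg$seed)
  paths <- c(
    genotypes = file.path(outdir, "genotypes.vcf"),
    peaks = file.path(outdir, "peaks.narrowPeak"),
    chip = file.path(outdir, "chip_counts.tsv"),
    input = file.path(outdir, "input_counts.tsv"),
    expression = file.path(outdir, "expression_counts.tsv"),
    protein = file.path(outdir, "protein_phenotypes.tsv"),
    pfm = file.path(outdir, "motifs.jaspar"),
    fasta = file.path(outdir, "target_region.fa"),
    truth = file.path(outdir, "truth.json"))
  write_vcf(sim$genotypes, paths["genotypes"])
  write_peaks(cas$peaks, paths["peaks"], dialect = "narrowPeak")
  write_counts(cas$chip, paths["chip"], feature_col = "peak")
  write_counts(cas$input, paths["input"], feature_col = "peak")
  write_counts(cas$expression, paths["expression"], feature_col = "gene")
  utils::write.table(cas$protein, paths["protein"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_jaspar_pfm(list(pfm), paths["pfm"])
  write_fasta(c(planted_region = planted$sequence), paths["fasta"])
  truth_out <- c(unclass(sim$truth),
                 list(target_peaks = as.list(cas$target_peaks),
                      planted_variant = planted$variant))
  jsonlite::write_json(truth_out, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         row.names = NULL)
  utils::write.table(manifest, file.path(outdir, "MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}

# A STAT-like palindromic PFM used for demonstration fixtures (synthetic;
# not taken from any motif database).
#' @noRd
demo_pfm <- function() {
  counts <- rbind(
    A = c(2, 1, 0, 40, 10, 10, 10, 0, 38, 1),
    C = c(3, 2, 1, 1, 10, 10, 10, 1, 1, 44),
    G = c(1, 2, 45, 2, 10, 10, 10, 2, 6, 2),
    T = c(44, 45, 4, 7, 20, 20, 20, 47, 5, 3))
  list(tf_id = "SYN0001", tf_name = "SYNSTAT", counts = counts)
}
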