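# GRM construction, REML variance components and mixed-linear-model
# association (MLMA). The REML solver works in the eigenbasis of the GRM
# (EMMA-style), profiling out the overall scale and optimising the
# heritability ratio in one dimension before computing information-based
# standard errors, which keeps genome scans and replicate simulations fast.

#' Compute a genomic relationship matrix (VanRaden method 1)
#'
#' Per-variant standardisation: `z = (x - 2p) / sqrt(2 p (1 - p))` with `p`
#' the alt-allele frequency, then `G = Z Z' / m`. Missing dosages are
#' mean-imputed per variant at this point of use only; monomorphic variants
#' are skipped (their count is reported on the result).
#'
#' @param g `GenotypeMatrix`.
#' @param exclude Optional region to leave out of the calculation: a bare
#'   chromosome name (leave-one-chromosome-out) or a `"chrom:start-end"`
#'   string / list (leave-one-segment-out).
#' @return A `Grm`: list with `matrix` (samples x samples), `n_variants_used`,
#'   `n_monomorphic`, `excluded_region`.
#' @export
compute_grm <- function(g, exclude = NULL) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  region <- parse_region(exclude)
  keep <- rep(TRUE, ncol(g$dosage))
  if (!is.null(region))
    keep <- !in_region(g$variants$chrom, g$variants$pos, region)
  x <- g$dosage[, keep, drop = FALSE]
  x <- impute_mean(x)
  p <- colMeans(x) / 2
  poly <- p > 0 & p < 1
  n_mono <- sum(!poly)
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  m <- ncol(x)
  if (m < 2) stop("fewer than 2 usable (polymorphic) variants for the GRM")
  z <- sweep(x, 2, 2 * p, "-")
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(z) / m
  dimnames(G) <- list(rownames(g$dosage), rownames(g$dosage))
  structure(list(matrix = G, n_variants_used = m, n_monomorphic = n_mono,
                 excluded_region = region), class = "Grm")
}

#' @noRd
impute_mean <- function(x) {
  if (!anyNA(x)) return(x)
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  x[idx] <- mu[idx[, 2]]
  x
}

# ---------------------------------------------------------------------------
# single-GRM REML in the eigenbasis

#' @noRd
grm_rotation <- function(grm) {
  e <- eigen(grm$matrix, symmetric = TRUE)
  list(U = e$vectors, lambda = pmax(e$values, 0))
}

# REML log-likelihood (up to an additive constant shared across h) for
# V = phi * (h * G + (1 - h) * I), with phi profiled out.
#' @noRd
reml_profile_ll <- function(h, lambda, yt, Xt) {
  d <- h * lambda + (1 - h)
  w <- 1 / d
  XtW <- Xt * w
  XtWX <- crossprod(Xt, XtW)
  cXtWX <- chol(XtWX)
  beta <- backsolve(cXtWX, forwardsolve(t(cXtWX), crossprod(XtW, yt)))
  r <- yt - Xt %*% beta
  rss <- sum(w * r^2)
  n <- length(yt); p <- ncol(Xt)
  phi <- rss / (n - p)
  -0.5 * (sum(log(d)) + 2 * sum(log(diag(cXtWX))) + (n - p) * log(phi) +
          (n - p))
}

#' Estimate variance components by REML against a GRM
#'
#' Fits `y ~ N(X beta, sigma2_g * G + sigma2_e * I)` by restricted maximum
#' likelihood: the model is rotated into the eigenbasis of `G`, the
#' heritability ratio is located by one-dimensional profile-likelihood
#' search, and standard errors come from the inverse Fisher information of
#' `(sigma2_g, sigma2_e)` at the optimum. The likelihood-ratio test against
#' `sigma2_g = 0` uses the boundary-corrected 50:50 mixture of a point mass
#' at zero and chi-squared with 1 df.
#'
#' @param y Numeric phenotype vector (names, if present, must match the GRM
#'   sample order).
#' @param grm A `Grm` (or a bare symmetric matrix).
#' @param covariates Optional numeric matrix of covariates (no intercept
#'   column; one is added).
#' @return A `VarianceComponents` list: `sigma2_g`, `sigma2_e`, `h2`, `se_h2`,
#'   `loglik`, `lrt`, `lrt_p`, `n`.
#' @export
reml_variance_components <- function(y, grm, covariates = NULL) {
  G <- if (inherits(grm, "Grm")) grm$matrix else as.matrix(grm)
  n <- length(y)
  stopifnot(nrow(G) == n)
  if (stats::var(y) == 0) stop("phenotype has no variance")
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (qr(X)$rank < ncol(X)) stop("covariates are rank deficient")
  rot <- grm_rotation(if (inherits(grm, "Grm")) grm else
                        structure(list(matrix = G), class = "Grm"))
  yt <- drop(crossprod(rot$U, y))
  Xt <- crossprod(rot$U, X)
  lambda <- rot$lambda

  f <- function(h) reml_profile_ll(h, lambda, yt, Xt)
  opt <- stats::optimize(f, interval = c(0, 1 - 1e-6), maximum = TRUE,
                         tol = 1e-9)
  ll0 <- f(0)
  h <- if (opt$objective > ll0) opt$maximum else 0
  ll <- max(opt$objective, ll0)

  # scale back to variances
  d <- h * lambda + (1 - h)
  w <- 1 / d
  XtW <- Xt * w
  XtWX <- crossprod(Xt, XtW)
  beta <- solve(XtWX, crossprod(XtW, yt))
  r <- yt - Xt %*% beta
  phi <- sum(w * r^2) / (n - ncol(Xt))
  sigma2_g <- phi * h
  sigma2_e <- phi * (1 - h)

  # Fisher information of (sigma2_g, sigma2_e): I_ij = tr(P V_i P V_j) / 2
  # computed in the eigenbasis, where P = W - W Xt (Xt' W Xt)^-1 Xt' W with
  # W = diag(1 / (sigma2_g * lambda + sigma2_e)).
  dv <- sigma2_g * lambda + sigma2_e
  wv <- 1 / dv
  XtWv <- Xt * wv
  M <- solve(crossprod(Xt, XtWv))            # (X' V^-1 X)^-1
  # diag of P in eigen coords: P = diag(wv) - XtWv M XtWv'
  # traces tr(P A P B) for A, B diagonal (lambda or 1):
  pdiagprod <- function(a, b) {
    # tr(P diag(a) P diag(b)) with P = W - W Xt M Xt' W, W = diag(wv):
    #   sum(wv^2 a b) - 2 tr(M Xt' diag(wv^3 a b) Xt)
    #   + tr(M Ca M Cb),  Ca = Xt' diag(wv^2 a) Xt, Cb likewise.
    Cab <- crossprod(Xt, (wv^3 * a * b) * Xt)
    Ca <- crossprod(Xt, (wv^2 * a) * Xt)
    Cb <- crossprod(Xt, (wv^2 * b) * Xt)
    sum(wv^2 * a * b) - 2 * sum(M * Cab) + sum((M %*% Ca) * t(M %*% Cb))
  }
  I11 <- 0.5 * pdiagprod(lambda, lambda)
  I12 <- 0.5 * pdiagprod(lambda, rep(1, n))
  I22 <- 0.5 * pdiagprod(rep(1, n), rep(1, n))
  info <- matrix(c(I11, I12, I12, I22), 2)
  se_h2 <- tryCatch({
    V <- solve(info)
    s <- sigma2_g + sigma2_e
    grad <- c(sigma2_e, -sigma2_g) / s^2
    sqrt(drop(t(grad) %*% V %*% grad))
  }, error = function(e) NA_real_)

  lrt <- 2 * (ll - ll0)
  lrt_p <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, 1, lower.tail = FALSE)
  list(sigma2_g = sigma2_g, sigma2_e = sigma2_e, h2 = h,
       se_h2 = se_h2, loglik = ll, lrt = lrt, lrt_p = lrt_p, n = n)
}

# ---------------------------------------------------------------------------
# MLMA

#' Mixed-linear-model association scan
#'
#' Variance components are estimated once under the null model (no variant
#' term), then each variant is tested by generalised least squares with
#' `V = sigma2_g * G + sigma2_e * I` held fixed, reporting the per-alt-allele
#' effect, its standard error and a Wald p-value from the standard normal.
#' Monomorphic variants are retained in the output with `status
#' = "monomorphic"` and `NA` statistics rather than silently dropped. For a
#' LOCO/LOSO design, pass a GRM built with the tested region excluded.
#'
#' @param y Phenotype vector, one value per GRM sample (in GRM order).
#' @param g `GenotypeMatrix` over the same samples (same order).
#' @param grm A `Grm`.
#' @param covariates Optional numeric covariate matrix (no intercept).
#' @param phenotype Name recorded on the result.
#' @return A `QtlSummary` with attributes `phenotype`, `covariates`,
#'   `grm_mode`, `sigma2_g`, `sigma2_e`.
#' @export
mlma <- function(y, g, grm, covariates = NULL, phenotype = "trait") {
  stopifnot(inherits(g, "GenotypeMatrix"), inherits(grm, "Grm"))
  n <- length(y)
  if (nrow(g$dosage) != n || nrow(grm$matrix) != n)
    stop("dimension mismatch between phenotype, genotypes and GRM")
  vc <- reml_variance_components(y, grm, covariates)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)

  rot <- grm_rotation(grm)
  d <- vc$sigma2_g * rot$lambda + vc$sigma2_e
  w <- 1 / d
  yt <- drop(crossprod(rot$U, y))
  Xt <- crossprod(rot$U, X)

  dos <- impute_mean(g$dosage)
  p <- colMeans(dos) / 2
  poly <- p > 1e-12 & p < 1 - 1e-12
  Gt <- crossprod(rot$U, dos)

  WX <- Xt * w
  A <- solve(crossprod(Xt, WX))
  XWy <- crossprod(WX, yt)
  B <- crossprod(Gt, WX)                  # m x p
  xWy <- drop(crossprod(Gt, w * yt))
  xWx <- colSums(Gt^2 * w)
  num <- xWy - drop(B %*% (A %*% XWy))
  den <- xWx - rowSums((B %*% A) * B)

  # a variant collinear with the covariates (e.g. a perfect-LD copy of a
  # conditioning variant) carries no testable information
  testable <- poly & den > 1e-8 * pmax(xWx, .Machine$double.eps)
  beta <- se <- pval <- rep(NA_real_, ncol(dos))
  beta[testable] <- num[testable] / den[testable]
  se[testable] <- sqrt(1 / den[testable])
  z <- abs(beta / se)
  pval <- 2 * stats::pnorm(-z)
  pval[!is.na(pval) & pval == 0] <- .Machine$double.xmin

  mode <- if (is.null(grm$excluded_region)) "full"
          else if (is.finite(grm$excluded_region$start)) "loso" else "loco"
  qtl_summary(data.frame(
    id = g$variants$id, chrom = g$variants$chrom, pos = g$variants$pos,
    ref = g$variants$ref, alt = g$variants$alt,
    maf = pmin(p, 1 - p), n = n, beta = beta, se = se, p = pval,
    status = ifelse(poly, ifelse(testable, "ok", "collinear"),
                    "monomorphic"), stringsAsFactors = FALSE),
    phenotype = phenotype, covariates = colnames(covariates) %||% character(),
    grm_mode = mode) -> qs
  attr(qs, "sigma2_g") <- vc$sigma2_g
  attr(qs, "sigma2_e") <- vc$sigma2_e
  qs
}

#' Association scan conditioning on one variant
#'
#' Re-runs [mlma()] with the dosage of the conditioning variant appended to
#' the covariates; the conditioning variant itself is reported with
#' `status = "conditioned"` and `NA` statistics.
#'
#' @inheritParams mlma
#' @param condition_on Variant id present in `g`.
#' @return A `QtlSummary`.
#' @export
conditional_scan <- function(y, g, grm, covariates = NULL, condition_on,
                             phenotype = "trait") {
  j <- match(condition_on, g$variants$id)
  if (is.na(j)) stop("unknown conditioning variant: ", condition_on)
  xc <- impute_mean(g$dosage[, j, drop = FALSE])
  colnames(xc) <- condition_on
  qs <- mlma(y, g, grm, covariates = cbind(covariates, xc),
             phenotype = phenotype)
  qs$beta[j] <- qs$se[j] <- qs$p[j] <- NA_real_
  qs$status[j] <- "conditioned"
  qs
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param m Number of tests, >= 1.
#' @return `alpha / m` at full precision, with the conventionally reported
#'   2-significant-figure value in attribute `"signif2"`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  structure(alpha / m, signif2 = signif(alpha / m, 2))
}
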