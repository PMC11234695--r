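# Repeated-measures protein phenotypes: skewness assessment, log transforms,
# and the aggregate phenotype from an animal-model REML fit with additive
# (relationship-structured) and permanent-environment random effects.

#' Sample skewness
#'
#' `sum((x - mean(x))^3) / (n * s^3)` with `s` the usual (n-1)-denominator
#' sample standard deviation. Used to decide whether a concentration
#' phenotype needs a log transform before association analysis.
#'
#' @param values Numeric vector, length >= 3, non-constant.
#' @return Skewness estimate (0 for symmetric data).
#' @export
sample_skewness <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 values for a skewness estimate")
  s <- stats::sd(values)
  if (s == 0) stop("skewness undefined for a constant vector")
  sum((values - mean(values))^3) / (n * s^3)
}

#' Convert a natural-log-scale allele effect to a fold change
#'
#' @param beta_log Effect on the natural-log phenotype scale per alt allele.
#' @param n_alleles 1 (per allele) or 2 (between opposing homozygotes).
#' @return `exp(beta_log * n_alleles)` to 3 significant figures, the
#'   conventional reporting precision for fold changes.
#' @export
effect_to_fold <- function(beta_log, n_alleles = 1) {
  stopifnot(is.finite(beta_log), n_alleles %in% c(1, 2))
  signif(exp(beta_log * n_alleles), 3)
}

#' Per-period natural-log phenotypes
#'
#' Splits a repeated-measures table into per-period vectors of
#' natural-log-transformed values. Refuses to transform an aggregate
#' phenotype: aggregates are centred near zero, so a large share of values
#' would be negative and the log undefined.
#'
#' @param tbl Repeated-measures `data.frame` with columns `animal_id`,
#'   `period`, `value` (concentrations, > 0).
#' @return Named list (one element per period) of named log-value vectors.
#' @export
prepare_log_phenotypes <- function(tbl) {
  if (inherits(tbl, "AggregatePhenotype") ||
      any(tolower(as.character(tbl$period)) %in% c("aggregate", "agg")))
    stop("refusing to log-transform an aggregate phenotype: ",
         "aggregate values are centred on zero and include negatives")
  bad <- tbl$value <= 0 | is.na(tbl$value)
  if (any(bad))
    stop("non-positive value(s) for animal(s): ",
         paste(unique(tbl$animal_id[bad]), collapse = ", "))
  split(stats::setNames(log(tbl$value), tbl$animal_id),
        as.character(tbl$period))
}

# ---------------------------------------------------------------------------
# AI-REML for y = X b + Z a + Z p + e,  a ~ (0, A sa2), p ~ (0, I sp2),
# e ~ (0, I se2). All heavy algebra is done at the animal level (n) rather
# than the record level (N) via the Woodbury identity, since Z'Z is diagonal.

#' @noRd
rm_design <- function(tbl, relationship, fixed_effects) {
  animals <- rownames(relationship)
  if (is.null(animals)) stop("relationship matrix needs dimnames (animal ids)")
  ai <- match(as.character(tbl$animal_id), animals)
  if (anyNA(ai))
    stop("animals missing from relationship matrix: ",
         paste(unique(tbl$animal_id[is.na(ai)]), collapse = ", "))
  X <- stats::model.matrix(~ factor(period), data = tbl)
  for (fe in fixed_effects) {
    v <- tbl[[fe]]
    if (is.null(v)) stop("unknown fixed effect column: ", fe)
    Xf <- if (is.numeric(v)) matrix(v, dimnames = list(NULL, fe))
          else stats::model.matrix(~ factor(v))[, -1, drop = FALSE]
    X <- cbind(X, Xf)
  }
  if (qr(X)$rank < ncol(X))
    stop("unestimable fixed effect (confounded levels) in: ",
         paste(c("period", fixed_effects), collapse = ", "))
  list(y = tbl$value, X = X, ai = ai, animals = animals)
}

#' Fit the repeated-measures animal model and build the aggregate phenotype
#'
#' Fits `y = X b + Z a + Z p + e` by average-information REML with an EM
#' fallback when the AI update would leave the parameter space, where `a` is
#' the additive animal effect with covariance `A * sigma2_a` (`A` a pedigree
#' or genomic relationship matrix), `p` a permanent-environment effect and
#' `e` the residual. Fixed effects always include the collection period;
#' further covariate columns of `tbl` can be named in `fixed_effects`.
#'
#' The aggregate phenotype for each animal is its additive BLUP plus the
#' mean of its residuals (`a_i + mean(e_it)`); set
#' `include_pe_in_aggregate = TRUE` to also add the permanent-environment
#' BLUP.
#'
#' @param tbl `data.frame` with columns `animal_id`, `period`, `value`, plus
#'   any covariate columns; at most one record per animal x period.
#' @param relationship Symmetric positive-semidefinite animal x animal
#'   matrix with animal ids as dimnames; every animal in `tbl` must appear.
#' @param fixed_effects Character vector of covariate column names.
#' @param include_pe Fit the permanent-environment component (default TRUE).
#' @param include_pe_in_aggregate Add the PE BLUP into the aggregate
#'   (default FALSE: the residual mean uses `e` only).
#' @param tol Convergence tolerance on the relative parameter change
#'   (default 1e-8).
#' @param max_iter Maximum REML iterations (default 200).
#' @return List with `aggregate` (data.frame `animal_id`, `value`,
#'   `n_records`; class `AggregatePhenotype`), `varcomp` (list `sigma2_a`,
#'   `sigma2_pe`, `sigma2_e`, `h2`, `se_h2`, `lrt_p`, `loglik`, `converged`,
#'   `iterations`, `ll_trace`), `blup_a`, `blup_pe`, `beta`.
#' @export
fit_repeated_measures <- function(tbl, relationship, fixed_effects = character(),
                                  include_pe = TRUE,
                                  include_pe_in_aggregate = FALSE,
                                  tol = 1e-8, max_iter = 200) {
  if (anyDuplicated(tbl[, c("animal_id", "period")]))
    stop("at most one record per animal x period")
  A <- as.matrix(relationship)
  if (max(abs(A - t(A))) > 1e-8) stop("relationship matrix must be symmetric")
  des <- rm_design(tbl, A, fixed_effects)
  y <- des$y; X <- des$X; ai <- des$ai
  n <- nrow(A); N <- length(y); p <- ncol(X)
  used <- sort(unique(ai))

  # degenerate data: nothing to partition
  ols <- stats::lm.fit(X, y)
  if (stats::var(ols$residuals) < 1e-24) {
    agg <- data.frame(animal_id = des$animals[used], value = 0,
                      n_records = as.vector(table(factor(ai, levels = used))))
    class(agg) <- c("AggregatePhenotype", "data.frame")
    return(list(aggregate = agg,
                varcomp = list(sigma2_a = 0, sigma2_pe = 0,
                               sigma2_e = 0, h2 = 0, se_h2 = NA_real_,
                               lrt_p = 1, loglik = NA_real_,
                               converged = TRUE, iterations = 0L,
                               ll_trace = numeric()),
                blup_a = stats::setNames(rep(0, n), des$animals),
                blup_pe = stats::setNames(rep(0, n), des$animals),
                beta = ols$coefficients))
  }

  nrec <- tabulate(ai, nbins = n)              # records per animal (Z'Z diag)
  Ztx <- function(v) {                         # Z' v  (n-vector / n x k)
    if (is.matrix(v)) {
      out <- matrix(0, n, ncol(v))
      for (k in seq_len(ncol(v))) out[, k] <- Zt1(v[, k])
      out
    } else Zt1(v)
  }
  Zt1 <- function(v) {
    out <- numeric(n)
    s <- rowsum(v, ai)
    out[as.integer(rownames(s))] <- s
    out
  }
  ZtX <- Ztx(X); Zty <- Zt1(y)

  eps <- 1e-10 * stats::var(y)
  nv <- if (include_pe) 3L else 2L
  theta <- rep(stats::var(ols$residuals) / nv, nv)

  machinery <- function(theta) {
    sa2 <- theta[1]
    sp2 <- if (include_pe) theta[2] else 0
    se2 <- theta[nv]
    D <- sa2 * A
    if (include_pe) diag(D) <- diag(D) + sp2
    Dinv <- solve(D)
    S <- solve(Dinv + diag(nrec / se2, n))
    Wv <- function(v) {                        # V^-1 v for record vector(s)
      if (is.matrix(v)) {
        zv <- Ztx(v)
        v / se2 - (S %*% zv)[ai, , drop = FALSE] / se2^2
      } else {
        zv <- Zt1(v)
        v / se2 - drop(S %*% zv)[ai] / se2^2
      }
    }
    Wy <- Wv(y); WX <- Wv(X)
    XtWX <- crossprod(X, WX)
    Mx <- solve(XtWX)
    beta <- drop(Mx %*% crossprod(WX, y))
    Py <- Wy - WX %*% (Mx %*% crossprod(X, Wy))
    # log|V| = N log se2 + log|D| + log|Dinv + Z'Z/se2|
    ldV <- N * log(se2) + determinant(D)$modulus +
      determinant(Dinv + diag(nrec / se2, n))$modulus
    ll <- -0.5 * (as.numeric(ldV) + as.numeric(determinant(XtWX)$modulus) +
                  sum(y * Py))
    list(S = S, se2 = se2, sa2 = sa2, sp2 = sp2, Wv = Wv, WX = WX, Mx = Mx,
         beta = beta, Py = drop(Py), ll = ll)
  }

  Pv <- function(mach, v) {                    # P v
    Wvv <- mach$Wv(v)
    Wvv - mach$WX %*% (mach$Mx %*% crossprod(X, Wvv))
  }

  traces <- function(mach) {
    se2 <- mach$se2; S <- mach$S
    # Z' V^-1 Z = diag(nrec)/se2 - diag(nrec) S diag(nrec) / se2^2
    ZtWZ <- diag(nrec / se2, n) - (nrec * t(nrec * S)) / se2^2
    trWV <- c(sum(A * ZtWZ), sum(diag(ZtWZ)),
              N / se2 - sum(diag(S) * nrec) / se2^2)
    # correction tr(Q V_i), Q = WX Mx WX'
    ZtWX <- Ztx(mach$WX)
    trQ <- c(sum((mach$Mx %*% t(ZtWX)) * t(A %*% ZtWX)),
             sum((mach$Mx %*% t(ZtWX)) * t(ZtWX)),
             sum((mach$Mx %*% t(mach$WX)) * t(mach$WX)))
    tr <- trWV - trQ
    if (include_pe) tr else tr[c(1, 3)]
  }

  quadratics <- function(mach) {
    Py <- mach$Py
    ZtPy <- Zt1(Py)
    q <- c(drop(crossprod(ZtPy, A %*% ZtPy)), sum(ZtPy^2), sum(Py^2))
    if (include_pe) q else q[c(1, 3)]
  }

  Vi_times <- function(k, v) {                 # V_k v on record scale
    if (include_pe) {
      switch(k, (A %*% Zt1(v))[ai], Zt1(v)[ai], v)
    } else {
      switch(k, (A %*% Zt1(v))[ai], v)
    }
  }

  ll_trace <- numeric()
  converged <- FALSE
  mach <- machinery(theta)
  for (it in seq_len(max_iter)) {
    ll_trace <- c(ll_trace, mach$ll)
    tr <- traces(mach)
    qd <- quadratics(mach)
    grad <- -0.5 * (tr - qd)
    # AI matrix: 0.5 * (V_i P y)' P (V_j P y)
    vlist <- lapply(seq_len(nv), function(k) Vi_times(k, mach$Py))
    Pvl <- lapply(vlist, function(v) drop(Pv(mach, v)))
    AI <- matrix(0, nv, nv)
    for (i2 in seq_len(nv)) for (j2 in i2:nv)
      AI[i2, j2] <- AI[j2, i2] <- 0.5 * sum(vlist[[i2]] * Pvl[[j2]])
    step <- tryCatch(solve(AI, grad), error = function(e) NULL)
    prop <- if (!is.null(step)) theta + step else NULL
    if (is.null(prop) || any(!is.finite(prop)) || any(prop < eps)) {
      # EM-flavoured fallback keeps estimates positive
      prop <- theta * qd / pmax(tr, eps)
      prop <- pmax(prop, eps)
    }
    delta <- max(abs(prop - theta) / (abs(theta) + 1e-8))
    theta <- prop
    mach <- machinery(theta)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged && max_iter > 0)
    warning("REML did not converge in ", max_iter, " iterations")

  # variance of theta from the final AI matrix
  vlist <- lapply(seq_len(nv), function(k) Vi_times(k, mach$Py))
  Pvl <- lapply(vlist, function(v) drop(Pv(mach, v)))
  AI <- matrix(0, nv, nv)
  for (i2 in seq_len(nv)) for (j2 in i2:nv)
    AI[i2, j2] <- AI[j2, i2] <- 0.5 * sum(vlist[[i2]] * Pvl[[j2]])
  sa2 <- theta[1]; sp2 <- if (include_pe) theta[2] else 0; se2 <- theta[nv]
  tot <- sa2 + sp2 + se2
  h2 <- sa2 / tot
  se_h2 <- tryCatch({
    Vth <- solve(AI)
    gr <- if (include_pe) c(tot - sa2, -sa2, -sa2) / tot^2
          else c(tot - sa2, -sa2) / tot^2
    sqrt(drop(t(gr) %*% Vth %*% gr))
  }, error = function(e) NA_real_)

  # LRT against sigma2_a = 0: refit without the additive term
  ll0 <- rm_null_loglik(y, X, ai, nrec, n, N, include_pe)
  lrt <- 2 * (mach$ll - ll0)
  lrt_p <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, 1, lower.tail = FALSE)

  # BLUPs and aggregate
  Py <- mach$Py
  blup_a <- drop(sa2 * (A %*% Zt1(Py)))
  blup_pe <- if (include_pe) sp2 * Zt1(Py) else rep(0, n)
  fitted_fix <- drop(X %*% mach$beta)
  ehat <- y - fitted_fix - blup_a[ai] - blup_pe[ai]
  emean <- numeric(n)
  s <- rowsum(ehat, ai)
  emean[as.integer(rownames(s))] <- s / nrec[as.integer(rownames(s))]
  aggval <- blup_a + emean
  if (include_pe_in_aggregate) aggval <- aggval + blup_pe
  agg <- data.frame(animal_id = des$animals[used], value = aggval[used],
                    n_records = nrec[used])
  class(agg) <- c("AggregatePhenotype", "data.frame")
  rownames(agg) <- NULL

  list(aggregate = agg,
       varcomp = list(sigma2_a = sa2, sigma2_pe = sp2, sigma2_e = se2,
                      h2 = h2, se_h2 = se_h2, lrt_p = lrt_p,
                      loglik = mach$ll, converged = converged,
                      iterations = it, ll_trace = ll_trace),
       blup_a = stats::setNames(blup_a, des$animals),
       blup_pe = stats::setNames(blup_pe, des$animals),
       beta = stats::setNames(mach$beta, colnames(X)))
}

# REML log-likelihood of the model without the additive animal term,
# maximised over (sigma2_pe, sigma2_e) [or sigma2_e only].
#' @noRd
rm_null_loglik <- function(y, X, ai, nrec, n, N, include_pe) {
  p <- ncol(X)
  if (!include_pe) {
    r <- stats::lm.fit(X, y)$residuals
    se2 <- sum(r^2) / (N - p)
    XtX <- crossprod(X)
    return(-0.5 * (N * log(se2) +
                   as.numeric(determinant(XtX / se2)$modulus) +
                   sum(r^2) / se2))
  }
  Zt1 <- function(v) {
    out <- numeric(n)
    s <- rowsum(v, ai)
    out[as.integer(rownames(s))] <- s
    out
  }
  ll_of <- function(par) {
    sp2 <- exp(par[1]); se2 <- exp(par[2])
    d <- 1 / (1 / sp2 + nrec / se2)           # S diagonal (D = sp2 I)
    Wv <- function(v) {
      if (is.matrix(v)) {
        zv <- apply(v, 2, Zt1)
        v / se2 - (d * zv)[ai, , drop = FALSE] / se2^2
      } else v / se2 - (d * Zt1(v))[ai] / se2^2
    }
    WX <- Wv(X); Wy <- Wv(y)
    XtWX <- crossprod(X, WX)
    Py <- Wy - WX %*% solve(XtWX, crossprod(X, Wy))
    # log|V| = N log se2 + log|I_n + sp2 diag(nrec) / se2|  (D = sp2 I)
    ldV <- N * log(se2) + sum(log1p(sp2 * nrec / se2))
    -0.5 * (ldV + as.numeric(determinant(XtWX)$modulus) + sum(y * Py))
  }
  v0 <- stats::var(stats::lm.fit(X, y)$residuals)
  opt <- stats::optim(log(c(v0 / 2, v0 / 2)), function(p) -ll_of(p),
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  -opt$value
}
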