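#' Per-cohort minor-allele-frequency filter
#'
#' Computes each locus's sample MAF in the analyzed cohort and flags loci at
#' or above the threshold (inclusive boundary: a sample MAF of exactly the
#' threshold passes). Filtering is per-cohort by design — a locus may be
#' common in the admixed cohort and rare in a source cohort.
#'
#' @param genotypes A `genotype_set` or dosage matrix.
#' @param threshold MAF threshold in `[0, 0.5]`.
#' @return Logical vector, `TRUE` for loci that pass.
#' @export
maf_filter <- function(genotypes, threshold) {
  G <- if (inherits(genotypes, "genotype_set")) genotypes$dosages else genotypes
  stopifnot(is.matrix(G), threshold >= 0, threshold <= 0.5)
  f <- colMeans(G) / 2
  maf <- pmin(f, 1 - f)
  maf >= threshold - 1e-12
}

#' Per-locus association scan
#'
#' Tests each locus for association with the phenotype by a separate
#' regression `y ~ dosage (+ theta)`: ordinary least squares for a
#' quantitative trait, maximum-likelihood logistic regression for a
#' dichotomous trait, each reporting the two-sided Wald p-value on the
#' dosage term. Supplying the global-ancestry covariate corrects for
#' population structure and is the convention for the admixed cohort; source
#' cohorts are scanned without covariates. Loci are marked untested (no
#' p-value) when monomorphic in the analyzed sample, below the MAF
#' threshold, or — for logistic fits — when the fit fails to converge
#' (typically separation at extreme frequencies; a warning reports the
#' count).
#'
#' All loci are fitted jointly by vectorized linear algebra: the linear scan
#' residualizes the phenotype and every dosage column against the covariates
#' (Frisch-Waugh), and the logistic scan runs Newton-Raphson simultaneously
#' across loci with closed-form 2x2/3x3 information solves. Results are
#' identical to per-locus [stats::lm()] / [stats::glm()] fits.
#'
#' @param genotypes A `genotype_set` or dosage matrix (individuals x loci).
#' @param y Phenotype vector: numeric (quantitative) or 0/1 (dichotomous).
#' @param covar Optional covariate vector (global ancestry) or matrix.
#' @param mode `"linear"` or `"logistic"`.
#' @param maf_threshold Sample-MAF filter applied before testing (default 0:
#'   only monomorphic loci are excluded).
#' @param maxit,tol Newton-Raphson iteration cap and convergence tolerance
#'   for logistic fits.
#' @return A data frame of class `assoc_table` with one row per locus:
#'   `locus`, `beta`, `se`, `p`, `tested`, `maf`.
#' @export
assoc_scan <- function(genotypes, y, covar = NULL,
                       mode = c("linear", "logistic"),
                       maf_threshold = 0, maxit = 100L, tol = 1e-8) {
  mode <- match.arg(mode)
  G <- if (inherits(genotypes, "genotype_set")) genotypes$dosages else genotypes
  stopifnot(is.matrix(G), length(y) == nrow(G))
  if (!is.null(covar)) {
    covar <- as.matrix(covar)
    stopifnot(nrow(covar) == nrow(G))
  }
  n <- nrow(G)
  L <- ncol(G)
  f <- colMeans(G) / 2
  maf <- pmin(f, 1 - f)
  poly <- matrixStats_colVars(G) > 0
  eligible <- poly & maf_filter(G, maf_threshold)

  beta <- se <- p <- rep(NA_real_, L)
  tested <- eligible
  if (any(eligible)) {
    Ge <- G[, eligible, drop = FALSE]
    fit <- if (mode == "linear") {
      .linear_scan(Ge, y, covar)
    } else {
      .logistic_scan(Ge, y, covar, maxit = maxit, tol = tol)
    }
    beta[eligible] <- fit$beta
    se[eligible] <- fit$se
    p[eligible] <- fit$p
    if (any(!fit$ok)) {
      bad <- which(eligible)[!fit$ok]
      tested[bad] <- FALSE
      beta[bad] <- se[bad] <- p[bad] <- NA_real_
      if (mode == "logistic")
        warning(length(bad), " locus/loci dropped: logistic fit did not ",
                "converge (likely separation)")
    }
  }
  structure(
    data.frame(locus = seq_len(L), beta = beta, se = se, p = p,
               tested = tested, maf = maf),
    class = c("assoc_table", "data.frame")
  )
}

# column variances without a matrixStats dependency
matrixStats_colVars <- function(G) {
  n <- nrow(G)
  if (n < 2) return(rep(0, ncol(G)))
  (colSums(G^2) - n * colMeans(G)^2) / (n - 1)
}

# OLS scan via Frisch-Waugh: residualize y and every dosage column on the
# nuisance design [1, covar], then per-locus simple regression. Identical to
# the full multiple regression's Wald test on the dosage coefficient.
.linear_scan <- function(G, y, covar) {
  n <- nrow(G)
  X0 <- if (is.null(covar)) matrix(1, n, 1) else cbind(1, covar)
  q0 <- qr(X0)
  yr <- qr.resid(q0, y)
  Gr <- qr.resid(q0, G)
  sxx <- colSums(Gr^2)
  sxy <- colSums(Gr * yr)
  df <- n - ncol(X0) - 1
  beta <- sxy / sxx
  rss <- sum(yr^2) - beta * sxy
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tstat <- beta / se
  list(beta = beta, se = se, p = 2 * stats::pt(-abs(tstat), df),
       ok = is.finite(beta) & is.finite(se) & sxx > 1e-12)
}

# Batched Newton-Raphson logistic scans: one model per locus with design
# [1, dosage (, theta)], advanced in lock-step via column sums and
# closed-form solves of the per-locus information matrix. Only loci that
# have not yet converged are carried into the next iteration; loci whose
# dosage coefficient runs away (|beta| > 30, i.e. separation) or whose
# information matrix degenerates are abandoned and flagged.
.logistic_scan <- function(G, y, covar, maxit = 100L, tol = 1e-8) {
  n <- nrow(G)
  L <- ncol(G)
  if (!is.null(covar) && ncol(covar) > 1)
    stop("logistic scan supports a single covariate column")
  th <- if (is.null(covar)) NULL else as.numeric(covar)
  py <- mean(y)
  b0 <- rep(log(py / (1 - py)), L)
  b1 <- numeric(L)
  b2 <- numeric(L)
  converged <- rep(FALSE, L)
  failed <- rep(FALSE, L)
  var1 <- rep(NA_real_, L)
  active <- seq_len(L)

  for (it in seq_len(maxit)) {
    Ga <- G[, active, drop = FALSE]
    m <- length(active)
    Eta <- matrix(b0[active], n, m, byrow = TRUE) +
      Ga * matrix(b1[active], n, m, byrow = TRUE)
    if (!is.null(th))
      Eta <- Eta + th * matrix(b2[active], n, m, byrow = TRUE)
    Mu <- stats::plogis(Eta)
    W <- Mu * (1 - Mu)
    R <- y - Mu  # y recycles down columns (rows are individuals)
    U0 <- colSums(R)
    U1 <- colSums(Ga * R)
    a <- colSums(W)
    WG <- W * Ga
    b <- colSums(WG)
    d <- colSums(WG * Ga)
    if (is.null(th)) {
      det <- a * d - b^2
      det[det <= 0] <- NA
      d0 <- (d * U0 - b * U1) / det
      d1 <- (a * U1 - b * U0) / det
      v1 <- a / det
      step_max <- pmax(abs(d0), abs(d1))
    } else {
      U2 <- colSums(R * th)
      cth <- colSums(W * th)
      e <- colSums(WG * th)
      fq <- colSums(W * th^2)
      A11 <- d * fq - e^2
      A12 <- -(b * fq - cth * e)
      A13 <- b * e - cth * d
      A22 <- a * fq - cth^2
      A23 <- -(a * e - b * cth)
      A33 <- a * d - b^2
      det <- a * A11 + b * A12 + cth * A13
      det[det <= 0] <- NA
      d0 <- (A11 * U0 + A12 * U1 + A13 * U2) / det
      d1 <- (A12 * U0 + A22 * U1 + A23 * U2) / det
      d2 <- (A13 * U0 + A23 * U1 + A33 * U2) / det
      v1 <- A22 / det
      step_max <- pmax(abs(d0), abs(d1), abs(d2))
      b2[active] <- b2[active] + ifelse(is.na(d2), 0, d2)
    }
    b0[active] <- b0[active] + ifelse(is.na(d0), 0, d0)
    b1[active] <- b1[active] + ifelse(is.na(d1), 0, d1)
    var1[active] <- v1
    bad <- is.na(step_max) | !is.finite(b1[active]) | abs(b1[active]) > 30
    done <- !bad & step_max < tol
    converged[active[done]] <- TRUE
    failed[active[bad]] <- TRUE
    active <- active[!done & !bad]
    if (!length(active)) break
  }
  se <- sqrt(var1)
  ok <- converged & !failed & is.finite(b1) & is.finite(se)
  z <- b1 / se
  list(beta = b1, se = se, p = 2 * stats::pnorm(-abs(z)), ok = ok)
}

#' Summarize discovery power across repetitions
#'
#' Power is the proportion of causal loci reaching significance (`p <=
#' alpha`, inclusive) in a scan; loci left untested (monomorphic, filtered,
#' or non-converged) count as non-significant, with all causal loci in the
#' denominator. The summary reports the mean and standard deviation of the
#' per-repetition proportions.
#'
#' @param scans A single `assoc_table` or a list of them (one per
#'   repetition).
#' @param causal_idx Indices of the causal loci.
#' @param alpha Significance threshold.
#' @return List of class `power_summary`: `power_mean`, `power_sd`,
#'   `per_rep`, `n_reps`, `alpha`.
#' @export
power_estimate <- function(scans, causal_idx, alpha) {
  if (inherits(scans, "assoc_table")) scans <- list(scans)
  stopifnot(length(scans) >= 1, length(causal_idx) >= 1, alpha >= 0)
  per_rep <- vapply(scans, function(tab) {
    sig <- tab$tested & !is.na(tab$p) & tab$p <= alpha
    mean(sig[causal_idx])
  }, numeric(1))
  structure(
    list(power_mean = mean(per_rep),
         power_sd = if (length(per_rep) > 1) stats::sd(per_rep) else NA_real_,
         per_rep = per_rep, n_reps = length(per_rep), alpha = alpha),
    class = "power_summary"
  )
}

#' @export
print.power_summary <- function(x, ...) {
  cat(sprintf("Power at alpha = %g: %.3f (SD %.3f, %d repetitions)\n",
              x$alpha, x$power_mean,
              if (is.na(x$power_sd)) 0 else x$power_sd, x$n_reps))
  invisible(x)
}

#' Empirical false positive rate at non-causal loci
#'
#' The proportion of non-causal (null) loci reaching significance in each
#' repetition's scan; untested loci count as non-significant with all null
#' loci in the denominator.
#'
#' @param scans A single `assoc_table` or a list of them.
#' @param noncausal_idx Indices of the non-causal loci.
#' @param alpha Significance threshold.
#' @return List with `fpr_mean`, `per_rep`, `n_reps`, `alpha`.
#' @export
false_positive_rate <- function(scans, noncausal_idx, alpha) {
  if (inherits(scans, "assoc_table")) scans <- list(scans)
  stopifnot(length(scans) >= 1, length(noncausal_idx) >= 1)
  per_rep <- vapply(scans, function(tab) {
    sig <- tab$tested & !is.na(tab$p) & tab$p <= alpha
    mean(sig[noncausal_idx])
  }, numeric(1))
  list(fpr_mean = mean(per_rep), per_rep = per_rep,
       n_reps = length(per_rep), alpha = alpha)
}
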