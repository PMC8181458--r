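#' Assign signed causal-effect weights tied to ancestral frequencies
#'
#' Weight magnitudes at causal loci are |N(0, 1)| draws. The sign is tied to
#' the allele's relative prevalence in the two source populations: positive
#' with probability `p1 / (p1 + p2)` (`sign_mode = "normalized"`, the
#' default), so alleles common in Population 1 tend to increase the trait.
#' This introduces a difference in the trait's directional selection between
#' the source populations and hence a correlation between the trait and
#' global ancestry in the admixed group. `sign_mode = "ratio"` instead uses
#' the capped ratio `min(p1 / p2, 1)`, offered for sensitivity analysis.
#'
#' @param freqs A [locus_frequencies()] object.
#' @param causal_idx Indices of causal loci; defaults to `freqs$causal_idx`.
#'   Loci with `p1 + p2 = 0` are not permitted (the sign trial is undefined);
#'   [locus_frequencies()] redraws such loci upstream.
#' @param sign_mode `"normalized"` or `"ratio"` (see above).
#' @param seed Optional integer seed.
#' @return Numeric vector of signed weights, one per causal locus (in
#'   `causal_idx` order).
#' @export
assign_effects <- function(freqs, causal_idx = freqs$causal_idx,
                           sign_mode = c("normalized", "ratio"), seed = NULL) {
  stopifnot(inherits(freqs, "locus_freqs"))
  sign_mode <- match.arg(sign_mode)
  p1 <- freqs$p1[causal_idx]
  p2 <- freqs$p2[causal_idx]
  if (any(p1 + p2 == 0))
    stop("causal locus with p1 = p2 = 0: sign probability undefined")
  q <- switch(sign_mode,
    normalized = p1 / (p1 + p2),
    ratio = pmin(ifelse(p2 == 0, 1, p1 / p2), 1)
  )
  w <- length(causal_idx)
  with_seed(seed, {
    magnitude <- abs(stats::rnorm(w))
    sign <- ifelse(stats::runif(w) < q, 1, -1)
    magnitude * sign
  })
}

#' True polygenic score from causal dosages and weights
#'
#' The additive genetic value of each individual:
#' \eqn{\mathrm{PRS}_i = \sum_{s \in \mathrm{causal}} g_{is} w_s}. No
#' dominance or epistasis.
#'
#' @param genotypes A `genotype_set` or a dosage matrix.
#' @param causal_idx Causal locus indices (columns of the dosage matrix).
#' @param weights Signed weights, one per causal locus.
#' @return Numeric vector of length `n_individuals`.
#' @export
compute_prs <- function(genotypes, causal_idx, weights) {
  G <- if (inherits(genotypes, "genotype_set")) genotypes$dosages else genotypes
  stopifnot(is.matrix(G), length(causal_idx) == length(weights),
            all(causal_idx >= 1 & causal_idx <= ncol(G)))
  drop(G[, causal_idx, drop = FALSE] %*% weights)
}

#' Simulate the non-genetic component of the phenotype
#'
#' The environmental score is the sum of random noise and an
#' ancestry-correlated confounder (socioeconomic-status-like effects that
#' track ancestry). Two constructions are available:
#' \describe{
#'   \item{`"gaussian_anc"`}{ancestry-weighted Gaussian noise
#'     \eqn{e_i = \theta_i \epsilon_{1i} + (1-\theta_i) \epsilon_{2i}} with
#'     \eqn{\epsilon_1, \epsilon_2} i.i.d. Gaussian — each individual mixes
#'     two ancestral noise sources in proportion to ancestry.}
#'   \item{`"linear_anc"`}{a linear ancestry term plus noise,
#'     \eqn{e_i = \lambda \theta_i + \epsilon_i}, where the \eqn{\lambda}
#'     term alone accounts for `anc_fraction` of total phenotypic variance.}
#' }
#' The free scales are solved empirically in the simulated cohort so that
#' `var(env) = var_g * (1 - h2) / h2` exactly, i.e. realized narrow-sense
#' heritability equals the target. `var_g` is the genetic variance of the
#' reference cohort — for the admixed cohort its own `var(prs)`, and for the
#' source cohorts the admixed cohort's value, so all three cohorts share one
#' environmental variance and their phenotypes live on one scale. In a
#' homogeneous cohort (constant theta) both modes reduce to plain Gaussian
#' noise at that same total variance.
#'
#' @param theta Global ancestry vector for the cohort.
#' @param var_g Reference additive-genetic variance (> 0 unless `h2 = 1`).
#' @param h2 Target narrow-sense heritability in (0, 1].
#' @param env_mode `"gaussian_anc"` (default) or `"linear_anc"`.
#' @param anc_fraction For `"linear_anc"`: fraction of total phenotypic
#'   variance explained by the linear ancestry term, in `[0, 1 - h2]`.
#' @param seed Optional integer seed.
#' @return Numeric vector of environmental scores (variance exactly
#'   `var_g (1 - h2) / h2`; zero when `h2 = 1`).
#' @export
simulate_environment <- function(theta, var_g, h2,
                                 env_mode = c("gaussian_anc", "linear_anc"),
                                 anc_fraction = 0, seed = NULL) {
  env_mode <- match.arg(env_mode)
  n <- length(theta)
  stopifnot(n >= 2)
  if (!(h2 > 0 && h2 <= 1))
    stop("h2 must lie in (0, 1]: the genetic variance is the scaling reference")
  if (h2 == 1) return(rep(0, n))
  stopifnot(var_g > 0, anc_fraction >= 0, anc_fraction <= 1 - h2 + 1e-12)
  var_env <- var_g * (1 - h2) / h2
  var_p <- var_g / h2

  scale_to <- function(x, target_var) {
    v <- stats::var(x)
    if (v == 0) {
      if (target_var > 0) stop("degenerate environmental draw (zero variance)")
      return(x * 0)
    }
    (x - mean(x)) * sqrt(target_var / v)
  }

  with_seed(seed, {
    if (env_mode == "gaussian_anc") {
      raw <- theta * stats::rnorm(n) + (1 - theta) * stats::rnorm(n)
      scale_to(raw, var_env)
    } else {
      var_anc <- anc_fraction * var_p
      eps <- stats::rnorm(n)
      if (stats::var(theta) == 0 || var_anc == 0) {
        scale_to(eps, var_env)
      } else {
        anc_term <- scale_to(theta, var_anc)
        # orthogonalize the noise against theta so the variance split is exact
        eps_res <- stats::residuals(stats::lm(eps ~ theta))
        anc_term + scale_to(eps_res, var_env - var_anc)
      }
    }
  })
}

#' Assemble the phenotype from genetic and environmental scores
#'
#' Quantitative traits are the direct sum of the polygenic score and the
#' environmental score. Dichotomous traits apply a liability threshold: the
#' `round(n * prevalence)` individuals with the highest liability (the same
#' sum) are cases, using the cohort's empirical quantile rather than a
#' Gaussian threshold because the liability is a finite mixture. Ties are
#' broken by rank order so the case count is exact.
#'
#' @param prs Numeric vector of true polygenic scores.
#' @param env Numeric vector of environmental scores.
#' @param type `"quantitative"` or `"dichotomous"`.
#' @param prevalence Case fraction in (0, 1); required for dichotomous traits.
#' @return An object of class `phenotype_set`: list with `prs`, `env`,
#'   `y_quant`, and (dichotomous only) `y_binary` in \{0, 1\}.
#' @examples
#' ph <- assemble_phenotype(rnorm(100), rnorm(100), "dichotomous", 0.05)
#' sum(ph$y_binary)   # exactly 5 cases
#' @export
assemble_phenotype <- function(prs, env,
                               type = c("quantitative", "dichotomous"),
                               prevalence = NULL) {
  type <- match.arg(type)
  stopifnot(length(prs) == length(env))
  y <- prs + env
  out <- list(prs = prs, env = env, y_quant = y, y_binary = NULL, type = type)
  if (type == "dichotomous") {
    stopifnot(!is.null(prevalence), prevalence > 0, prevalence < 1)
    n <- length(y)
    n_cases <- round(n * prevalence)
    yb <- integer(n)
    yb[order(y, decreasing = TRUE)[seq_len(n_cases)]] <- 1L
    out$y_binary <- yb
    out$prevalence <- prevalence
  }
  structure(out, class = "phenotype_set")
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat(sprintf("Phenotype set: %d individuals, %s trait", length(x$y_quant),
              x$type))
  if (x$type == "dichotomous")
    cat(sprintf(" (%d cases)", sum(x$y_binary)))
  cat("\n")
  invisible(x)
}
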