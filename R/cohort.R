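#' Draw one repetition's shared genetic architecture
#'
#' A repetition of any experiment fixes the genetics once — ancestral and
#' population allele frequencies, the identity of the causal loci, and their
#' signed weights — and reuses it across the admixed and both source
#' cohorts, so cross-population comparisons hold the architecture constant.
#'
#' @param n_loci Total number of LD-independent loci.
#' @param n_causal Number of causal loci (`w`), sampled uniformly without
#'   replacement.
#' @param fst_background Background F_ST at non-causal loci.
#' @param delta MAF-linked F_ST increment at causal loci (flexible mode).
#' @param fst_causal Fixed F_ST at causal loci, or `NULL` for flexible mode.
#' @param sign_mode Sign-trial mode for [assign_effects()].
#' @param seed Optional integer seed.
#' @return An object of class `trait_architecture`: list with `freqs`
#'   ([locus_frequencies()]), `causal_idx`, `weights`, and the generating
#'   parameters.
#' @export
simulate_architecture <- function(n_loci = 1000L, n_causal = 100L,
                                  fst_background = 0.2, delta = 0.3,
                                  fst_causal = NULL,
                                  sign_mode = "normalized", seed = NULL) {
  n_loci <- as.integer(n_loci)
  n_causal <- as.integer(n_causal)
  stopifnot(n_causal >= 0, n_causal <= n_loci)
  with_seed(seed, {
    causal_idx <- sort(sample.int(n_loci, n_causal))
    freqs <- locus_frequencies(n_loci, causal_idx,
                               fst_background = fst_background,
                               delta = delta, fst_causal = fst_causal)
    weights <- assign_effects(freqs, causal_idx, sign_mode = sign_mode)
    structure(
      list(freqs = freqs, causal_idx = causal_idx, weights = weights,
           n_loci = n_loci, n_causal = n_causal,
           fst_background = fst_background, delta = delta,
           fst_causal = fst_causal, sign_mode = sign_mode),
      class = "trait_architecture"
    )
  })
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf(
    "Trait architecture: %d causal of %d loci, causal F_ST %s, background %g\n",
    x$n_causal, x$n_loci,
    if (is.null(x$fst_causal)) sprintf("%g + (1-MAF)*%g", x$fst_background,
                                       x$delta) else format(x$fst_causal),
    x$fst_background))
  invisible(x)
}

#' Simulate one cohort under a shared architecture
#'
#' Draws global ancestry from the spec, genotypes conditional on ancestry
#' and the architecture's population frequencies, the true polygenic score,
#' the environmental score, and the phenotype. For the admixed cohort the
#' environmental variance is anchored to the cohort's own realized genetic
#' variance (`env_var = NULL`); source cohorts are then simulated with the
#' admixed cohort's `env_var` so all three phenotypes share one scale.
#'
#' @param arch A [simulate_architecture()] object.
#' @param spec An [admixture_spec()] or [ancestral_spec()].
#' @param h2 Target narrow-sense heritability in (0, 1].
#' @param trait_type `"quantitative"` or `"dichotomous"`.
#' @param prevalence Case prevalence for dichotomous traits (default 0.05).
#' @param env_mode,anc_fraction Environment model, see
#'   [simulate_environment()].
#' @param env_var Environmental variance to impose, or `NULL` to derive it
#'   from this cohort's realized `var(prs)` and `h2`.
#' @param seed Optional integer seed.
#' @return An object of class `cohort`: list with `theta`, `genotypes`,
#'   `phenotype` (a `phenotype_set`), `env_var`, `spec`.
#' @export
simulate_cohort <- function(arch, spec, h2 = 0.5,
                            trait_type = c("quantitative", "dichotomous"),
                            prevalence = 0.05,
                            env_mode = "gaussian_anc", anc_fraction = 0,
                            env_var = NULL, seed = NULL) {
  stopifnot(inherits(arch, "trait_architecture"),
            inherits(spec, "admixture_spec"))
  trait_type <- match.arg(trait_type)
  with_seed(seed, {
    theta <- sample_global_ancestry(spec)
    gs <- sample_genotypes(arch$freqs, theta = theta)
    prs <- compute_prs(gs, arch$causal_idx, arch$weights)
    var_g <- if (is.null(env_var)) stats::var(prs) else env_var * h2 / (1 - h2)
    if (h2 < 1 && var_g <= 0)
      stop("realized genetic variance is zero; cannot scale the environment ",
           "(no polymorphic causal loci in this cohort?)")
    env <- simulate_environment(theta, var_g, h2, env_mode = env_mode,
                                anc_fraction = anc_fraction)
    ph <- assemble_phenotype(prs, env, trait_type,
                             prevalence = if (trait_type == "dichotomous")
                               prevalence else NULL)
    structure(
      list(theta = theta, genotypes = gs, phenotype = ph,
           env_var = if (h2 < 1) stats::var(env) else 0, spec = spec,
           h2 = h2),
      class = "cohort"
    )
  })
}

#' @export
print.cohort <- function(x, ...) {
  print(x$spec)
  print(x$phenotype)
  invisible(x)
}

#' Simulate the admixed and both source cohorts under one architecture
#'
#' Convenience wrapper for the standard three-cohort design: an admixed
#' cohort plus homogeneous Population-1 and Population-2 cohorts generated
#' through the same machinery (theta identically 1 or 0), sharing the
#' repetition's architecture and the admixed cohort's environmental
#' variance.
#'
#' @param arch A [simulate_architecture()] object.
#' @param n Individuals per cohort, a single number or a length-3 vector
#'   `(admixed, pop1, pop2)`.
#' @param admix_mean,admix_var Beta moments of the admixed cohort's
#'   Population-1 ancestry fraction.
#' @param ... Passed to [simulate_cohort()] (`h2`, `trait_type`, ...).
#' @param seed Optional integer seed.
#' @return Named list of three `cohort` objects: `admixed`, `pop1`, `pop2`.
#' @export
simulate_three_cohorts <- function(arch, n = 1000L, admix_mean = 0.75,
                                   admix_var = 0.02, ..., seed = NULL) {
  n <- rep(as.integer(n), length.out = 3)
  with_seed(seed, {
    admixed <- simulate_cohort(arch, admixture_spec(admix_mean, admix_var,
                                                    n[1]), ...)
    list(
      admixed = admixed,
      pop1 = simulate_cohort(arch, ancestral_spec(1, n[2]), ...,
                             env_var = admixed$env_var),
      pop2 = simulate_cohort(arch, ancestral_spec(2, n[3]), ...,
                             env_var = admixed$env_var)
    )
  })
}

#' Scan one cohort for phenotype-genotype associations
#'
#' Dispatches to the linear or logistic per-locus scan according to the
#' cohort's trait type, supplying the global-ancestry covariate only for
#' admixed cohorts (source cohorts have constant ancestry and are scanned
#' without covariates).
#'
#' @param cohort A [simulate_cohort()] object.
#' @param maf_threshold Sample-MAF filter (default 0).
#' @return An `assoc_table` (see [assoc_scan()]).
#' @export
scan_cohort <- function(cohort, maf_threshold = 0) {
  stopifnot(inherits(cohort, "cohort"))
  admixed <- cohort$spec$variance > 0
  if (cohort$phenotype$type == "quantitative") {
    assoc_scan(cohort$genotypes, cohort$phenotype$y_quant,
               covar = if (admixed) cohort$theta,
               mode = "linear", maf_threshold = maf_threshold)
  } else {
    assoc_scan(cohort$genotypes, cohort$phenotype$y_binary,
               covar = if (admixed) cohort$theta,
               mode = "logistic", maf_threshold = maf_threshold)
  }
}
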