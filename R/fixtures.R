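#' Deterministic small three-cohort bundles for tests and examples
#'
#' Generates 200-individual, 200-locus admixed/Pop1/Pop2 cohort bundles
#' through the real simulation pipeline under a fixed preset:
#' \describe{
#'   \item{`standard-small`}{the standard setting scaled down — African-
#'     American-like ancestry (mean 0.75), background F_ST 0.2 with
#'     MAF-linked increment 0.3 at the 20 causal loci, h2 0.5.}
#'   \item{`high-fst-small`}{fixed causal F_ST 0.8 over background 0.2 —
#'     strongly diverged trait loci.}
#'   \item{`chilean-small`}{a Chilean-like scenario: background F_ST 0.18
#'     between the source populations, admixed ancestry mean 0.55 (majority
#'     European-like component; the ancestry moments are a preset
#'     assumption).}
#' }
#'
#' @param preset One of `"standard-small"`, `"high-fst-small"`,
#'   `"chilean-small"`.
#' @param seed Integer seed; the same (preset, seed) pair always returns an
#'   identical bundle.
#' @return List with `arch` (the shared [simulate_architecture()]) and
#'   cohorts `admixed`, `pop1`, `pop2`.
#' @export
fixture_cohorts <- function(preset = c("standard-small", "high-fst-small",
                                       "chilean-small"), seed = 7L) {
  preset <- match.arg(preset)
  par <- switch(preset,
    "standard-small" = list(fst_background = 0.2, delta = 0.3,
                            fst_causal = NULL, admix_mean = 0.75,
                            admix_var = 0.02),
    "high-fst-small" = list(fst_background = 0.2, delta = 0.3,
                            fst_causal = 0.8, admix_mean = 0.75,
                            admix_var = 0.02),
    "chilean-small" = list(fst_background = 0.18, delta = 0.3,
                           fst_causal = NULL, admix_mean = 0.55,
                           admix_var = 0.02)
  )
  arch <- simulate_architecture(
    n_loci = 200L, n_causal = 20L, fst_background = par$fst_background,
    delta = par$delta, fst_causal = par$fst_causal,
    seed = derive_seed(seed, "fixture", preset, "arch"))
  cohorts <- simulate_three_cohorts(
    arch, n = 200L, admix_mean = par$admix_mean, admix_var = par$admix_var,
    h2 = 0.5, trait_type = "quantitative",
    seed = derive_seed(seed, "fixture", preset, "cohorts"))
  c(list(arch = arch, preset = preset,
         fst_background = par$fst_background), cohorts)
}
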