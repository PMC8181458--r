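# Standard-setting defaults: 100 causal of 1000 loci, background F_ST 0.2
# with MAF-linked increment 0.3, h2 0.5, prevalence 0.05, admixed ancestry
# Beta(mean 0.75, var 0.02), alpha 0.05, no MAF filter, 50 repetitions.

#' Default run configuration (the "standard" setting)
#'
#' @return Nested named list with namespaces `ancestry`, `loci`, `fst`,
#'   `trait`, `assoc`, `experiment`, plus `master_seed`.
#' @export
default_config <- function() {
  list(
    ancestry = list(mean = 0.75, variance = 0.02, n_individuals = 1000L),
    loci = list(n_total = 1000L, n_causal = 100L),
    fst = list(background = 0.2, delta = 0.3, fixed = NULL),
    trait = list(type = "quantitative", h2 = 0.5, prevalence = 0.05,
                 env_mode = "gaussian_anc", env_anc_fraction = 0,
                 sign_mode = "normalized"),
    assoc = list(alpha = 0.05, maf_threshold = 0),
    experiment = list(n_reps = 50L),
    master_seed = 1L
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration file, fills unspecified keys with the
#' standard-setting defaults, and validates every value. Unknown keys are
#' rejected, and all schema violations are reported together. An empty file
#' (or `path = NULL`) yields the full default configuration. The flexible
#' MAF-linked F_ST mode (`fst$delta`) and the fixed mode (`fst$fixed`) are
#' mutually exclusive: setting `fst$fixed` overrides the increment at
#' causal loci.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Validated nested list as in [default_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    stopifnot(file.exists(path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    problems <- character(0)
    for (section in names(user)) {
      if (section == "master_seed") {
        cfg$master_seed <- user$master_seed
        next
      }
      if (!section %in% names(cfg)) {
        problems <- c(problems, paste0("unknown section: ", section))
        next
      }
      for (key in names(user[[section]])) {
        if (!key %in% names(cfg[[section]])) {
          problems <- c(problems,
                        paste0("unknown key: ", section, ".", key))
        } else {
          cfg[[section]][[key]] <- user[[section]][[key]]
        }
      }
    }
    if (length(problems))
      stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  }
  validate_config(cfg)
}

#' Validate a configuration list
#'
#' @param cfg Nested configuration list.
#' @return The configuration, invisibly coerced (integer counts), or an
#'   error listing every offending key.
#' @export
validate_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)

  a <- cfg$ancestry
  chk(is.numeric(a$mean) && a$mean > 0 && a$mean < 1,
      "ancestry.mean must be in (0, 1)")
  chk(is.numeric(a$variance) && a$variance > 0 &&
        a$variance < a$mean * (1 - a$mean),
      "ancestry.variance must be in (0, mean*(1-mean))")
  chk(is.numeric(a$n_individuals) && a$n_individuals >= 1,
      "ancestry.n_individuals must be >= 1")

  l <- cfg$loci
  chk(is.numeric(l$n_total) && l$n_total >= 1, "loci.n_total must be >= 1")
  chk(is.numeric(l$n_causal) && l$n_causal >= 0 &&
        l$n_causal <= l$n_total,
      "loci.n_causal must be in [0, loci.n_total]")

  f <- cfg$fst
  chk(is.numeric(f$background) && f$background > 0 && f$background < 1,
      "fst.background must be in (0, 1)")
  chk(is.numeric(f$delta) && f$delta >= 0, "fst.delta must be >= 0")
  chk(is.null(f$fixed) ||
        (is.numeric(f$fixed) && f$fixed > 0 && f$fixed < 1),
      "fst.fixed must be in (0, 1) or absent")

  t <- cfg$trait
  chk(t$type %in% c("quantitative", "dichotomous"),
      "trait.type must be 'quantitative' or 'dichotomous'")
  chk(is.numeric(t$h2) && t$h2 > 0 && t$h2 <= 1,
      "trait.h2 must be in (0, 1]")
  chk(is.numeric(t$prevalence) && t$prevalence > 0 && t$prevalence < 1,
      "trait.prevalence must be in (0, 1)")
  chk(t$env_mode %in% c("gaussian_anc", "linear_anc"),
      "trait.env_mode must be 'gaussian_anc' or 'linear_anc'")
  chk(is.numeric(t$env_anc_fraction) && t$env_anc_fraction >= 0 &&
        t$env_anc_fraction <= 1 - t$h2 + 1e-12,
      "trait.env_anc_fraction must be in [0, 1 - h2]")
  chk(t$sign_mode %in% c("normalized", "ratio"),
      "trait.sign_mode must be 'normalized' or 'ratio'")

  s <- cfg$assoc
  chk(is.numeric(s$alpha) && all(s$alpha > 0 & s$alpha <= 1),
      "assoc.alpha must be in (0, 1]")
  chk(is.numeric(s$maf_threshold) && s$maf_threshold >= 0 &&
        s$maf_threshold <= 0.5,
      "assoc.maf_threshold must be in [0, 0.5]")

  chk(is.numeric(cfg$experiment$n_reps) && cfg$experiment$n_reps >= 1,
      "experiment.n_reps must be >= 1")
  chk(is.numeric(cfg$master_seed) && length(cfg$master_seed) == 1,
      "master_seed must be a single integer")

  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  cfg$ancestry$n_individuals <- as.integer(cfg$ancestry$n_individuals)
  cfg$loci$n_total <- as.integer(cfg$loci$n_total)
  cfg$loci$n_causal <- as.integer(cfg$loci$n_causal)
  cfg$experiment$n_reps <- as.integer(cfg$experiment$n_reps)
  cfg$master_seed <- as.integer(cfg$master_seed)
  cfg
}
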