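#' Power grid over sample size, F_ST, heritability, and trait type
#'
#' For every grid cell and repetition, simulates the three cohorts (admixed,
#' Population 1, Population 2) under a shared architecture, scans each for
#' association (ancestry covariate in the admixed cohort only), and records
#' discovery power at each significance level together with the false
#' positive rate over the non-causal loci. The derived column `power_ratio`
#' is the admixed power divided by the mean of the two source-population
#' powers; repetitions where that mean is zero leave the ratio `NA` (the
#' count is reported via a message).
#'
#' @param sample_sizes Vector of per-cohort sample sizes `N`.
#' @param fst_values For `fst_mode = "fixed"`, the causal-locus F_ST values
#'   to sweep; for `"flexible"` a single background value used with `delta`.
#' @param h2_values Narrow-sense heritabilities to sweep.
#' @param trait_types Subset of `c("quantitative", "dichotomous")`.
#' @param n_reps Repetitions per cell (>= 2 so the SD is defined).
#' @param alpha_levels Significance thresholds to evaluate.
#' @param fst_mode `"fixed"` (constant causal F_ST per cell, background 0.2
#'   at null loci) or `"flexible"` (background + MAF-linked increment at
#'   causal loci).
#' @param n_loci,n_causal Locus counts (defaults 1000 / 100).
#' @param fst_background Background F_ST at non-causal loci (default 0.2).
#' @param delta MAF-linked increment for flexible mode (default 0.3).
#' @param admix_mean,admix_var Admixed-ancestry Beta moments.
#' @param prevalence Dichotomous-trait prevalence (default 0.05).
#' @param env_mode,anc_fraction Environment model.
#' @param maf_threshold Per-cohort MAF filter before testing (default 0).
#' @param seed Master seed; every repetition derives its own stream.
#' @return Long-format data frame, one row per cell x repetition x alpha,
#'   with per-population powers, the power ratio, and per-population false
#'   positive rates.
#' @export
run_power_grid <- function(sample_sizes = 1000L,
                           fst_values = c(0.2, 0.5, 0.8),
                           h2_values = 0.5,
                           trait_types = "quantitative",
                           n_reps = 20L,
                           alpha_levels = 0.05,
                           fst_mode = c("fixed", "flexible"),
                           n_loci = 1000L, n_causal = 100L,
                           fst_background = 0.2, delta = 0.3,
                           admix_mean = 0.75, admix_var = 0.02,
                           prevalence = 0.05,
                           env_mode = "gaussian_anc", anc_fraction = 0,
                           maf_threshold = 0, seed = 1L) {
  fst_mode <- match.arg(fst_mode)
  stopifnot(n_reps >= 2, all(trait_types %in% c("quantitative",
                                                "dichotomous")))
  cells <- expand.grid(n = sample_sizes, fst = fst_values, h2 = h2_values,
                       trait_type = trait_types, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells) * n_reps * length(alpha_levels))
  k <- 0L
  n_ratio_dropped <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    for (rep_i in seq_len(n_reps)) {
      s <- derive_seed(seed, "power_grid", cell$n, cell$fst, cell$h2,
                       cell$trait_type, rep_i)
      arch <- simulate_architecture(
        n_loci = n_loci, n_causal = n_causal,
        fst_background = if (fst_mode == "flexible") cell$fst
                         else fst_background,
        delta = delta,
        fst_causal = if (fst_mode == "fixed") cell$fst,
        seed = derive_seed(s, "arch"))
      cohorts <- simulate_three_cohorts(
        arch, n = cell$n, admix_mean = admix_mean, admix_var = admix_var,
        h2 = cell$h2, trait_type = cell$trait_type, prevalence = prevalence,
        env_mode = env_mode, anc_fraction = anc_fraction,
        seed = derive_seed(s, "cohorts"))
      scans <- lapply(cohorts, scan_cohort, maf_threshold = maf_threshold)
      null_idx <- setdiff(seq_len(n_loci), arch$causal_idx)
      for (alpha in alpha_levels) {
        pw <- vapply(scans, function(tab)
          power_estimate(tab, arch$causal_idx, alpha)$power_mean, numeric(1))
        fpr <- if (length(null_idx)) vapply(scans, function(tab)
          false_positive_rate(tab, null_idx, alpha)$fpr_mean, numeric(1))
          else rep(NA_real_, 3)
        anc_mean <- mean(c(pw[["pop1"]], pw[["pop2"]]))
        if (anc_mean == 0) n_ratio_dropped <- n_ratio_dropped + 1L
        k <- k + 1L
        rows[[k]] <- data.frame(
          n = cell$n, fst = cell$fst, h2 = cell$h2,
          trait_type = cell$trait_type, rep = rep_i, alpha = alpha,
          power_admixed = pw[["admixed"]], power_pop1 = pw[["pop1"]],
          power_pop2 = pw[["pop2"]],
          power_ratio = if (anc_mean > 0) pw[["admixed"]] / anc_mean
                        else NA_real_,
          fpr_admixed = fpr[[1]], fpr_pop1 = fpr[[2]], fpr_pop2 = fpr[[3]])
      }
    }
  }
  if (n_ratio_dropped > 0)
    message(n_ratio_dropped,
            " repetition(s) had zero mean ancestral power; ratio set to NA")
  do.call(rbind, rows)
}

#' Cross-population replication of discovered associations
#'
#' Quantifies the asymmetry in replication between the admixed cohort and
#' the major source population. Per repetition: simulate training cohorts
#' (default 10,000 individuals) and independent test cohorts (default
#' 1,000) for both populations under one shared architecture; restrict to
#' loci passing the MAF filter in both training cohorts; "discover" loci at
#' `alpha` in one population's training scan and re-test exactly those loci
#' in the other population's test-cohort scan at the same threshold. Both
#' directions (admixed to Population 1 and the reverse) are recorded, and a
#' one-sided Wilcoxon rank-sum test across repetitions asks whether
#' admixed-discovered signals replicate at a higher rate.
#'
#' @param n_train,n_test Training and test cohort sizes.
#' @param n_loci,n_causal Locus counts; the default makes every locus causal
#'   (high polygenicity, 1000 causal variants).
#' @param fst_causal Fixed F_ST at causal loci (default 0.5).
#' @param fst_background Background F_ST at any non-causal loci.
#' @param maf_threshold Per-cohort MAF filter (default 0.05).
#' @param alpha Discovery and replication threshold (default 0.05).
#' @param n_reps Number of repetitions.
#' @param restrict_to_causal Only count causal loci as discoverable?
#'   (default `FALSE`: all loci common in both cohorts are eligible).
#' @param paired Use a paired Wilcoxon signed-rank test across repetitions
#'   instead of the unpaired rank-sum (repetitions share architectures, so
#'   pairing is defensible; default unpaired).
#' @param h2,trait_type,prevalence,env_mode,anc_fraction,admix_mean,admix_var
#'   Cohort parameters as in [simulate_cohort()].
#' @param seed Master seed.
#' @return List of class `replication_result`: per-repetition data frame
#'   (`direction`, `rep`, `n_discovered`, `n_replicated`, `proportion`),
#'   per-direction mean proportions, and the one-sided Wilcoxon p-value for
#'   admixed-to-Pop1 exceeding Pop1-to-admixed.
#' @export
replication_experiment <- function(n_train = 10000L, n_test = 1000L,
                                   n_loci = 1000L, n_causal = 1000L,
                                   fst_causal = 0.5, fst_background = 0.2,
                                   maf_threshold = 0.05, alpha = 0.05,
                                   n_reps = 20L, restrict_to_causal = FALSE,
                                   paired = FALSE,
                                   h2 = 0.5, trait_type = "quantitative",
                                   prevalence = 0.05,
                                   env_mode = "gaussian_anc",
                                   anc_fraction = 0,
                                   admix_mean = 0.75, admix_var = 0.02,
                                   seed = 1L) {
  stopifnot(n_reps >= 2)
  rows <- vector("list", 2L * n_reps)
  k <- 0L
  for (rep_i in seq_len(n_reps)) {
    s <- derive_seed(seed, "replication", rep_i)
    arch <- simulate_architecture(n_loci = n_loci, n_causal = n_causal,
                                  fst_background = fst_background,
                                  fst_causal = fst_causal,
                                  seed = derive_seed(s, "arch"))
    sim_one <- function(pop, n, tag) {
      spec <- if (pop == "admixed") admixture_spec(admix_mean, admix_var, n)
              else ancestral_spec(1, n)
      simulate_cohort(arch, spec, h2 = h2, trait_type = trait_type,
                      prevalence = prevalence, env_mode = env_mode,
                      anc_fraction = anc_fraction, env_var = env_ref,
                      seed = derive_seed(s, tag))
    }
    env_ref <- NULL
    train_adx <- sim_one("admixed", n_train, "train_adx")
    env_ref <- train_adx$env_var
    train_p1 <- sim_one("pop1", n_train, "train_p1")
    test_adx <- sim_one("admixed", n_test, "test_adx")
    test_p1 <- sim_one("pop1", n_test, "test_p1")

    common <- maf_filter(train_adx$genotypes, maf_threshold) &
      maf_filter(train_p1$genotypes, maf_threshold)
    if (restrict_to_causal)
      common <- common & seq_len(n_loci) %in% arch$causal_idx

    scan_train_adx <- scan_cohort(train_adx, maf_threshold = maf_threshold)
    scan_train_p1 <- scan_cohort(train_p1, maf_threshold = maf_threshold)
    scan_test_adx <- scan_cohort(test_adx, maf_threshold = maf_threshold)
    scan_test_p1 <- scan_cohort(test_p1, maf_threshold = maf_threshold)

    sig <- function(tab, idx)
      idx[tab$tested[idx] & !is.na(tab$p[idx]) & tab$p[idx] <= alpha]
    eligible <- which(common)
    for (direction in c("ADMIXED->POP1", "POP1->ADMIXED")) {
      disc_tab <- if (direction == "ADMIXED->POP1") scan_train_adx
                  else scan_train_p1
      repl_tab <- if (direction == "ADMIXED->POP1") scan_test_p1
                  else scan_test_adx
      discovered <- sig(disc_tab, eligible)
      replicated <- sig(repl_tab, discovered)
      k <- k + 1L
      rows[[k]] <- data.frame(
        direction = direction, rep = rep_i,
        n_discovered = length(discovered),
        n_replicated = length(replicated),
        proportion = if (length(discovered)) length(replicated) /
          length(discovered) else NA_real_)
    }
  }
  per_rep <- do.call(rbind, rows)
  a2p <- per_rep$proportion[per_rep$direction == "ADMIXED->POP1"]
  p2a <- per_rep$proportion[per_rep$direction == "POP1->ADMIXED"]
  dropped <- sum(is.na(per_rep$proportion))
  if (dropped > 0)
    message(dropped, " repetition-direction(s) had zero discoveries")
  # ties across repetition proportions are routine; the normal approximation
  # wilcox.test falls back to is the intended behavior
  wt <- suppressWarnings(if (paired) {
    stats::wilcox.test(a2p, p2a, alternative = "greater", paired = TRUE)
  } else {
    stats::wilcox.test(a2p, p2a, alternative = "greater")
  })
  structure(
    list(per_rep = per_rep,
         mean_admixed_to_pop1 = mean(a2p, na.rm = TRUE),
         mean_pop1_to_admixed = mean(p2a, na.rm = TRUE),
         wilcoxon_p = wt$p.value, alpha = alpha, n_reps = n_reps,
         paired = paired),
    class = "replication_result"
  )
}

#' @export
print.replication_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Replication across %d repetitions (alpha = %g):\n",
    "  ADMIXED -> POP1: mean proportion %.3f\n",
    "  POP1 -> ADMIXED: mean proportion %.3f\n",
    "  one-sided Wilcoxon p = %.3g\n"),
    x$n_reps, x$alpha, x$mean_admixed_to_pop1, x$mean_pop1_to_admixed,
    x$wilcoxon_p))
  invisible(x)
}

#' Cross-population polygenic-score transferability
#'
#' Trains per-locus weights by association scans in large cohorts (default
#' 10,000 individuals) of each of the three populations, then constructs
#' estimated polygenic scores in independent test cohorts (default 1,000)
#' of every population, selecting training loci that pass the training
#' cohort's MAF filter and reach the chosen stringency. Accuracy is the
#' Pearson correlation between the estimated and true polygenic scores in
#' the test cohort; the result is the full 3x3 train-by-test matrix of mean
#' correlations across repetitions with bootstrap confidence intervals of
#' the mean.
#'
#' @param n_train,n_test Training and test cohort sizes.
#' @param n_loci,n_causal Locus counts (defaults 1000 / 1000).
#' @param fst_causal Fixed causal-locus F_ST, or `NULL` for the flexible
#'   background-plus-increment mode.
#' @param fst_background,delta Background F_ST and MAF-linked increment.
#' @param selection `"true_positives"` (significant loci that are truly
#'   causal) or `"all_positives"` (every significant locus).
#' @param alpha Stringency for selecting training loci (default 0.05).
#' @param maf_threshold Training-cohort MAF filter (default 0.05).
#' @param n_reps Repetitions.
#' @param n_boot Bootstrap resamples for the CI of the mean (default 1000).
#' @param h2,trait_type,prevalence,env_mode,anc_fraction,admix_mean,admix_var
#'   Cohort parameters as in [simulate_cohort()].
#' @param seed Master seed.
#' @return List of class `prs_accuracy`: `mean_r` (3x3 matrix,
#'   train x test), `ci_lower`/`ci_upper` (bootstrap 95% CIs), `per_rep`
#'   (long data frame), plus the settings.
#' @export
prs_transferability <- function(n_train = 10000L, n_test = 1000L,
                                n_loci = 1000L, n_causal = 1000L,
                                fst_causal = NULL,
                                fst_background = 0.2, delta = 0.3,
                                selection = c("true_positives",
                                              "all_positives"),
                                alpha = 0.05, maf_threshold = 0.05,
                                n_reps = 20L, n_boot = 1000L,
                                h2 = 0.5, trait_type = "quantitative",
                                prevalence = 0.05,
                                env_mode = "gaussian_anc", anc_fraction = 0,
                                admix_mean = 0.75, admix_var = 0.02,
                                seed = 1L) {
  selection <- match.arg(selection)
  pops <- c("admixed", "pop1", "pop2")
  rows <- vector("list", n_reps * 9L)
  k <- 0L
  for (rep_i in seq_len(n_reps)) {
    s <- derive_seed(seed, "prs", rep_i)
    arch <- simulate_architecture(n_loci = n_loci, n_causal = n_causal,
                                  fst_background = fst_background,
                                  delta = delta, fst_causal = fst_causal,
                                  seed = derive_seed(s, "arch"))
    make <- function(pop, n, tag, env_var = NULL) {
      spec <- switch(pop,
                     admixed = admixture_spec(admix_mean, admix_var, n),
                     pop1 = ancestral_spec(1, n),
                     pop2 = ancestral_spec(2, n))
      simulate_cohort(arch, spec, h2 = h2, trait_type = trait_type,
                      prevalence = prevalence, env_mode = env_mode,
                      anc_fraction = anc_fraction, env_var = env_var,
                      seed = derive_seed(s, tag))
    }
    train <- list(admixed = make("admixed", n_train, "train_admixed"))
    env_ref <- train$admixed$env_var
    train$pop1 <- make("pop1", n_train, "train_pop1", env_ref)
    train$pop2 <- make("pop2", n_train, "train_pop2", env_ref)
    test <- list(admixed = make("admixed", n_test, "test_admixed", env_ref),
                 pop1 = make("pop1", n_test, "test_pop1", env_ref),
                 pop2 = make("pop2", n_test, "test_pop2", env_ref))
    scans <- lapply(train, scan_cohort, maf_threshold = maf_threshold)
    for (tr in pops) {
      tab <- scans[[tr]]
      sel <- tab$tested & !is.na(tab$p) & tab$p <= alpha
      if (selection == "true_positives")
        sel <- sel & seq_len(n_loci) %in% arch$causal_idx
      sel_idx <- which(sel)
      for (te in pops) {
        r <- NA_real_
        if (length(sel_idx)) {
          g_test <- test[[te]]$genotypes$dosages[, sel_idx, drop = FALSE]
          prs_hat <- drop(g_test %*% tab$beta[sel_idx])
          prs_true <- test[[te]]$phenotype$prs
          if (stats::sd(prs_hat) > 0 && stats::sd(prs_true) > 0)
            r <- stats::cor(prs_hat, prs_true)
        }
        k <- k + 1L
        rows[[k]] <- data.frame(train = tr, test = te, rep = rep_i,
                                n_selected = length(sel_idx), r = r)
      }
    }
  }
  per_rep <- do.call(rbind, rows)
  mean_r <- ci_lo <- ci_hi <- matrix(NA_real_, 3, 3,
                                     dimnames = list(train = pops,
                                                     test = pops))
  boot_seed <- derive_seed(seed, "prs", "boot")
  for (tr in pops) for (te in pops) {
    rs <- per_rep$r[per_rep$train == tr & per_rep$test == te]
    rs <- rs[!is.na(rs)]
    if (!length(rs)) next
    mean_r[tr, te] <- mean(rs)
    bm <- with_seed(derive_seed(boot_seed, tr, te), {
      vapply(seq_len(n_boot), function(i)
        mean(sample(rs, replace = TRUE)), numeric(1))
    })
    ci_lo[tr, te] <- stats::quantile(bm, 0.025, names = FALSE)
    ci_hi[tr, te] <- stats::quantile(bm, 0.975, names = FALSE)
  }
  structure(
    list(mean_r = mean_r, ci_lower = ci_lo, ci_upper = ci_hi,
         per_rep = per_rep, selection = selection, alpha = alpha,
         n_reps = n_reps),
    class = "prs_accuracy"
  )
}

#' @export
print.prs_accuracy <- function(x, ...) {
  cat(sprintf(
    "PRS transfer accuracy (%s, alpha = %g, %d repetitions):\n",
    x$selection, x$alpha, x$n_reps))
  print(round(x$mean_r, 3))
  invisible(x)
}

#' Power to detect a trait-ancestry correlation without genotypes
#'
#' A genotype-free side calculation: is a sample large enough to observe a
#' dichotomous trait's correlation with global ancestry? Per repetition,
#' global ancestry is drawn from the admixture spec and case status from a
#' logistic model in ancestry, with the intercept solved numerically so the
#' expected prevalence equals the target incidence; the trait is then
#' tested against ancestry by logistic regression. Power is the proportion
#' of repetitions reaching significance.
#'
#' @param incidence Target case prevalence in (0, 1).
#' @param ancestry_effect Log-odds of case status per unit of ancestry
#'   fraction (0 gives the null calibration).
#' @param n Sample size per repetition.
#' @param n_reps Number of repetitions.
#' @param alpha Significance threshold (default 0.05).
#' @param admix_mean,admix_var Ancestry Beta moments.
#' @param seed Master seed.
#' @return List with `power`, `n_significant`, `n_reps`, `alpha`.
#' @export
ancestry_trait_power_estimate <- function(incidence, ancestry_effect, n,
                                          n_reps = 200L, alpha = 0.05,
                                          admix_mean = 0.75,
                                          admix_var = 0.02, seed = 1L) {
  stopifnot(incidence > 0, incidence < 1, n >= 10)
  if (incidence * n < 5)
    warning("fewer than 5 expected cases; logistic fits will be unstable")
  spec <- admixture_spec(admix_mean, admix_var, n)
  sig <- logical(n_reps)
  for (rep_i in seq_len(n_reps)) {
    sig[rep_i] <- with_seed(derive_seed(seed, "anc_trait", rep_i), {
      theta <- sample_global_ancestry(spec)
      b0 <- stats::uniroot(function(b)
        mean(stats::plogis(b + ancestry_effect * theta)) - incidence,
        interval = c(-50, 50), tol = 1e-10)$root
      y <- stats::rbinom(n, 1, stats::plogis(b0 + ancestry_effect * theta))
      if (length(unique(y)) < 2) return(FALSE)
      fit <- stats::glm(y ~ theta, family = stats::binomial())
      stats::coef(summary(fit))["theta", "Pr(>|z|)"] <= alpha
    })
  }
  list(power = mean(sig), n_significant = sum(sig), n_reps = n_reps,
       alpha = alpha)
}
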