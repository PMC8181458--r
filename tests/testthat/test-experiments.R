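test_that("the power grid is reproducible and reports coherent summaries", {
  run <- function() suppressWarnings(suppressMessages(
    run_power_grid(sample_sizes = 400, fst_values = 0.5, h2_values = 0.5,
                   trait_types = "quantitative", n_reps = 3,
                   alpha_levels = c(0.05, 5e-4), fst_mode = "fixed",
                   n_loci = 200, n_causal = 20, seed = 77)))
  r1 <- run()
  r2 <- run()
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 3 * 2)
  expect_true(all(r1$power_admixed >= 0 & r1$power_admixed <= 1))
  # stricter alpha never increases power, per repetition and population
  for (rep_i in unique(r1$rep)) {
    loose <- r1[r1$rep == rep_i & r1$alpha == 0.05, ]
    strict <- r1[r1$rep == rep_i & r1$alpha == 5e-4, ]
    expect_true(all(strict[, c("power_admixed", "power_pop1",
                               "power_pop2")] <=
                      loose[, c("power_admixed", "power_pop1",
                                "power_pop2")]))
  }
})

test_that("power increases with sample size", {
  res <- suppressWarnings(suppressMessages(
    run_power_grid(sample_sizes = c(250, 2000), fst_values = 0.5,
                   h2_values = 0.5, trait_types = "quantitative",
                   n_reps = 4, fst_mode = "fixed", n_loci = 200,
                   n_causal = 20, seed = 88)))
  m <- aggregate(power_admixed ~ n, res, mean)
  expect_gt(m$power_admixed[m$n == 2000], m$power_admixed[m$n == 250])
})

test_that("self-replication is complete and degenerate thresholds saturate", {
  # a cohort's own discoveries replicate in itself by construction
  arch <- small_arch(n_loci = 200, n_causal = 200, fst_causal = 0.5,
                     seed = 91)
  coh <- simulate_cohort(arch, admixture_spec(0.75, 0.02, 1500), h2 = 0.5,
                         seed = 92)
  tab <- scan_cohort(coh, maf_threshold = 0.05)
  disc <- which(tab$tested & tab$p <= 0.05)
  expect_gt(length(disc), 0)
  re_sig <- tab$tested[disc] & tab$p[disc] <= 0.05
  expect_true(all(re_sig))

  # alpha = 1: every tested locus is discovered, and every discovered locus
  # still tested in the reciprocal cohort replicates (only loci that drop
  # below the MAF filter or go monomorphic in the smaller test cohort fail)
  res <- suppressMessages(replication_experiment(
    n_train = 400, n_test = 400, n_loci = 100, n_causal = 100,
    fst_causal = 0.5, alpha = 1, n_reps = 2, seed = 93))
  expect_true(all(res$per_rep$n_replicated <= res$per_rep$n_discovered))
  expect_true(all(res$per_rep$proportion >= 0.9))
  expect_gt(mean(res$per_rep$proportion), 0.95)
})

test_that("replication bookkeeping respects its invariants", {
  res <- suppressMessages(replication_experiment(
    n_train = 600, n_test = 300, n_loci = 150, n_causal = 150,
    fst_causal = 0.5, n_reps = 3, seed = 94))
  expect_true(all(res$per_rep$n_replicated <= res$per_rep$n_discovered))
  expect_equal(nrow(res$per_rep), 6)
  expect_true(res$wilcoxon_p > 0 && res$wilcoxon_p <= 1)
  # paired variant runs too
  resp <- suppressMessages(replication_experiment(
    n_train = 600, n_test = 300, n_loci = 150, n_causal = 150,
    fst_causal = 0.5, n_reps = 3, paired = TRUE, seed = 94))
  expect_true(resp$paired)
})

test_that("PRS estimation approaches the truth within one population", {
  # all causal loci selected, large training cohort, same-population test
  res <- prs_transferability(n_train = 4000, n_test = 500, n_loci = 100,
                             n_causal = 100, fst_causal = 0.2,
                             alpha = 1, maf_threshold = 0, n_reps = 2,
                             n_boot = 100, seed = 95)
  expect_gt(res$mean_r["pop1", "pop1"], 0.95)
  expect_gt(res$mean_r["admixed", "admixed"], 0.95)
  expect_true(all(res$per_rep$r >= -1 & res$per_rep$r <= 1, na.rm = TRUE))
  expect_true(all(res$ci_lower <= res$mean_r & res$mean_r <= res$ci_upper))
})

test_that("admixed-trained weights transfer to a source population better
          than the other source population's weights do", {
  res <- prs_transferability(n_train = 3000, n_test = 500, n_loci = 300,
                             n_causal = 300, fst_causal = 0.5,
                             n_reps = 4, n_boot = 100, seed = 96)
  expect_gt(res$mean_r["admixed", "pop1"], res$mean_r["pop2", "pop1"])
  expect_gt(res$mean_r["admixed", "pop2"], res$mean_r["pop1", "pop2"])
})

test_that("ancestry-trait power is calibrated at zero effect and monotone", {
  null_pow <- ancestry_trait_power_estimate(0.2, 0, n = 500, n_reps = 300,
                                            seed = 97)$power
  expect_lt(abs(null_pow - 0.05), 0.04)
  # monotone in n and in effect size
  p_small <- ancestry_trait_power_estimate(0.2, 2, n = 150, n_reps = 120,
                                           seed = 98)$power
  p_large <- ancestry_trait_power_estimate(0.2, 2, n = 2000, n_reps = 120,
                                           seed = 98)$power
  expect_gte(p_large, p_small)
  p_weak <- ancestry_trait_power_estimate(0.2, 0.5, n = 800, n_reps = 120,
                                          seed = 99)$power
  p_strong <- ancestry_trait_power_estimate(0.2, 4, n = 800, n_reps = 120,
                                            seed = 99)$power
  expect_gte(p_strong, p_weak)
  expect_warning(ancestry_trait_power_estimate(0.05, 1, n = 60, n_reps = 2,
                                               seed = 1), "unstable")
})
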