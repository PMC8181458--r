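test_that("effect signs follow the ancestral-frequency trial", {
  # symmetric frequencies: sign is +1 with probability exactly 0.5
  n <- 20000
  fr_sym <- manual_freqs(p1 = rep(0.4, n), p2 = rep(0.4, n))
  w <- assign_effects(fr_sym, seq_len(n), seed = 1)
  expect_lt(abs(mean(w > 0) - 0.5), 0.015)

  # q = p1/(p1+p2): at (0.99, 0.01), positive with probability 0.99
  fr_skew <- manual_freqs(p1 = rep(0.99, n), p2 = rep(0.01, n))
  w2 <- assign_effects(fr_skew, seq_len(n), seed = 2)
  expect_lt(abs(mean(w2 > 0) - 0.99), 0.005)

  # magnitudes are |N(0,1)|: E|Z| = sqrt(2/pi)
  expect_lt(abs(mean(abs(w)) - sqrt(2 / pi)), 0.02)

  # capped-ratio mode: p1 >= p2 forces a positive sign
  w3 <- assign_effects(fr_skew, seq_len(n), sign_mode = "ratio", seed = 3)
  expect_true(all(w3 > 0))

  fr_dead <- manual_freqs(p1 = c(0.5, 0), p2 = c(0.5, 0))
  expect_error(assign_effects(fr_dead, 1:2), "undefined")
})

test_that("effect signs induce a positive PRS-ancestry correlation", {
  # the stated purpose of the sign trial, checked across repetitions
  pos <- 0
  for (i in 1:20) {
    arch <- simulate_architecture(n_loci = 150, n_causal = 100,
                                  fst_causal = 0.5, seed = 100 + i)
    spec <- admixture_spec(0.75, 0.02, 1000)
    th <- sample_global_ancestry(spec, seed = 200 + i)
    gs <- sample_genotypes(arch$freqs, theta = th, seed = 300 + i)
    prs <- compute_prs(gs, arch$causal_idx, arch$weights)
    pos <- pos + (cor(prs, th) > 0)
  }
  expect_gte(pos, 18)  # >= 90% of repetitions
})

test_that("the polygenic score is the additive dosage-weight sum", {
  G <- matrix(c(0L, 1L, 2L), 3, 1)
  expect_equal(compute_prs(G, 1, 1.5), c(0, 1.5, 3.0))
  G2 <- matrix(rbinom(50 * 4, 2, 0.4), 50, 4)
  expect_equal(compute_prs(G2, 1:4, rep(0, 4)), rep(0, 50))
  w <- c(0.5, -1, 2, 0.1)
  prs <- compute_prs(G2, 1:4, w)
  perm <- sample(50)
  expect_equal(compute_prs(G2[perm, ], 1:4, w), prs[perm])
})

test_that("environment scaling yields the target heritability exactly", {
  set.seed(4)
  th <- sample_global_ancestry(admixture_spec(0.75, 0.02, 1e4))
  prs <- th * 2 + rnorm(1e4)
  vg <- var(prs)
  for (h2 in c(0.2, 0.5, 0.8)) {
    env <- simulate_environment(th, vg, h2, seed = 5)
    expect_equal(var(env), vg * (1 - h2) / h2, tolerance = 1e-10)
    y <- prs + env
    expect_lt(abs(vg / var(y) - h2), 0.02)
  }
  expect_identical(simulate_environment(th, vg, 1), rep(0, 1e4))
  expect_error(simulate_environment(th, vg, 0), "h2")
})

test_that("linear ancestry confounding explains its configured variance share", {
  set.seed(6)
  th <- sample_global_ancestry(admixture_spec(0.75, 0.02, 1e4))
  prs <- th * 2 + rnorm(1e4)
  vg <- var(prs)
  env <- simulate_environment(th, vg, h2 = 0.5, env_mode = "linear_anc",
                              anc_fraction = 0.10, seed = 7)
  expect_equal(var(env), vg, tolerance = 1e-10)  # (1-h2)/h2 = 1
  # variance of the ancestry term alone, as a share of total phenotypic
  # variance, equals anc_fraction
  lambda_term <- env - residuals(lm(env ~ th))
  expect_lt(abs(var(lambda_term) / (vg / 0.5) - 0.10), 0.02)
})

test_that("both environment modes reduce to plain noise in homogeneous cohorts", {
  th <- rep(1, 5000)
  for (mode in c("gaussian_anc", "linear_anc")) {
    env <- simulate_environment(th, var_g = 2, h2 = 0.5, env_mode = mode,
                                anc_fraction = if (mode == "linear_anc")
                                  0.1 else 0, seed = 8)
    expect_equal(var(env), 2, tolerance = 1e-10)
    expect_gt(shapiro.test(env[1:3000])$p.value, 1e-4)
  }
})

test_that("the liability threshold produces an exact case count", {
  set.seed(9)
  ph <- assemble_phenotype(rnorm(1000), rnorm(1000), "dichotomous", 0.05)
  expect_equal(sum(ph$y_binary), 50L)
  expect_equal(ph$y_quant, ph$prs + ph$env)
  # prevalence 0.5 with symmetric scores: cases are the upper half
  y <- seq(-1, 1, length.out = 100)
  ph2 <- assemble_phenotype(y, rep(0, 100), "dichotomous", 0.5)
  expect_equal(ph2$y_binary, rep(c(0L, 1L), each = 50))
  # location shift leaves case assignment unchanged
  ph3 <- assemble_phenotype(y + 100, rep(0, 100), "dichotomous", 0.5)
  expect_identical(ph2$y_binary, ph3$y_binary)
})

test_that("realized heritability matches the target in a full cohort", {
  arch <- small_arch(seed = 13)
  coh <- simulate_cohort(arch, admixture_spec(0.75, 0.02, 1e4), h2 = 0.5,
                         seed = 14)
  vg <- var(coh$phenotype$prs)
  expect_lt(abs(vg / var(coh$phenotype$y_quant) - 0.5), 0.02)
})

test_that("source-population phenotype means separate at moderate F_ST", {
  # with signs favoring Population-1-frequent alleles, Pop1 means exceed
  # Pop2 means in >= 90% of repetitions
  sep <- 0
  for (i in 1:10) {
    arch <- small_arch(n_loci = 200, n_causal = 50, fst_causal = 0.2,
                       seed = 400 + i)
    coh <- simulate_three_cohorts(arch, n = 500, h2 = 0.5, seed = 500 + i)
    sep <- sep + (mean(coh$pop1$phenotype$y_quant) >
                    mean(coh$pop2$phenotype$y_quant))
  }
  expect_gte(sep, 9)
})

test_that("phenotype-ancestry correlation increases with causal F_ST", {
  mean_corr <- vapply(c(0.2, 0.5, 0.8), function(f) {
    corrs <- vapply(1:8, function(i) {
      arch <- simulate_architecture(n_loci = 300, n_causal = 100,
                                    fst_causal = f,
                                    seed = round(1e4 * f) + i)
      coh <- simulate_cohort(arch, admixture_spec(0.75, 0.02, 500),
                             h2 = 0.5, seed = round(2e4 * f) + i)
      cor(coh$phenotype$y_quant, coh$theta)
    }, numeric(1))
    mean(corrs)
  }, numeric(1))
  expect_true(all(mean_corr > 0))
  expect_true(all(diff(mean_corr) > 0))
})
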