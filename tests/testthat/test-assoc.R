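test_that("the linear scan reproduces per-locus lm() Wald results", {
  set.seed(1)
  n <- 150
  G <- matrix(rbinom(n * 8, 2, 0.3), n, 8)
  th <- runif(n)
  y <- 0.5 * G[, 3] + th + rnorm(n)
  tab <- assoc_scan(G, y, covar = th, mode = "linear")
  for (j in c(1, 3, 6)) {
    cf <- summary(lm(y ~ G[, j] + th))$coefficients
    expect_equal(tab$beta[j], unname(cf[2, 1]))
    expect_equal(tab$se[j], unname(cf[2, 2]))
    expect_equal(tab$p[j], unname(cf[2, 4]))
  }
  # and without the covariate
  tab0 <- assoc_scan(G, y, mode = "linear")
  cf0 <- summary(lm(y ~ G[, 3]))$coefficients
  expect_equal(tab0$beta[3], unname(cf0[2, 1]))
  expect_equal(tab0$p[3], unname(cf0[2, 4]))
})

test_that("the logistic scan reproduces per-locus glm() Wald results", {
  set.seed(2)
  n <- 300
  G <- matrix(rbinom(n * 8, 2, runif(8, 0.1, 0.5)), n, 8, byrow = TRUE)
  th <- runif(n)
  yb <- rbinom(n, 1, plogis(-1.5 + G[, 2] + th))
  tab <- assoc_scan(G, yb, covar = th, mode = "logistic")
  for (j in c(2, 5, 8)) {
    cf <- summary(glm(yb ~ G[, j] + th, family = binomial))$coefficients
    expect_equal(tab$beta[j], unname(cf[2, 1]), tolerance = 1e-5)
    expect_equal(tab$se[j], unname(cf[2, 2]), tolerance = 1e-5)
    expect_equal(tab$p[j], unname(cf[2, 4]), tolerance = 1e-4)
  }
  tab0 <- assoc_scan(G, yb, mode = "logistic")
  cf0 <- summary(glm(yb ~ G[, 4], family = binomial))$coefficients
  expect_equal(tab0$beta[4], unname(cf0[2, 1]), tolerance = 1e-5)
})

test_that("a perfect signal yields an essentially zero p-value", {
  set.seed(3)
  G <- matrix(rbinom(100 * 5, 2, 0.4), 100, 5)
  y <- as.numeric(G[, 2])
  tab <- assoc_scan(G, y, mode = "linear")
  expect_lt(tab$p[2], 1e-10)
})

test_that("monomorphic and filtered loci are marked untested", {
  set.seed(4)
  G <- cbind(rep(0L, 200), rbinom(200, 2, 0.5), rbinom(200, 2, 0.02))
  y <- rnorm(200)
  tab <- assoc_scan(G, y, mode = "linear")
  expect_false(tab$tested[1])
  expect_true(is.na(tab$p[1]))
  expect_true(tab$tested[2])
  # MAF filter: rare locus 3 removed at a 5% threshold
  tab5 <- assoc_scan(G, y, mode = "linear", maf_threshold = 0.05)
  expect_false(tab5$tested[3])
})

test_that("the MAF filter boundary is inclusive and per-cohort", {
  # 10 carriers of 100 diploids: sample MAF exactly 0.05
  G <- matrix(0L, 100, 2)
  G[1:10, 1] <- 1L
  G[1:30, 2] <- 1L
  expect_identical(maf_filter(G, 0.05), c(TRUE, TRUE))
  expect_identical(maf_filter(G, 0.10), c(FALSE, TRUE))
  expect_identical(maf_filter(G, 0), c(TRUE, TRUE))
  expect_identical(unname(maf_filter(matrix(0L, 50, 1), 0.01)), FALSE)
})

test_that("a permuted phenotype is rejected at the nominal rate", {
  fr <- locus_frequencies(1000, fst_background = 0.2, seed = 21)
  th <- sample_global_ancestry(admixture_spec(0.75, 0.02, 800), seed = 22)
  gs <- sample_genotypes(fr, theta = th, seed = 23)
  set.seed(24)
  y <- sample(rnorm(800))  # pure noise, independent of all genotypes
  tab <- assoc_scan(gs, y, covar = th, mode = "linear")
  fpr <- false_positive_rate(tab, 1:1000, 0.05)$fpr_mean
  expect_lt(abs(fpr - 0.05), 0.02)
})

test_that("power and FPR summaries follow their definitions", {
  mk <- function(p) {
    structure(data.frame(locus = seq_along(p), beta = 0, se = 1, p = p,
                         tested = !is.na(p), maf = 0.3),
              class = c("assoc_table", "data.frame"))
  }
  # all causal significant / none significant
  expect_equal(power_estimate(mk(rep(1e-12, 10)), 1:5, 0.05)$power_mean, 1)
  expect_equal(power_estimate(mk(rep(0.9, 10)), 1:5, 0.05)$power_mean, 0)
  # untested loci count as non-significant
  expect_equal(power_estimate(mk(c(1e-9, NA, 1e-9, NA)), 1:4,
                              0.05)$power_mean, 0.5)
  # two repetitions at 0.4 and 0.6: mean 0.5, SD sqrt(0.02) = 0.1414...
  two <- list(mk(c(rep(0.01, 4), rep(0.9, 6))),
              mk(c(rep(0.01, 6), rep(0.9, 4))))
  ps <- power_estimate(two, 1:10, 0.05)
  expect_equal(ps$power_mean, 0.5)
  expect_equal(ps$power_sd, sd(c(0.4, 0.6)))
  # FPR degenerate thresholds
  tab <- mk(runif(100))
  expect_equal(false_positive_rate(tab, 1:100, 0)$fpr_mean, 0)
  expect_equal(false_positive_rate(tab, 1:100, 1)$fpr_mean, 1)
  # inclusive comparison p <= alpha
  expect_equal(power_estimate(mk(rep(0.05, 4)), 1:4, 0.05)$power_mean, 1)
})

test_that("power is monotone non-increasing in stringency", {
  arch <- small_arch(seed = 31)
  coh <- simulate_three_cohorts(arch, n = 1000, h2 = 0.5, seed = 32)
  tab <- scan_cohort(coh$admixed)
  pw <- vapply(c(0.05, 5e-4, 5e-6, 5e-8), function(a)
    power_estimate(tab, arch$causal_idx, a)$power_mean, numeric(1))
  expect_true(all(diff(pw) <= 0))
})

test_that("omitting the ancestry covariate inflates false positives", {
  # strongly differentiated null loci + ancestry-correlated phenotype
  fpr_with <- fpr_wo <- numeric(3)
  for (i in 1:3) {
    arch <- simulate_architecture(n_loci = 500, n_causal = 50,
                                  fst_background = 0.5, fst_causal = 0.5,
                                  seed = 600 + i)
    coh <- simulate_cohort(arch, admixture_spec(0.75, 0.02, 800), h2 = 0.5,
                           seed = 700 + i)
    nul <- setdiff(1:500, arch$causal_idx)
    y <- coh$phenotype$y_quant
    s1 <- assoc_scan(coh$genotypes, y, covar = coh$theta, mode = "linear")
    s0 <- assoc_scan(coh$genotypes, y, mode = "linear")
    fpr_with[i] <- false_positive_rate(s1, nul, 0.05)$fpr_mean
    fpr_wo[i] <- false_positive_rate(s0, nul, 0.05)$fpr_mean
  }
  expect_true(all(fpr_wo > fpr_with))
})
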