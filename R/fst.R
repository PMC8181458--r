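#' Weir-Cockerham F_ST from two genotype samples
#'
#' Variance-components estimator of F_ST (theta) between two populations
#' from diploid dosage matrices, used here to validate that simulated
#' genotypes recover their generative divergence parameter. For each locus
#' the among-population (`a`), among-individual (`b`) and within-individual
#' (`c`) components are computed from sample allele frequencies and observed
#' heterozygosity; the per-locus estimate is `a / (a + b + c)` and the
#' multi-locus estimate is the ratio of averages `sum(a) / sum(a + b + c)`.
#' Per-locus estimates are not truncated and can be negative at
#' undifferentiated loci. Loci monomorphic for the same allele in both
#' samples carry no information and are excluded from the multi-locus
#' average.
#'
#' @param dosages_pop1,dosages_pop2 Integer matrices (individuals x loci,
#'   allele counts 0/1/2) over the same loci, each with >= 2 individuals.
#' @return List with `per_locus` (numeric vector, `NA` at excluded loci),
#'   `overall` (ratio-of-averages estimate), and `n_loci_used`.
#' @examples
#' fr <- locus_frequencies(200, seed = 1)
#' g1 <- sample_genotypes(fr, theta = rep(1, 50), seed = 2)$dosages
#' g2 <- sample_genotypes(fr, theta = rep(0, 50), seed = 3)$dosages
#' wc_fst(g1, g2)$overall
#' @export
wc_fst <- function(dosages_pop1, dosages_pop2) {
  stopifnot(is.matrix(dosages_pop1), is.matrix(dosages_pop2),
            ncol(dosages_pop1) == ncol(dosages_pop2),
            nrow(dosages_pop1) >= 2, nrow(dosages_pop2) >= 2)
  r <- 2  # number of populations
  n1 <- nrow(dosages_pop1)
  n2 <- nrow(dosages_pop2)
  p1 <- colMeans(dosages_pop1) / 2
  p2 <- colMeans(dosages_pop2) / 2
  h1 <- colMeans(dosages_pop1 == 1L)
  h2 <- colMeans(dosages_pop2 == 1L)

  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  denom <- a + b + cc
  informative <- denom != 0 & !(pbar %in% c(0, 1) & s2 == 0)
  per_locus <- ifelse(informative, a / denom, NA_real_)
  overall <- sum(a[informative]) / sum(denom[informative])
  list(per_locus = per_locus, overall = overall,
       n_loci_used = sum(informative))
}
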