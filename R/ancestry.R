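#' Beta shape parameters from ancestry mean and variance
#'
#' Global ancestry in a two-way admixed population is modeled as a Beta
#' distribution parameterized by its first two moments: the population mean
#' `m` and variance `v` of the Population-1 ancestry fraction. The
#' method-of-moments shapes are
#' \deqn{a = m\left(\frac{m(1-m)}{v} - 1\right), \qquad b = \frac{1-m}{m}\,a,}
#' so that `Beta(a, b)` has mean exactly `m` and variance exactly `v`.
#'
#' @param m Mean ancestry fraction, in (0, 1).
#' @param v Variance of the ancestry fraction; must satisfy
#'   `0 < v < m * (1 - m)`, otherwise the implied shapes are non-positive.
#' @return Named numeric vector `c(shape1, shape2)`.
#' @examples
#' beta_shapes_from_moments(0.5, 0.05)   # Beta(2, 2)
#' @export
beta_shapes_from_moments <- function(m, v) {
  stopifnot(is.numeric(m), is.numeric(v), length(m) == 1L, length(v) == 1L)
  if (!(m > 0 && m < 1))
    stop("ancestry mean `m` must lie strictly in (0, 1), got ", m)
  if (!(v > 0 && v < m * (1 - m)))
    stop("ancestry variance `v` must lie strictly in (0, m*(1-m)) = (0, ",
         format(m * (1 - m)), "); got ", v)
  a <- m * (m * (1 - m) / v - 1)
  b <- (1 - m) / m * a
  c(shape1 = a, shape2 = b)
}

#' Specify a two-way admixed cohort's ancestry distribution
#'
#' Bundles the mean and variance of the Population-1 global ancestry fraction
#' with a cohort size, validating feasibility of the implied Beta
#' distribution. The degenerate source populations are represented by
#' `ancestral_spec()`.
#'
#' @param mean Mean Population-1 ancestry fraction, in (0, 1). The default
#'   0.75 approximates the average West African ancestry fraction in African
#'   Americans.
#' @param variance Variance of the ancestry fraction (default 0.02).
#' @param n_individuals Number of diploid individuals (>= 1).
#' @return An object of class `admixture_spec`.
#' @seealso [sample_global_ancestry()], [ancestral_spec()]
#' @export
admixture_spec <- function(mean = 0.75, variance = 0.02, n_individuals = 1000L) {
  beta_shapes_from_moments(mean, variance)  # validates (mean, variance)
  n_individuals <- as.integer(n_individuals)
  stopifnot(length(n_individuals) == 1L, n_individuals >= 1L)
  structure(
    list(mean = mean, variance = variance, n_individuals = n_individuals),
    class = "admixture_spec"
  )
}

#' Specify a homogeneous (non-admixed) source population
#'
#' A source population is the degenerate case of admixture with all ancestry
#' from one side: theta identically 1 (Population 1) or 0 (Population 2).
#' Cohorts built from such a spec pass through the same genotype and
#' phenotype machinery as admixed cohorts, which guarantees the three cohorts
#' share locus frequencies and genetic architecture.
#'
#' @param population 1 or 2.
#' @param n_individuals Number of diploid individuals.
#' @return An object of class `admixture_spec` with zero ancestry variance.
#' @export
ancestral_spec <- function(population, n_individuals = 1000L) {
  stopifnot(population %in% c(1, 2))
  n_individuals <- as.integer(n_individuals)
  stopifnot(n_individuals >= 1L)
  structure(
    list(mean = if (population == 1) 1 else 0, variance = 0,
         n_individuals = n_individuals, population = as.integer(population)),
    class = "admixture_spec"
  )
}

#' @export
print.admixture_spec <- function(x, ...) {
  if (x$variance == 0) {
    cat(sprintf("Homogeneous Population %d cohort: %d individuals\n",
                if (x$mean == 1) 1L else 2L, x$n_individuals))
  } else {
    cat(sprintf(
      "Admixed cohort: %d individuals, Pop1 ancestry ~ Beta(mean = %g, var = %g)\n",
      x$n_individuals, x$mean, x$variance))
  }
  invisible(x)
}

#' Sample global ancestry fractions
#'
#' Draws each individual's genome-wide Population-1 ancestry fraction
#' \eqn{\theta_i} from the Beta distribution implied by the spec's mean and
#' variance. Draws are clipped to `[1e-6, 1 - 1e-6]` so that downstream
#' binomial sampling and regression scans remain well-posed at the corners;
#' homogeneous specs return exactly 0 or 1.
#'
#' @param spec An [admixture_spec()] or [ancestral_spec()].
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return Numeric vector of length `n_individuals`, entries in `[0, 1]`.
#' @examples
#' theta <- sample_global_ancestry(admixture_spec(0.75, 0.02, 500), seed = 1)
#' mean(theta)
#' @export
sample_global_ancestry <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "admixture_spec"))
  with_seed(seed, {
    if (spec$variance == 0) {
      rep(spec$mean, spec$n_individuals)
    } else {
      sh <- beta_shapes_from_moments(spec$mean, spec$variance)
      th <- stats::rbeta(spec$n_individuals, sh[["shape1"]], sh[["shape2"]])
      pmin(pmax(th, 1e-6), 1 - 1e-6)
    }
  })
}

#' Sample per-haplotype local ancestry
#'
#' At each of `n_loci` LD-independent loci, each of an individual's two
#' haplotype copies descends from Population 1 with probability equal to that
#' individual's global ancestry \eqn{\theta_i}, independently across loci and
#' haplotypes (so the Population-1 haplotype count at a locus is
#' Binomial(2, \eqn{\theta_i})).
#'
#' @param theta Numeric vector of global ancestry fractions in `[0, 1]`.
#' @param n_loci Number of loci (>= 1).
#' @param seed Optional integer seed.
#' @return Integer array `n_individuals x n_loci x 2` with entries 1
#'   (Population 1) or 2 (Population 2).
#' @export
sample_local_ancestry <- function(theta, n_loci, seed = NULL) {
  stopifnot(is.numeric(theta), all(theta >= 0 & theta <= 1), n_loci >= 1)
  n <- length(theta)
  n_loci <- as.integer(n_loci)
  with_seed(seed, {
    u <- array(stats::runif(n * n_loci * 2L), dim = c(n, n_loci, 2L))
    la <- array(2L, dim = c(n, n_loci, 2L))
    la[u < theta] <- 1L  # theta recycles along the first dimension
    la
  })
}
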