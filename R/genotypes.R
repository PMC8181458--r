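#' Draw ancestral allele frequencies
#'
#' Per-locus allele frequencies in the common ancestor of the two source
#' populations, drawn i.i.d. uniform on `[0.001, 0.999]` (common-variant
#' focus; the narrow support keeps Balding-Nichols Beta shapes finite).
#'
#' @param n_loci Number of loci.
#' @param lower,upper Support of the uniform draw.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n_loci`.
#' @export
draw_ancestral_freqs <- function(n_loci, lower = 0.001, upper = 0.999,
                                 seed = NULL) {
  stopifnot(n_loci >= 1, lower > 0, upper < 1, lower < upper)
  with_seed(seed, stats::runif(n_loci, lower, upper))
}

#' Effective F_ST at a locus as a function of ancestral rarity
#'
#' Divergence at a locus is modeled as a genome-wide background F_ST plus an
#' increment that grows as the ancestral minor allele becomes rarer:
#' \deqn{F_{ST} = F_{ST}^{G} + (1 - \mathrm{MAF}_a)\,\delta}
#' with \eqn{\mathrm{MAF}_a = \min(p_s, 1 - p_s)}. Rare ancestral variants
#' drift to more different frequencies in diverged populations, especially
#' under a bottleneck; the increment mimics that. With `delta = 0` the locus
#' F_ST is simply the fixed background value. The result is clamped to
#' `[1e-4, 1 - 1e-4]` so the implied Balding-Nichols Beta shapes stay
#' positive when a large background plus increment would exceed 1.
#'
#' @param p_s Ancestral allele frequency (vectorized).
#' @param fst_background Genome-wide background F_ST, in (0, 1).
#' @param delta Increment per unit decrease of ancestral MAF (default 0.3).
#' @return Numeric vector of per-locus effective F_ST values.
#' @examples
#' effective_fst(0.5, 0.2, 0.3)   # 0.35
#' @export
effective_fst <- function(p_s, fst_background, delta = 0.3) {
  stopifnot(fst_background > 0, fst_background < 1, delta >= 0)
  maf_a <- pmin(p_s, 1 - p_s)
  pmin(pmax(fst_background + (1 - maf_a) * delta, 1e-4), 1 - 1e-4)
}

#' Draw present-day population allele frequencies (Balding-Nichols)
#'
#' Given the ancestral frequency `p_s` and a locus F_ST `F`, the two source
#' populations' frequencies are independent draws from
#' \deqn{Beta\!\left(p_s\frac{1-F}{F},\;(1-p_s)\frac{1-F}{F}\right),}
#' which has mean `p_s` and variance `p_s (1 - p_s) F` -- a single
#' divergence event with drift governed by F_ST. Draws may hit exact 0 or 1
#' (fixation), which the genotype sampler tolerates.
#'
#' @param p_s Ancestral allele frequencies (vectorized).
#' @param fst_s Per-locus F_ST values in (0, 1), recycled against `p_s`.
#' @param seed Optional integer seed.
#' @return List with numeric vectors `p1` and `p2`.
#' @export
draw_population_freqs <- function(p_s, fst_s, seed = NULL) {
  stopifnot(all(p_s > 0 & p_s < 1), all(fst_s > 0 & fst_s < 1))
  k <- (1 - fst_s) / fst_s
  n <- length(p_s)
  with_seed(seed, list(
    p1 = stats::rbeta(n, p_s * k, (1 - p_s) * k),
    p2 = stats::rbeta(n, p_s * k, (1 - p_s) * k)
  ))
}

#' Build the per-locus frequency table for a simulated trait
#'
#' Draws ancestral frequencies, assigns per-locus F_ST (trait F_ST at causal
#' loci, background F_ST elsewhere), and draws the two source populations'
#' present-day frequencies under Balding-Nichols. Causal loci use either the
#' MAF-linked flexible F_ST (`fst_causal = NULL`, background + increment) or
#' a fixed value (`fst_causal` given); non-causal loci always use the
#' background. Causal loci that come out lost in both populations
#' (`p1 = p2 = 0`) are redrawn, since an allele absent everywhere can carry
#' no effect.
#'
#' @param n_loci Total number of LD-independent loci.
#' @param causal_idx Integer indices of causal loci (possibly empty).
#' @param fst_background Background F_ST at non-causal loci (default 0.2).
#' @param delta MAF-linked F_ST increment at causal loci (default 0.3);
#'   ignored when `fst_causal` is given.
#' @param fst_causal Fixed F_ST at causal loci, or `NULL` for the flexible
#'   MAF-linked mode.
#' @param seed Optional integer seed.
#' @return An object of class `locus_freqs`: list with vectors `p` (ancestral
#'   frequency), `fst`, `p1`, `p2`, logical `causal`, and `causal_idx`.
#' @export
locus_frequencies <- function(n_loci, causal_idx = integer(0),
                              fst_background = 0.2, delta = 0.3,
                              fst_causal = NULL, seed = NULL) {
  n_loci <- as.integer(n_loci)
  causal_idx <- as.integer(causal_idx)
  stopifnot(n_loci >= 1, !anyDuplicated(causal_idx),
            all(causal_idx >= 1 & causal_idx <= n_loci))
  with_seed(seed, {
    p <- draw_ancestral_freqs(n_loci)
    fst <- rep(pmin(pmax(fst_background, 1e-4), 1 - 1e-4), n_loci)
    if (length(causal_idx)) {
      fst[causal_idx] <- if (is.null(fst_causal)) {
        effective_fst(p[causal_idx], fst_background, delta)
      } else {
        stopifnot(fst_causal > 0, fst_causal < 1)
        fst_causal
      }
    }
    pops <- draw_population_freqs(p, fst)
    # redraw causal loci lost in both source populations (no effect possible)
    for (attempt in 1:100) {
      dead <- causal_idx[pops$p1[causal_idx] == 0 & pops$p2[causal_idx] == 0]
      if (!length(dead)) break
      redraw <- draw_population_freqs(p[dead], fst[dead])
      pops$p1[dead] <- redraw$p1
      pops$p2[dead] <- redraw$p2
    }
    structure(
      list(p = p, fst = fst, p1 = pops$p1, p2 = pops$p2,
           causal = seq_len(n_loci) %in% causal_idx,
           causal_idx = sort(causal_idx)),
      class = "locus_freqs"
    )
  })
}

#' @export
print.locus_freqs <- function(x, ...) {
  cat(sprintf(
    "Locus frequency table: %d loci (%d causal), F_ST range [%.3g, %.3g]\n",
    length(x$p), length(x$causal_idx), min(x$fst), max(x$fst)))
  invisible(x)
}

#' Sample diploid genotypes conditional on local ancestry
#'
#' Each haplotype copy carries the counted allele with probability `p1` or
#' `p2` according to that copy's local ancestry; the diploid dosage is the
#' sum over the two copies. Local ancestry can be supplied explicitly (an
#' array from [sample_local_ancestry()]) or sampled on the fly from `theta`,
#' in which case the per-haplotype ancestry draw and allele draw are fused
#' and the ancestry array is only materialized when `keep_local = TRUE`.
#'
#' @param freqs A [locus_frequencies()] object (fields `p1`, `p2` are used).
#' @param theta Global ancestry vector; required when `local` is `NULL`.
#' @param local Optional local-ancestry array (`n x n_loci x 2`, entries
#'   1/2) overriding on-the-fly sampling.
#' @param keep_local Return the local-ancestry array alongside the dosages?
#' @param seed Optional integer seed.
#' @return An object of class `genotype_set`: list with `dosages`
#'   (`n x n_loci` integer matrix of allele counts 0/1/2), `freqs`, `theta`,
#'   and `local` (array or `NULL`).
#' @examples
#' fr <- locus_frequencies(5, causal_idx = 1:2, seed = 1)
#' gs <- sample_genotypes(fr, theta = rep(0.75, 10), seed = 2)
#' dim(gs$dosages)
#' @export
sample_genotypes <- function(freqs, theta = NULL, local = NULL,
                             keep_local = FALSE, seed = NULL) {
  stopifnot(inherits(freqs, "locus_freqs"))
  n_loci <- length(freqs$p1)
  if (is.null(local) && is.null(theta))
    stop("supply either `theta` or a `local` ancestry array")
  with_seed(seed, {
    if (is.null(local)) {
      n <- length(theta)
      if (keep_local) {
        local <- sample_local_ancestry(theta, n_loci)
      }
    } else {
      stopifnot(length(dim(local)) == 3L, dim(local)[2] == n_loci,
                dim(local)[3] == 2L)
      n <- dim(local)[1]
      if (!is.null(theta)) stopifnot(length(theta) == n)
    }
    dosages <- matrix(0L, n, n_loci)
    for (h in 1:2) {
      if (is.null(local)) {
        anc1 <- matrix(stats::runif(n * n_loci), n, n_loci) < theta
      } else {
        anc1 <- local[, , h] == 1L
      }
      # per-haplotype success probability by ancestry, p1/p2 recycled by row
      ph <- matrix(freqs$p2, n, n_loci, byrow = TRUE)
      pm1 <- matrix(freqs$p1, n, n_loci, byrow = TRUE)
      ph[anc1] <- pm1[anc1]
      dosages <- dosages + (matrix(stats::runif(n * n_loci), n, n_loci) < ph)
    }
    storage.mode(dosages) <- "integer"
    structure(
      list(dosages = dosages, freqs = freqs,
           theta = theta, local = if (keep_local) local else NULL),
      class = "genotype_set"
    )
  })
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("Genotype set: %d individuals x %d loci\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}
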