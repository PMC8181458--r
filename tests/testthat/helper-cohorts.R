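# Small deterministic building blocks shared across test files.

# a standard-setting architecture at reduced locus count
small_arch <- function(n_loci = 300L, n_causal = 30L, fst_causal = NULL,
                       fst_background = 0.2, seed = 42L) {
  simulate_architecture(n_loci = n_loci, n_causal = n_causal,
                        fst_background = fst_background,
                        fst_causal = fst_causal, seed = seed)
}

# a locus_freqs object with hand-set frequencies, for exact-value tests
manual_freqs <- function(p1, p2, fst = 0.2) {
  structure(
    list(p = (p1 + p2) / 2, fst = rep(fst, length(p1)), p1 = p1, p2 = p2,
         causal = rep(FALSE, length(p1)), causal_idx = integer(0)),
    class = "locus_freqs"
  )
}
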