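#' Derive a child seed deterministically from a master seed
#'
#' Experiments spawn many independent random streams (one per repetition,
#' population, and pipeline stage). Each stream's seed is derived by hashing
#' the master seed together with a tag describing the stream, so results are
#' reproducible regardless of execution order and streams do not collide for
#' distinct tags.
#'
#' @param master_seed Integer master seed.
#' @param ... Tag components (strings or numbers) identifying the stream,
#'   e.g. `derive_seed(1, "power_grid", rep = 3, pop = "admixed")`.
#' @return An integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' derive_seed(1, "rep", 1) != derive_seed(1, "rep", 2)
#' @export
derive_seed <- function(master_seed, ...) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  tokens <- unlist(lapply(list(...), as.character), use.names = FALSE)
  txt <- paste(c(format(master_seed, scientific = FALSE), tokens),
               collapse = "\x1f")
  # 32-bit FNV-1a in double arithmetic (exact: intermediates stay < 2^53)
  h <- 2166136261
  for (code in utf8ToInt(txt)) {
    h <- bitwXor_dbl(h, code)
    h <- (h * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

# xor of two non-negative doubles < 2^32 without integer overflow
bitwXor_dbl <- function(a, b) {
  r <- 0
  bit <- 1
  for (k in 1:32) {
    r <- r + bit * as.numeric(xor(a %% 2 >= 1, b %% 2 >= 1))
    a <- a %/% 2
    b <- b %/% 2
    bit <- bit * 2
    if (a == 0 && b == 0) break
  }
  r
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state,
#' so seeded helpers do not perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the current stream untouched.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
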