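# Internal helpers: seed derivation, RNG scoping, FFT-friendly lengths.

#' Derive a child seed from a master seed
#'
#' Deterministic Lehmer-style mixing so that every stochastic stage of the
#' pipeline (sessions, folds, window draws, weight init, permutations) gets
#' its own reproducible stream from a single master seed. Results stay below
#' 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param ... integer tags identifying the consumer (stage id, fold index,
#'   permutation index, ...).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  ks <- as.double(c(...))
  x <- as.double(seed) %% 2147483647
  if (x <= 0) x <- x + 2147483646
  for (k in ks) {
    x <- (x * 48271 + abs(k) + 1) %% 2147483647
    if (x == 0) x <- 1
  }
  as.integer(x)
}

# Evaluate `code` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Smallest 5-smooth integer >= n. Session lengths contain large prime
# factors (5 s at 2343.8 Hz = 11719 samples, a prime), for which mixed-radix
# FFT degenerates; padding to a 2/3/5-smooth length keeps FFTs fast.
next_fast_len <- function(n) {
  n <- as.integer(n)
  if (n <= 6L) return(max(n, 1L))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

rms <- function(x) sqrt(mean(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
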