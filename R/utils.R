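#' @importFrom stats runif rnorm median
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_glowsel <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

#' Derive a child RNG seed from a master seed
#'
#' Streams of randomness (one per sensor model, fold, repeat, ...) are keyed
#' by a deterministic integer derived from the master seed and a stream
#' index, so every component of a run can be reproduced in isolation.
#' Uses a Lehmer-style multiplicative scramble modulo the Mersenne prime
#' 2^31 - 1; results are always positive and below 2^31.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return a positive integer seed.
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647
  x <- (abs(as.numeric(master)) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + as.numeric(index) * 7919 + 1) %% m
  as.integer(x + 1)
}

# run a thunk under a seeded, restored RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}
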