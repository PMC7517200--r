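#' Derive a child RNG seed from a master seed and a named key
#'
#' Every stochastic component of an experiment (pattern generation,
#' connectivity sampling, lexicon assembly, timescale sampling, ...) draws its
#' own seed from the master seed through a named key, so that e.g. changing
#' the number of batches never perturbs the patterns themselves.
#'
#' @param master integer master seed
#' @param key character key naming the consumer
#' @return an integer seed in `[0, 2^31 - 2]`
#' @export
seed_for <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(key))
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(master) %% 2147483647 * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_that <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)

# sample() that never interprets a length-1 pool as 1:n
safe_sample <- function(pool, size, replace = FALSE) {
  pool[sample.int(length(pool), size, replace = replace)]
}
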