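#' @useDynLib gmsvm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom sd cor pt pchisq pnorm qnorm quantile
#' @importFrom utils write.table read.delim
"_PACKAGE"

# Evaluate expr under a given seed without disturbing the caller's RNG
# stream; used so that pipeline stages are reproducible independently of
# subject order or prior draws.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# A self-contained RNG stream: each call advances the stream's own state and
# leaves the global RNG untouched.
local_rng <- function(seed) {
  state <- NULL
  run <- function(f) {
    old <- get0(".Random.seed", envir = globalenv())
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = globalenv())
    res <- f()
    state <<- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    res
  }
  list(
    sample_perm = function(n) run(function() sample.int(n)),
    sample_int = function(n, k) run(function() sample.int(n, k)),
    rnorm = function(n, mean = 0, sd = 1) run(function() rnorm(n, mean, sd)),
    runif = function(n, min = 0, max = 1) run(function() runif(n, min, max)),
    rbinom = function(n, size, prob) run(function() rbinom(n, size, prob)),
    # Derive sub-seeds for stages; kept below 2^31 - 1.
    draw_seeds = function(k) run(function() sample.int(2147483646L, k))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
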