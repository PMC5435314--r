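# Isolated, seedable RNG stream. Every stochastic entry point in the package
# draws from one of these, so a single integer seed fully determines its
# output and the caller's .Random.seed is left untouched.
local_rng <- function(seed) {
  state <- NULL
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    if (is.null(state)) set.seed(as.integer(seed)) else {
      assign(".Random.seed", state, globalenv())
    }
    res <- expr
    state <<- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
    res
  }
  # sample from the elements of x, never from seq_len(x)
  safe_sample <- function(x, size, replace = FALSE, prob = NULL) {
    x[sample.int(length(x), size, replace = replace, prob = prob)]
  }
  list(
    shuffle = function(x) with_state(safe_sample(x, length(x))),
    sample  = function(x, size, replace = FALSE, prob = NULL) {
      with_state(safe_sample(x, size, replace, prob))
    },
    int     = function() with_state(sample.int(2147483646L, 1L)),
    unif    = function(n, min = 0, max = 1) with_state(stats::runif(n, min, max)),
    bernoulli = function(n, p) with_state(stats::runif(n) < p)
  )
}
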