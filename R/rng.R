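## Reproducible substream management built on the L'Ecuyer-CMRG generator.
##
## Every stochastic stage of the pipeline draws from its own substream,
## derived deterministically from a single root seed.  Scenario k always
## owns stream k, so any scenario (and its replicate data sets) can be
## regenerated in isolation, independently of how many scenarios a given
## run asked for.  Within a scenario's stream, the scenario-parameter draw,
## the replicate-data draw and the MCMC stage use disjoint substreams.

# substream depth per pipeline stage within a scenario's stream
RNG_STAGE <- c(scenario = 0L, data = 1L, mcmc = 2L)

#' Derive L'Ecuyer-CMRG stream states from a root seed
#'
#' Returns a list of `.Random.seed` states, one per requested stream.
#' Stream `i` is obtained by advancing the L'Ecuyer-CMRG stream `i` times
#' from the state implied by `seed`, so the mapping (seed, i) -> state is
#' fixed regardless of `n`.  `stage` selects a substream within each
#' stream (via [parallel::nextRNGSubStream()]) so that different pipeline
#' stages never share random numbers.
#'
#' @param seed integer root seed.
#' @param n number of streams to derive.
#' @param stage one of `"scenario"`, `"data"`, `"mcmc"`.
#' @return list of `n` integer vectors, each a valid `.Random.seed`.
#' @keywords internal
rng_substreams <- function(seed, n, stage = "scenario") {
  stopifnot(length(seed) == 1L, is.finite(seed), n >= 1L)
  depth <- RNG_STAGE[[match.arg(stage, names(RNG_STAGE))]]
  old_kind <- RNGkind()
  old_seed <- get_random_seed()
  on.exit(restore_random_seed(old_seed, old_kind), add = TRUE)
  set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
  s <- .Random.seed
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    sub <- s
    for (d in seq_len(depth)) sub <- parallel::nextRNGSubStream(sub)
    streams[[i]] <- sub
  }
  streams
}

#' Evaluate an expression under a given RNG state, then restore the caller's
#' @keywords internal
with_rng_state <- function(state, expr) {
  old_kind <- RNGkind()
  old_seed <- get_random_seed()
  on.exit(restore_random_seed(old_seed, old_kind), add = TRUE)
  assign(".Random.seed", state, envir = globalenv())
  expr
}

get_random_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

restore_random_seed <- function(seed, kind) {
  if (is.null(seed)) {
    suppressWarnings(RNGkind(kind[1L], kind[2L], kind[3L]))
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
  invisible(NULL)
}
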