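#' Derive a reproducible sub-seed for a named random-number substream
#'
#' The simulator draws random numbers for different purposes (cohort
#' generation, management assignment, event times, fatality, economics,
#' second-order parameter draws) from separate substreams keyed by name.
#' Adding draws in one substream therefore never perturbs another, and
#' every substream is fully determined by the root seed.
#'
#' @param seed integer root seed.
#' @param name character substream label.
#' @return An integer seed below 2^31, deterministic in `(seed, name)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes) * 7919)
  as.integer((abs(as.double(seed)) * 48271 + h) %% 2147483647)
}

#' Uniform draws from a named substream
#'
#' Draws `n` uniforms from the substream `name` of root seed `seed`
#' without touching the caller's RNG state.
#'
#' @param seed integer root seed.
#' @param name character substream label.
#' @param n number of draws.
#' @return Numeric vector of `n` uniforms.
#' @export
substream_runif <- function(seed, name, n) {
  if (n == 0L) return(numeric(0))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  stats::runif(n)
}

substream_eval <- function(seed, name, expr_fun) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr_fun()
}
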