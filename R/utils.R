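#' Derive a child seed from a root seed
#'
#' All randomness in the package flows from one root seed. Independent
#' random streams (subjects, replications, MCMC chains) get child seeds via a
#' fixed affine map modulo the Mersenne prime 2^31 - 1, so every derived seed
#' fits a 32-bit integer and distinct streams never collide for stream
#' indices below 2^15.
#'
#' @param seed Integer root seed.
#' @param stream Non-negative integer stream index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- 2147483647   # 2^31 - 1
  s <- (abs(as.numeric(seed)) %% m)
  # two multiplicative steps keep nearby (seed, stream) pairs apart
  s <- (s * 48271) %% m
  s <- (s + (as.numeric(stream) + 1) * 69621) %% m
  s <- (s * 16807) %% m
  as.integer(if (s == 0) 1 else s)
}

#' Evaluate an expression under a local RNG state
#'
#' Sets the seed, evaluates, and restores the caller's RNG state so library
#' code never perturbs user-level randomness.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stop() with sprintf formatting, no call in message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
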