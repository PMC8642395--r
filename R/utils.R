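#' @useDynLib korotkoff, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif uniroot sd median approx
NULL

rms <- function(x) sqrt(mean(x^2))

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded package internals do
#' not disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation: one master seed, per-use sub-seeds.
# Knuth multiplicative hash, kept inside the 32-bit signed range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 2654435761 + 97 * as.numeric(k)) %% 2147483647)
}
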