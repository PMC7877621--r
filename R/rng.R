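#' Derive a reproducible sub-seed for a named purpose
#'
#' All stochastic stages of the analysis (roster generation, reviewer
#' assignment, PoS simulation, coefficient sampling, the evolutionary solver)
#' draw from their own substream, derived deterministically from one master
#' seed and a purpose label. This keeps stages decoupled: adding iterations to
#' one stage never perturbs another, and the optimizer can reuse identical
#' draws across portfolio evaluations (common random numbers).
#'
#' @param seed Master seed (integer).
#' @param purpose Character label of the consuming stage.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(purpose))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- (abs(seed) %% m)
  for (code in utf8ToInt(purpose)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
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
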