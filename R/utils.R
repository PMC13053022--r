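#' Derive a deterministic child seed from a global seed and a stage name
#'
#' Every stochastic stage of a pipeline receives its own reproducible stream:
#' the child seed is a deterministic hash of the global seed and the stage
#' label, kept below 2^31 so it is always a valid R integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage label (e.g. "scenes", "simulate").
#' @return an integer seed.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under `seed` when non-NULL, restoring the caller's RNG state.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}
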