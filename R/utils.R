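# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Symmetric rounding used when converting continuous in-plane actions into
#' integer grid steps: 3.5 -> 4 and -3.5 -> -4, so that positive and negative
#' displacements are treated identically.
#'
#' @param x numeric vector.
#' @return integer vector of the same length.
#' @keywords internal
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. Keeps environment-internal draws
# (mismatch sampling) from perturbing user-level streams such as PPO action
# sampling.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of one root seed into stage-specific seeds. `offset`
# is a fixed per-stage counter so partial re-runs of a pipeline reuse the
# same stream per stage. Kept below 2^31 - 1.
derive_seed <- function(root_seed, offset) {
  as.integer((as.numeric(root_seed) * 1000 + offset) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("%s must be finite", what), call. = FALSE)
}
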