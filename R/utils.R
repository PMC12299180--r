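# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package funnels through this so results
# are pure functions of their arguments (including the seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# side/scale as an exact integer (tolerating floating-point scales like 2.5)
cells_per_side <- function(side, scale) {
  k <- side / scale
  if (abs(k - round(k)) > 1e-9) {
    stop("plot side (", side, " m) is not divisible by scale (", scale, " m)",
         call. = FALSE)
  }
  as.integer(round(k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
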