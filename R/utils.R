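# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All randomized operations in the package route through this so that no
# function leaves a footprint on the global stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
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

stop_catapot <- function(...) stop(..., call. = FALSE)

# Format a double so the TSV dialects round-trip: integers print bare,
# everything else with 17 significant digits.
fmt_num <- function(x) {
  ifelse(is.finite(x) & x == round(x) & abs(x) < 1e15,
         sprintf("%.0f", x),
         vapply(x, function(v) format(v, digits = 17, scientific = FALSE),
                character(1)))
}

logistic <- function(eta) 1 / (1 + exp(-eta))
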