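#' Deterministic seed derivation
#'
#' All randomness in the package flows from one named seed. Child seeds for
#' sub-tasks (per-sample shape, per-epoch shuffling, per-annotator jitter, ...)
#' are derived deterministically from the parent seed and a sequence of string
#' or integer labels, so no component depends on global RNG state left behind
#' by another.
#'
#' @param seed integer parent seed.
#' @param ... labels (strings or integers) identifying the sub-task.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  labs <- list(...)
  h <- as.double(seed %% 2147483647)
  for (lab in labs) {
    v <- if (is.character(lab)) utf8ToInt(lab) else as.integer(lab)
    for (x in v) h <- (h * 69069 + as.double(x) + 1) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so callers never perturb (or depend on)
#' global RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
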