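# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#'
#' All exported simulation functions take an explicit `seed` argument and run
#' through this helper, so calling them never perturbs the caller's random
#' number stream and identical seeds give bitwise-identical output.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a root seed
#'
#' Stream-splitting scheme for the pipeline: each named stage gets an
#' independent, reproducible seed as a deterministic function of the root
#' seed and the stage index, kept inside the 32-bit signed-integer range.
#'
#' @param seed root seed (integer).
#' @param stage stage index (small positive integer).
#' @return an integer seed.
#' @noRd
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + stage * 9973) %% 2147483647)
}

# Single numeric probability check used by several validators.
check_prob <- function(x, name, open_low = TRUE, open_high = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  lo_ok <- if (open_low) x > 0 else x >= 0
  hi_ok <- if (open_high) x < 1 else x <= 1
  if (!lo_ok || !hi_ok) {
    stop(sprintf("`%s` = %g is outside the valid probability range", name, x),
         call. = FALSE)
  }
  invisible(x)
}
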