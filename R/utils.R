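# Internal helpers shared across modules.

SPEED_OF_LIGHT <- 3e8  # m/s; rounded value so the conventional radar constants reproduce

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so simulator calls are deterministic
#' without disturbing the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}

#' @keywords internal
rms <- function(x) sqrt(mean(x^2))

# half-open interval sample index: sample i (1-based) covers [(i-1)/fs, i/fs)
time_to_index <- function(t, fs) floor(t * fs) + 1L
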