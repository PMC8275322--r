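#' Derive a child seed from a master seed and a stage label
#'
#' All randomness in the package flows from one master seed. Every stage
#' (split, CV repeat, model fit, synthetic sample, ...) receives its own seed
#' derived deterministically from the master seed and a short text label, so
#' that changing one stage never perturbs another and whole pipelines are
#' reproducible from a single integer.
#'
#' @param master integer master seed.
#' @param label character stage label, e.g. \code{"cv_repeat_1"}.
#' @return An integer seed in \code{[0, 2^31 - 2]}.
#' @export
#' @examples
#' derive_seed(1, "split")
#' derive_seed(1, "cv_repeat_2")
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  # 31-based polynomial rolling hash mod a Mersenne prime; stays < 2^53 so
  # double arithmetic is exact
  h <- abs(as.double(master)) %% 2147483647
  for (b in utf8ToInt(as.character(label))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the caller's RNG
#' state, so library code never disturbs the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

# internal: stop with a classed condition so callers can test error categories
rawms_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "rawms_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
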