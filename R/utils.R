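# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that simulators are pure functions of
#' their `seed` argument and never disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_rng <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
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

# stopifnot() variant that raises classed argument errors with readable text
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) {
    stop(errorCondition(msg, class = c("apygwas_argument_error", "error")))
  }
  invisible(TRUE)
}

numerical_error <- function(msg) {
  stop(errorCondition(msg, class = c("apygwas_numerical_error", "error")))
}

format_error <- function(msg) {
  stop(errorCondition(msg, class = c("apygwas_format_error", "error")))
}
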