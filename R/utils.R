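#' @keywords internal
"_PACKAGE"

# Internal validation helpers. All user-facing errors go through stop() with
# call. = FALSE so messages read as package errors, not internal frames.

abort <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
}

# Seed handling: every stochastic entry point takes an integer `seed` and runs
# under a local RNG state so package calls never disturb the caller's stream.
with_seed <- function(seed, expr) {
  assert_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
              "`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Missing genotype sentinel used across readers/writers.
.MISSING <- NA_character_

is_missing_call <- function(a1, a2) is.na(a1) | is.na(a2)
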