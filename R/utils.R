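#' Evaluate code under a temporary seed
#'
#' Runs `expr` with the RNG seeded at `seed`, restoring the caller's RNG
#' state afterwards. A `NULL` seed evaluates `expr` in the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed_or_stream <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() wrapper keeping call noise out of user-facing errors
abort <- function(...) stop(..., call. = FALSE)
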