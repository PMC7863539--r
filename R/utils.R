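# Internal helpers shared across modules.

# The six relationship kinds plus "none" (no relationship).
RELATION_KINDS <- c("low_low", "low_high", "high_low", "high_high",
                    "equivalent", "opposite")

QUADRANTS <- c("q00", "q01", "q10", "q11")

# Discrete state codes: low = 0, intermediate = 1, high = 2.
STATE_LOW <- 0L
STATE_INT <- 1L
STATE_HIGH <- 2L

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the previous RNG state,
#' so that seeded package functions do not disturb the caller's random
#' stream. A `NULL` seed evaluates the expression with the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_stage <- function(stage, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(paste0("boolimp_", stage, "_error"), "boolimp_error",
              "error", "condition"),
    list(message = sprintf("[%s] %s", stage, msg), call = sys.call(-1)))
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
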