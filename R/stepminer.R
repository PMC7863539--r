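# StepMiner: one-step function fit on sorted log2 abundances.
#
# For a microbe's n sorted values, every split k in 1..(n-1) defines a step
# with left mean m1 (the k smallest values) and right mean m2 (the rest);
# the fit minimizes SSE = sum_left (x - m1)^2 + sum_right (x - m2)^2 and the
# threshold is the midpoint (m1 + m2) / 2, where the fitted step crosses
# between its two levels. Sorting makes only a step-up fit meaningful.

#' Fit a step function to one microbe's log2 abundances
#'
#' @param x Numeric vector of log2 abundances (missing values dropped;
#'   at least 4 non-missing values required).
#' @return An object of class `"step_fit"`: a list with `threshold`,
#'   `step_index` (number of samples on the low side), `left_mean`,
#'   `right_mean`, `sse`, `degenerate` and `n`.
#' @examples
#' fit_step(c(1, 1, 1, 5, 5, 5))  # threshold 3, sse 0
#' @export
fit_step <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4)
    stop_stage("stepminer", "need at least 4 non-missing values, got %d", n)
  xs <- sort(x)
  if (xs[n] - xs[1] == 0) {
    return(structure(list(threshold = xs[1], step_index = NA_integer_,
                          left_mean = xs[1], right_mean = xs[1],
                          sse = 0, degenerate = TRUE, n = n),
                     class = "step_fit"))
  }
  cs <- cumsum(xs)
  total <- cs[n]
  k <- seq_len(n - 1L)
  m1 <- cs[k] / k
  m2 <- (total - cs[k]) / (n - k)
  # SSE identity: sum(x^2) - k*m1^2 - (n-k)*m2^2
  sse <- sum(xs^2) - k * m1^2 - (n - k) * m2^2
  best <- which.min(sse)                      # first minimum: smallest k wins ties
  structure(list(threshold = (m1[best] + m2[best]) / 2,
                 step_index = as.integer(best),
                 left_mean = m1[best], right_mean = m2[best],
                 sse = max(sse[best], 0), degenerate = FALSE, n = n),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("StepMiner fit (degenerate): constant at %.4g, n = %d\n",
                x$threshold, x$n))
  } else {
    cat(sprintf("StepMiner fit: threshold %.4g (step after %d of %d sorted samples)\n",
                x$threshold, x$step_index, x$n))
    cat(sprintf("  means %.4g | %.4g, SSE %.4g\n",
                x$left_mean, x$right_mean, x$sse))
  }
  invisible(x)
}

#' Discretize log2 abundances into low/intermediate/high
#'
#' Values above `threshold + margin` are high (2), below
#' `threshold - margin` low (0), and otherwise — including values exactly
#' on either boundary, and missing values — intermediate (1). Intermediate
#' samples are ignored downstream because noise could place them on either
#' side of the threshold. A degenerate fit yields an all-intermediate
#' vector with a warning.
#'
#' @param x Numeric vector of log2 abundances.
#' @param fit A [fit_step()] result for the same microbe.
#' @param margin Noise half-width around the threshold; default 0.5.
#' @return Integer vector of states (0 low, 1 intermediate, 2 high).
#' @export
discretize <- function(x, fit, margin = 0.5) {
  stopifnot(inherits(fit, "step_fit"), margin >= 0)
  if (fit$degenerate) {
    warning("degenerate step fit: all samples classified intermediate")
    return(rep(STATE_INT, length(x)))
  }
  out <- rep(STATE_INT, length(x))
  out[!is.na(x) & x > fit$threshold + margin] <- STATE_HIGH
  out[!is.na(x) & x < fit$threshold - margin] <- STATE_LOW
  out
}

#' Threshold and discretize every microbe of an abundance matrix
#'
#' @param m Abundance matrix (samples x OTUs) of log2 values.
#' @param margin Noise half-width passed to [discretize()].
#' @return A list of class `"stepminer_thresholds"`: `fits` (named list of
#'   `step_fit`), `thresholds` (named numeric), `degenerate` (named
#'   logical), and `discrete` (integer matrix of states, same dimnames
#'   as `m`).
#' @export
threshold_matrix <- function(m, margin = 0.5) {
  m <- as.matrix(m)
  if (nrow(m) < 4)
    stop_stage("stepminer", "need at least 4 samples, got %d", nrow(m))
  fits <- vector("list", ncol(m))
  names(fits) <- colnames(m)
  disc <- matrix(STATE_INT, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    fits[[j]] <- fit_step(m[, j])
    disc[, j] <- if (fits[[j]]$degenerate) STATE_INT
                 else discretize(m[, j], fits[[j]], margin)
  }
  structure(list(
    fits = fits,
    thresholds = vapply(fits, `[[`, numeric(1), "threshold"),
    degenerate = vapply(fits, `[[`, logical(1), "degenerate"),
    discrete = disc,
    margin = margin), class = "stepminer_thresholds")
}

#' @export
print.stepminer_thresholds <- function(x, ...) {
  cat(sprintf("StepMiner thresholds for %d microbes (%d samples), margin %.2g\n",
              length(x$fits), nrow(x$discrete), x$margin))
  if (any(x$degenerate))
    cat(sprintf("  %d degenerate (constant) microbe(s)\n", sum(x$degenerate)))
  invisible(x)
}

#' Write a threshold report TSV
#'
#' Columns: otu_id, threshold, m1, m2, sse, degenerate.
#' @param tm A [threshold_matrix()] result.
#' @param path Output path.
#' @export
write_threshold_table <- function(tm, path) {
  df <- data.frame(
    otu_id = names(tm$fits),
    threshold = tm$thresholds,
    m1 = vapply(tm$fits, `[[`, numeric(1), "left_mean"),
    m2 = vapply(tm$fits, `[[`, numeric(1), "right_mean"),
    sse = vapply(tm$fits, `[[`, numeric(1), "sse"),
    degenerate = tm$degenerate,
    row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
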