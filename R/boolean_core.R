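# BooleanNet sparse-quadrant statistics and pair classification.
#
# With both microbes discretized, the samples where neither is intermediate
# fall into four quadrants a00, a01, a10, a11 — (A,B) low/low, low/high,
# high/low, high/high. A quadrant is significantly sparse when its count is
# far below the expectation under an independence model of the marginals:
#
#   expected   = (A-marginal x B-marginal) / total
#   S          = (expected - observed) / sqrt(expected)
#   error rate = 1/2 (observed / A-marginal + observed / B-marginal)
#
# One sparse quadrant gives an asymmetric implication; the two off-diagonal
# quadrants sparse give "equivalent"; the two diagonal quadrants sparse give
# "opposite".

#' Significance and filtering parameters for Boolean implication tests
#'
#' Defaults follow the published convention: an implication is significant
#' when the S statistic exceeds 3 and the error rate is below 0.1. The
#' dynamic-range filter (`min_side_fraction`, `min_side_count`) requires
#' each microbe to have enough samples on both sides of its threshold to
#' enter pair testing; set both to 0 to disable it.
#'
#' @param s_min Minimum S statistic; default 3.
#' @param err_max Maximum error rate; default 0.1.
#' @param min_side_fraction Minimum fraction of samples required low and
#'   high per microbe; default 0.05.
#' @param min_side_count Minimum absolute number of samples required low
#'   and high per microbe; default 3. The filter applies
#'   `max(min_side_count, min_side_fraction * n)`.
#' @return A list of class `"significance_params"`.
#' @export
significance_params <- function(s_min = 3, err_max = 0.1,
                                min_side_fraction = 0.05,
                                min_side_count = 3) {
  stopifnot(s_min > 0, err_max > 0, err_max < 1,
            min_side_fraction >= 0, min_side_count >= 0)
  structure(list(s_min = s_min, err_max = err_max,
                 min_side_fraction = min_side_fraction,
                 min_side_count = min_side_count),
            class = "significance_params")
}

#' Quadrant counts of a discretized microbe pair
#'
#' Samples where either microbe is intermediate are excluded from all four
#' cells.
#'
#' @param dA,dB Integer state vectors (0 low, 1 intermediate, 2 high) of
#'   equal length.
#' @return A list of class `"quadrant_counts"` with `a00`, `a01`, `a10`,
#'   `a11`, `n_used`, `n_dropped_intermediate`.
#' @export
quadrant_counts <- function(dA, dB) {
  if (length(dA) != length(dB))
    stop_stage("boolean_core", "state vectors differ in length (%d vs %d)",
               length(dA), length(dB))
  keep <- !is.na(dA) & !is.na(dB) & dA != STATE_INT & dB != STATE_INT
  a <- dA[keep]
  b <- dB[keep]
  structure(list(
    a00 = sum(a == STATE_LOW & b == STATE_LOW),
    a01 = sum(a == STATE_LOW & b == STATE_HIGH),
    a10 = sum(a == STATE_HIGH & b == STATE_LOW),
    a11 = sum(a == STATE_HIGH & b == STATE_HIGH),
    n_used = sum(keep),
    n_dropped_intermediate = length(dA) - sum(keep)),
    class = "quadrant_counts")
}

# Marginals relevant to each quadrant: the A-side (row) marginal shares the
# quadrant's A state, the B-side (column) marginal its B state.
quadrant_margins <- function(q, quadrant) {
  switch(quadrant,
    q00 = list(obs = q$a00, row = q$a00 + q$a01, col = q$a00 + q$a10),
    q01 = list(obs = q$a01, row = q$a00 + q$a01, col = q$a01 + q$a11),
    q10 = list(obs = q$a10, row = q$a10 + q$a11, col = q$a00 + q$a10),
    q11 = list(obs = q$a11, row = q$a10 + q$a11, col = q$a01 + q$a11),
    stop_stage("boolean_core", "unknown quadrant '%s'", quadrant))
}

#' Test one quadrant of a pair for significant sparsity
#'
#' @param q A [quadrant_counts()] result with `n_used > 0`.
#' @param quadrant One of `"q00"`, `"q01"`, `"q10"`, `"q11"`.
#' @param params A [significance_params()] list.
#' @return A list of class `"sparsity_test"` with `quadrant`, `expected`,
#'   `observed`, `s_statistic`, `error_rate`, `passes`. When the expected
#'   count or a marginal is zero the statistics are `NA` and `passes` is
#'   `FALSE`, so all-pairs scans never abort on degenerate tables.
#' @export
sparsity_test <- function(q, quadrant = c("q00", "q01", "q10", "q11"),
                          params = significance_params()) {
  quadrant <- match.arg(quadrant)
  if (q$n_used == 0)
    stop_stage("boolean_core", "empty quadrant table (all samples intermediate)")
  m <- quadrant_margins(q, quadrant)
  expected <- m$row * m$col / q$n_used
  if (expected == 0 || m$row == 0 || m$col == 0) {
    s <- NA_real_
    err <- NA_real_
    passes <- FALSE
  } else {
    s <- (expected - m$obs) / sqrt(expected)
    err <- 0.5 * (m$obs / m$row + m$obs / m$col)
    passes <- s > params$s_min && err < params$err_max
  }
  structure(list(quadrant = quadrant, expected = expected, observed = m$obs,
                 s_statistic = s, error_rate = err, passes = passes),
            class = "sparsity_test")
}

# Which quadrant's sparsity implies which relationship, A on the x-axis:
# a sparse (A low, B low) quadrant means A low forces B high, and so on.
SPARSE_TO_KIND <- c(q00 = "low_high", q01 = "low_low",
                    q10 = "high_high", q11 = "high_low")

#' Classify a microbe pair into a Boolean implication relationship
#'
#' Runs [sparsity_test()] on all four quadrants. Exactly one passing
#' quadrant yields the corresponding asymmetric implication; both
#' off-diagonal quadrants (`q01`, `q10`) yield `equivalent`; both diagonal
#' quadrants (`q00`, `q11`) yield `opposite`; any other combination —
#' including three or four sparse quadrants, which violate the implication
#' model — yields `none`. The per-quadrant tests are retained for audit.
#'
#' @param q A [quadrant_counts()] result.
#' @param params A [significance_params()] list.
#' @return A list of class `"boolean_relation"` with `kind` and `tests`.
#' @export
classify_pair <- function(q, params = significance_params()) {
  tests <- lapply(QUADRANTS, function(qu) sparsity_test(q, qu, params))
  names(tests) <- QUADRANTS
  pass <- vapply(tests, `[[`, logical(1), "passes")
  kind <- if (sum(pass) == 1) {
    SPARSE_TO_KIND[[QUADRANTS[pass]]]
  } else if (sum(pass) == 2 && pass[["q01"]] && pass[["q10"]]) {
    "equivalent"
  } else if (sum(pass) == 2 && pass[["q00"]] && pass[["q11"]]) {
    "opposite"
  } else {
    "none"
  }
  structure(list(kind = kind, tests = tests), class = "boolean_relation")
}

#' @export
print.boolean_relation <- function(x, ...) {
  cat(sprintf("Boolean relation: %s\n", x$kind))
  for (t in x$tests)
    cat(sprintf("  %s: observed %d, expected %.3f, S %.3f, error %.4f%s\n",
                t$quadrant, t$observed, t$expected,
                ifelse(is.na(t$s_statistic), NA, t$s_statistic),
                ifelse(is.na(t$error_rate), NA, t$error_rate),
                if (isTRUE(t$passes)) "  [sparse]" else ""))
  invisible(x)
}

# Kind mapping under swapping the two microbes (contrapositive convention):
# A low -> B low restated with B first is B high -> A high, so low_low and
# high_high exchange; low_high and high_low are self-dual; symmetric kinds
# are unchanged.
SWAP_KIND <- c(low_low = "high_high", high_high = "low_low",
               low_high = "low_high", high_low = "high_low",
               equivalent = "equivalent", opposite = "opposite")

#' Canonicalize a classified pair to lexicographic id order
#'
#' Boolean implications are written with the x-axis microbe first, and each
#' asymmetric implication has a logically identical contrapositive with the
#' microbes exchanged. Canonical records always name the lexicographically
#' smaller OTU first, remapping the kind accordingly.
#'
#' @param otu_a,otu_b OTU identifiers, `otu_a` the x-axis microbe.
#' @param kind A relationship kind (not `"none"`), or a
#'   `"boolean_relation"` object.
#' @return A list with `otu_a`, `otu_b`, `kind` in canonical order.
#' @export
canonicalize_relation <- function(otu_a, otu_b, kind) {
  if (inherits(kind, "boolean_relation")) kind <- kind$kind
  if (!kind %in% RELATION_KINDS)
    stop_stage("boolean_core", "cannot canonicalize kind '%s'", kind)
  if (otu_a <= otu_b) list(otu_a = otu_a, otu_b = otu_b, kind = kind)
  else list(otu_a = otu_b, otu_b = otu_a, kind = SWAP_KIND[[kind]])
}

#' Microbes with enough dynamic range to enter pair testing
#'
#' A microbe must have at least `max(min_side_count,
#' min_side_fraction * n)` samples called low and as many called high;
#' near-constant microbes otherwise generate spurious implications.
#'
#' @param discrete Integer state matrix (samples x microbes).
#' @param params A [significance_params()] list.
#' @return Logical vector, one entry per microbe.
#' @export
testable_microbes <- function(discrete, params = significance_params()) {
  n <- nrow(discrete)
  need <- max(params$min_side_count, params$min_side_fraction * n)
  n_low <- colSums(discrete == STATE_LOW)
  n_high <- colSums(discrete == STATE_HIGH)
  n_low >= need & n_high >= need
}
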