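# Boolean implication analysis: the one-stop fitting function and its
# methods.

#' Fit a Boolean implication analysis to an OTU table
#'
#' The full per-dataset procedure: log2-transform raw counts (skipped when
#' `x` is already an `"otu_abundance"` matrix), fit a StepMiner threshold
#' per microbe, discretize each sample into low/intermediate/high around
#' the threshold with a noise margin, and classify every pair of microbes
#' with enough dynamic range into one of six Boolean implication
#' relationship kinds via sparse-quadrant statistics.
#'
#' @param x Raw counts (`"otu_counts"` or a plain samples x OTUs matrix)
#'   or log2 abundances (`"otu_abundance"`).
#' @param pseudocount,scaling,depth Passed to [transform_log2()] when `x`
#'   holds raw counts.
#' @param margin Discretization noise half-width; default 0.5.
#' @param params A [significance_params()] list (S > 3, error rate < 0.1
#'   by default).
#' @param dataset_id Label attached to the relation table.
#' @return An object of class `"bia"`: a list with `abundance`,
#'   `thresholds` (a `"stepminer_thresholds"` object), `relations` (a
#'   `"relation_table"`), `params`, `margin` and `call`. Methods:
#'   [print.bia()], [summary.bia()], [coef.bia()] (the per-microbe
#'   thresholds), [predict.bia()] (discretize new samples), [plot.bia()]
#'   (pair scatter with thresholds).
#' @examples
#' ds <- generate_dataset(120, 6, list(pair_spec("high_low")), seed = 7)
#' fit <- bia(ds$counts)
#' fit$relations[, 1:3]
#' coef(fit)[1:2]
#' @export
bia <- function(x, pseudocount = 1, scaling = "none", depth = NULL,
                margin = 0.5, params = significance_params(),
                dataset_id = "dataset") {
  m <- if (inherits(x, "otu_abundance")) x
       else transform_log2(x, pseudocount, scaling, depth)
  tm <- threshold_matrix(m, margin)
  rt <- scan_pairs(tm$discrete, params, dataset_id)
  structure(list(abundance = m, thresholds = tm, relations = rt,
                 params = params, margin = margin,
                 dataset_id = dataset_id, call = match.call()),
            class = "bia")
}

#' @export
print.bia <- function(x, ...) {
  cat("Boolean implication analysis\n")
  cat(sprintf("  %d samples x %d microbes; %d microbe(s) pass the range filter\n",
              nrow(x$abundance), ncol(x$abundance),
              length(attr(x$relations, "microbes_tested"))))
  cat(sprintf("  %d relationship(s) among %d pair(s) tested (S > %g, error < %g, margin %g)\n",
              nrow(x$relations), attr(x$relations, "n_pairs_tested"),
              x$params$s_min, x$params$err_max, x$margin))
  if (nrow(x$relations)) print(table(kind = x$relations$kind))
  invisible(x)
}

#' Summary of a Boolean implication analysis
#'
#' @param object A `"bia"` fit.
#' @param ... Unused.
#' @export
summary.bia <- function(object, ...) {
  rel <- object$relations
  kind_counts <- table(factor(rel$kind, levels = RELATION_KINDS))
  structure(list(
    n_samples = nrow(object$abundance),
    n_microbes = ncol(object$abundance),
    n_degenerate = sum(object$thresholds$degenerate),
    n_tested = length(attr(rel, "microbes_tested")),
    n_dropped = length(attr(rel, "microbes_dropped")),
    n_pairs_tested = attr(rel, "n_pairs_tested"),
    kind_counts = kind_counts,
    threshold_range = range(object$thresholds$thresholds),
    params = object$params, margin = object$margin),
    class = "summary.bia")
}

#' @export
print.summary.bia <- function(x, ...) {
  cat("Boolean implication analysis summary\n")
  cat(sprintf("  samples: %d, microbes: %d (%d degenerate)\n",
              x$n_samples, x$n_microbes, x$n_degenerate))
  cat(sprintf("  range filter: %d tested, %d dropped\n",
              x$n_tested, x$n_dropped))
  cat(sprintf("  pairs tested: %d; relationships by kind:\n", x$n_pairs_tested))
  print(x$kind_counts)
  cat(sprintf("  thresholds in [%.3g, %.3g]; margin %g; S > %g; error < %g\n",
              x$threshold_range[1], x$threshold_range[2], x$margin,
              x$params$s_min, x$params$err_max))
  invisible(x)
}

#' Per-microbe thresholds of a fitted analysis
#'
#' @param object A `"bia"` fit.
#' @param ... Unused.
#' @return Named numeric vector of StepMiner thresholds (log2 scale).
#' @export
coef.bia <- function(object, ...) object$thresholds$thresholds

#' Discretize new samples with the thresholds of a fitted analysis
#'
#' @param object A `"bia"` fit.
#' @param newdata Counts or log2 abundances for the same microbes; when
#'   omitted, the training samples' states are returned.
#' @param type `"discrete"` (state codes 0/1/2) or `"label"` (low /
#'   intermediate / high).
#' @param ... Unused.
#' @return Matrix of states, samples x microbes.
#' @export
predict.bia <- function(object, newdata = NULL,
                        type = c("discrete", "label"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    out <- object$thresholds$discrete
  } else {
    m <- if (inherits(newdata, "otu_abundance")) newdata
         else transform_log2(newdata,
                             attr(object$abundance, "pseudocount"),
                             attr(object$abundance, "scaling"))
    miss <- setdiff(colnames(m), names(object$thresholds$fits))
    if (length(miss))
      stop_stage("bia", "microbe(s) not in the fit: %s",
                 paste(utils::head(miss, 3), collapse = ", "))
    out <- matrix(STATE_INT, nrow(m), ncol(m), dimnames = dimnames(m))
    for (j in colnames(m)) {
      f <- object$thresholds$fits[[j]]
      if (!f$degenerate)
        out[, j] <- discretize(m[, j], f, object$margin)
    }
  }
  if (type == "label")
    out[] <- c("low", "intermediate", "high")[out + 1L]
  out
}

#' Scatter plot of one microbe pair with thresholds and noise margins
#'
#' Log2 abundances of `otu_a` (x-axis) against `otu_b` (y-axis), one point
#' per sample, with each microbe's StepMiner threshold and its
#' intermediate band drawn.
#'
#' @param x A `"bia"` fit.
#' @param otu_a,otu_b Microbe ids to plot.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bia <- function(x, otu_a, otu_b, ...) {
  for (id in c(otu_a, otu_b))
    if (!id %in% colnames(x$abundance))
      stop_stage("bia", "unknown OTU id '%s'", id)
  xa <- x$abundance[, otu_a]
  xb <- x$abundance[, otu_b]
  ta <- x$thresholds$thresholds[[otu_a]]
  tb <- x$thresholds$thresholds[[otu_b]]
  graphics::plot(xa, xb, pch = 16, col = "#00000080",
                 xlab = sprintf("%s (log2 abundance)", otu_a),
                 ylab = sprintf("%s (log2 abundance)", otu_b), ...)
  graphics::abline(v = ta, h = tb, col = "red")
  graphics::abline(v = ta + c(-1, 1) * x$margin,
                   h = tb + c(-1, 1) * x$margin, col = "red", lty = 3)
  invisible(x)
}
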