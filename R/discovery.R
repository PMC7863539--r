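# All-pairs scanning, permutation FDR, cross-dataset invariants,
# correlation comparison and metadata differential analysis.

#' Scan all microbe pairs for Boolean implication relationships
#'
#' Applies the dynamic-range filter, then tests every unordered pair of
#' surviving microbes once. The quadrant tables of all pairs are obtained
#' with four cross-products of the low/high indicator matrices, so the
#' scan is vectorized over pairs; results are identical to calling
#' [quadrant_counts()] and [classify_pair()] per pair. Records are emitted
#' in canonical (lexicographic) pair order and contain only pairs whose
#' kind is not `"none"`.
#'
#' @param discrete Integer state matrix (samples x microbes) from
#'   [threshold_matrix()], or a `"stepminer_thresholds"` object.
#' @param params A [significance_params()] list.
#' @param dataset_id Label stored on the table (used by
#'   [find_invariants()]).
#' @return A data.frame of class `"relation_table"` with columns `otu_a`,
#'   `otu_b`, `kind`, the four quadrant counts, `n_used`, and per-quadrant
#'   S statistics (`s00`..`s11`) and error rates (`err00`..`err11`).
#'   Attributes: `dataset_id`, `n_pairs_tested`, `microbes_tested`,
#'   `microbes_dropped`, `params`.
#' @export
scan_pairs <- function(discrete, params = significance_params(),
                       dataset_id = "dataset") {
  if (inherits(discrete, "stepminer_thresholds")) discrete <- discrete$discrete
  if (is.null(colnames(discrete)))
    stop_stage("discovery", "discrete matrix must carry microbe ids as colnames")
  keep <- testable_microbes(discrete, params)
  ids <- sort(colnames(discrete)[keep])          # canonical column order
  empty <- relation_records(0)
  if (length(ids) < 2) {
    warning("fewer than 2 microbes pass the dynamic-range filter")
    return(new_relation_table(empty, dataset_id, 0L, ids,
                              colnames(discrete)[!keep], params))
  }
  d <- discrete[, ids, drop = FALSE]
  L <- matrix(as.numeric(d == STATE_LOW), nrow(d))
  H <- matrix(as.numeric(d == STATE_HIGH), nrow(d))
  A00 <- crossprod(L, L); A01 <- crossprod(L, H)
  A10 <- crossprod(H, L); A11 <- crossprod(H, H)
  tot <- A00 + A01 + A10 + A11
  rowlow <- A00 + A01; rowhigh <- A10 + A11      # A-side marginals
  collow <- A00 + A10; colhigh <- A01 + A11      # B-side marginals
  pass_q <- function(obs, rowm, colm) {
    e <- rowm * colm / tot
    s <- (e - obs) / sqrt(e)
    err <- 0.5 * (obs / rowm + obs / colm)
    list(s = s, err = err,
         pass = !is.na(s) & !is.na(err) & e > 0 &
                s > params$s_min & err < params$err_max)
  }
  t00 <- pass_q(A00, rowlow, collow)
  t01 <- pass_q(A01, rowlow, colhigh)
  t10 <- pass_q(A10, rowhigh, collow)
  t11 <- pass_q(A11, rowhigh, colhigh)
  npass <- t00$pass + t01$pass + t10$pass + t11$pass
  kind <- matrix("none", length(ids), length(ids))
  kind[npass == 1 & t00$pass] <- "low_high"
  kind[npass == 1 & t01$pass] <- "low_low"
  kind[npass == 1 & t10$pass] <- "high_high"
  kind[npass == 1 & t11$pass] <- "high_low"
  kind[npass == 2 & t01$pass & t10$pass] <- "equivalent"
  kind[npass == 2 & t00$pass & t11$pass] <- "opposite"
  ut <- which(upper.tri(kind) & kind != "none", arr.ind = TRUE)
  recs <- if (nrow(ut) == 0) empty else data.frame(
    otu_a = ids[ut[, 1]], otu_b = ids[ut[, 2]], kind = kind[ut],
    a00 = A00[ut], a01 = A01[ut], a10 = A10[ut], a11 = A11[ut],
    n_used = tot[ut],
    s00 = t00$s[ut], s01 = t01$s[ut], s10 = t10$s[ut], s11 = t11$s[ut],
    err00 = t00$err[ut], err01 = t01$err[ut],
    err10 = t10$err[ut], err11 = t11$err[ut],
    stringsAsFactors = FALSE)
  recs <- recs[order(recs$otu_a, recs$otu_b), , drop = FALSE]
  rownames(recs) <- NULL
  new_relation_table(recs, dataset_id,
                     as.integer(choose(length(ids), 2)), ids,
                     colnames(discrete)[!keep], params)
}

relation_records <- function(n) {
  data.frame(otu_a = character(n), otu_b = character(n), kind = character(n),
             a00 = integer(n), a01 = integer(n), a10 = integer(n),
             a11 = integer(n), n_used = integer(n),
             s00 = numeric(n), s01 = numeric(n), s10 = numeric(n),
             s11 = numeric(n), err00 = numeric(n), err01 = numeric(n),
             err10 = numeric(n), err11 = numeric(n),
             stringsAsFactors = FALSE)
}

new_relation_table <- function(recs, dataset_id, n_pairs_tested,
                               microbes_tested, microbes_dropped, params) {
  structure(recs, dataset_id = dataset_id,
            n_pairs_tested = n_pairs_tested,
            microbes_tested = microbes_tested,
            microbes_dropped = microbes_dropped,
            params = params,
            class = c("relation_table", "data.frame"))
}

#' @export
print.relation_table <- function(x, ...) {
  cat(sprintf("Boolean relation table '%s': %d relationship(s) from %d pair(s) of %d microbe(s)\n",
              attr(x, "dataset_id"), nrow(x), attr(x, "n_pairs_tested"),
              length(attr(x, "microbes_tested"))))
  if (nrow(x)) print(table(kind = x$kind))
  invisible(x)
}

#' Permutation-based false discovery rate for a Boolean implication scan
#'
#' Each microbe's values are independently permuted across samples
#' `n_perm` times and relationships are recounted with identical
#' parameters. The FDR is the ratio of the average relationship count in
#' the permuted datasets to the count in the original dataset (undefined
#' when the original count is zero). StepMiner thresholds are invariant to
#' sample permutation, so the original fits are reused; equivalently, the
#' discretized state vectors themselves are permuted.
#'
#' @param m Abundance matrix of log2 values (or a
#'   `"stepminer_thresholds"` object to skip refitting).
#' @param margin Discretization noise half-width; default 0.5.
#' @param params A [significance_params()] list.
#' @param n_perm Number of permutation rounds; default 10.
#' @param seed Integer seed governing all shuffles.
#' @return A list of class `"fdr_result"`: `n_original`,
#'   `per_permutation_counts`, `mean_permuted`, `fdr` (`NA` when
#'   undefined), `n_perm`, `seed`.
#' @export
permutation_fdr <- function(m, margin = 0.5, params = significance_params(),
                            n_perm = 10, seed = NULL) {
  if (n_perm < 1)
    stop_stage("discovery", "n_perm must be >= 1")
  tm <- if (inherits(m, "stepminer_thresholds")) m
        else threshold_matrix(m, margin)
  orig <- scan_pairs(tm$discrete, params)
  n_original <- nrow(orig)
  disc <- tm$discrete
  n <- nrow(disc)
  counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(r) {
      perm <- disc
      for (j in seq_len(ncol(disc)))        # fixed microbe order for determinism
        perm[, j] <- disc[sample.int(n), j]
      nrow(suppressWarnings(scan_pairs(perm, params)))
    }, integer(1))
  })
  structure(list(n_original = n_original,
                 per_permutation_counts = counts,
                 mean_permuted = mean(counts),
                 fdr = if (n_original > 0) mean(counts) / n_original
                       else NA_real_,
                 n_perm = n_perm, seed = seed,
                 original = orig), class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("Permutation FDR: %d original relationship(s), mean %.2f over %d permutation(s)\n",
              x$n_original, x$mean_permuted, x$n_perm))
  cat(sprintf("  FDR = %s\n",
              if (is.na(x$fdr)) "undefined (no original relationships)"
              else format(x$fdr, digits = 4)))
  invisible(x)
}

#' Relationships consistent across several datasets
#'
#' A pair is a candidate invariant when both microbes passed the
#' dynamic-range filter in every dataset and the pair carries the
#' identical relationship kind in every dataset. Pairs significant
#' somewhere but untestable (a microbe absent or filtered) elsewhere are
#' excluded from the invariants and tallied separately — absence of
#' evidence is not treated as inconsistency.
#'
#' @param tables List of `"relation_table"` objects with distinct
#'   `dataset_id`s.
#' @param k_required Number of datasets that must report the identical
#'   kind; default all. The pair must still be testable in every dataset
#'   and must not carry a conflicting kind anywhere.
#' @return A list of class `"invariant_table"`: `invariants` (data.frame
#'   `otu_a`, `otu_b`, `kind`, `n_datasets`, with per-dataset minimum S
#'   and maximum error rate over the supporting quadrants), `untestable`
#'   (data.frame of excluded pairs), `n_datasets`.
#' @export
find_invariants <- function(tables, k_required = length(tables)) {
  if (length(tables) < 2)
    stop_stage("discovery", "need at least 2 relation tables")
  ids <- vapply(tables, attr, character(1), "dataset_id")
  if (anyDuplicated(ids))
    stop_stage("discovery", "duplicate dataset_id: %s",
               ids[duplicated(ids)][1])
  k <- length(tables)
  tested <- lapply(tables, attr, "microbes_tested")
  keys <- unique(unlist(lapply(tables, function(t)
    if (nrow(t)) paste(t$otu_a, t$otu_b, sep = "\r") else character())))
  inv <- list(); unt <- list()
  for (key in keys) {
    pair <- strsplit(key, "\r", fixed = TRUE)[[1]]
    testable <- vapply(tested, function(ms)
      all(pair %in% ms), logical(1))
    kinds <- vapply(tables, function(t) {
      i <- which(t$otu_a == pair[1] & t$otu_b == pair[2])
      if (length(i)) t$kind[i[1]] else "none"
    }, character(1))
    if (!all(testable)) {
      unt[[key]] <- data.frame(otu_a = pair[1], otu_b = pair[2],
                               n_testable = sum(testable),
                               stringsAsFactors = FALSE)
      next
    }
    observed <- kinds[kinds != "none"]
    if (length(unique(observed)) == 1 && length(observed) >= k_required &&
        (k_required < k || all(kinds != "none"))) {
      s_min_ds <- vapply(seq_len(k), function(d) {
        t <- tables[[d]]
        i <- which(t$otu_a == pair[1] & t$otu_b == pair[2])
        if (!length(i)) return(NA_real_)
        min(unlist(t[i, c("s00", "s01", "s10", "s11")]), na.rm = TRUE)
      }, numeric(1))
      inv[[key]] <- data.frame(otu_a = pair[1], otu_b = pair[2],
                               kind = observed[1], n_datasets = k,
                               min_s = min(s_min_ds, na.rm = TRUE),
                               stringsAsFactors = FALSE)
    }
  }
  bind <- function(lst, empty) if (length(lst)) {
    out <- do.call(rbind, lst)
    rownames(out) <- NULL
    out[order(out$otu_a, out$otu_b), , drop = FALSE]
  } else empty
  structure(list(
    invariants = bind(inv, data.frame(otu_a = character(), otu_b = character(),
                                      kind = character(), n_datasets = integer(),
                                      min_s = numeric())),
    untestable = bind(unt, data.frame(otu_a = character(), otu_b = character(),
                                      n_testable = integer())),
    n_datasets = k), class = "invariant_table")
}

#' @export
print.invariant_table <- function(x, ...) {
  cat(sprintf("%d candidate invariant(s) across %d datasets (%d pair(s) untestable somewhere)\n",
              nrow(x$invariants), x$n_datasets, nrow(x$untestable)))
  if (nrow(x$invariants)) print(table(kind = x$invariants$kind))
  invisible(x)
}

#' Pearson correlation of related pairs, summarized by relationship kind
#'
#' Mirrors a correlation-based co-occurrence analysis: for each related
#' pair (restricted to a random subset of microbes when the matrix is
#' large), the Pearson correlation of the two microbes' log2 abundances
#' is computed over all samples — intermediate samples are not excluded —
#' and binned per relationship kind.
#'
#' @param m Abundance matrix of log2 values.
#' @param rt A `"relation_table"` from [scan_pairs()].
#' @param subset_size Number of microbes to subsample; default 500. When
#'   the matrix has fewer microbes, all are used.
#' @param seed Seed for the subsample.
#' @return A list of class `"corr_summary"`: `pairs` (data.frame `otu_a`,
#'   `otu_b`, `kind`, `r`), `histogram` (kind x bin count matrix, bins of
#'   width 0.1 on \[-1, 1\]), `n_excluded` (pairs dropped for zero
#'   variance).
#' @export
correlate_by_relation <- function(m, rt, subset_size = 500, seed = NULL) {
  microbes <- colnames(m)
  if (length(microbes) > subset_size)
    microbes <- with_seed(seed, sample(microbes, subset_size))
  recs <- rt[rt$otu_a %in% microbes & rt$otu_b %in% microbes, , drop = FALSE]
  r <- vapply(seq_len(nrow(recs)), function(i)
    suppressWarnings(stats::cor(m[, recs$otu_a[i]], m[, recs$otu_b[i]],
                                method = "pearson")), numeric(1))
  pairs <- data.frame(otu_a = recs$otu_a, otu_b = recs$otu_b,
                      kind = recs$kind, r = r, stringsAsFactors = FALSE)
  n_excluded <- sum(is.na(pairs$r))
  pairs <- pairs[!is.na(pairs$r), , drop = FALSE]
  breaks <- seq(-1, 1, by = 0.1)
  kinds <- sort(unique(pairs$kind))
  hist <- t(vapply(kinds, function(k)
    table(cut(pairs$r[pairs$kind == k], breaks, include.lowest = TRUE)),
    integer(length(breaks) - 1)))
  structure(list(pairs = pairs, histogram = hist, breaks = breaks,
                 n_excluded = n_excluded, subset = microbes),
            class = "corr_summary")
}

#' @export
print.corr_summary <- function(x, ...) {
  cat(sprintf("Correlation summary over %d related pair(s) (%d excluded, zero variance)\n",
              nrow(x$pairs), x$n_excluded))
  if (nrow(x$pairs)) {
    med <- tapply(x$pairs$r, x$pairs$kind, stats::median)
    for (k in names(med))
      cat(sprintf("  %-10s median r = %+.3f\n", k, med[k]))
  }
  invisible(x)
}

#' Differential abundance between two metadata groups
#'
#' Per-OTU two-sample t-test (Welch by default) on log2 abundances
#' between the samples of two levels of a metadata factor, reporting the
#' mean difference (group_a - group_b), t statistic, p value and
#' -log10(p). OTUs are ranked by descending -log10(p), ties broken by
#' absolute mean difference; OTUs whose test is undefined (zero variance
#' in both groups with equal means) carry `NA` statistics and sort last.
#'
#' @param m Abundance matrix of log2 values.
#' @param meta A `"sample_metadata"` data.frame (aligned internally).
#' @param factor_name Metadata column defining the groups.
#' @param group_a,group_b Factor levels to compare.
#' @param var_equal Use the pooled-variance (Student) t-test instead of
#'   Welch; default `FALSE`.
#' @return A data.frame of class `"diff_table"`: `otu_id`, `mean_diff`,
#'   `t`, `p`, `neg_log10_p`.
#' @export
differential_metadata <- function(m, meta, factor_name, group_a, group_b,
                                  var_equal = FALSE) {
  al <- align_samples(m, meta)
  fac <- al$metadata[[factor_name]]
  if (is.null(fac))
    stop_stage("discovery", "metadata factor '%s' not found", factor_name)
  ia <- which(!is.na(fac) & fac == group_a)
  ib <- which(!is.na(fac) & fac == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop_stage("discovery", "each group needs >= 2 samples (got %d and %d)",
               length(ia), length(ib))
  res <- lapply(colnames(al$abundance), function(otu) {
    xa <- al$abundance[ia, otu]
    xb <- al$abundance[ib, otu]
    tt <- tryCatch(stats::t.test(xa, xb, var.equal = var_equal),
                   error = function(e) NULL)   # constant data -> undefined
    data.frame(otu_id = otu, mean_diff = mean(xa) - mean(xb),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$neg_log10_p <- -log10(out$p)
  out <- out[order(-out$neg_log10_p, -abs(out$mean_diff), out$otu_id,
                   na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diff_table", "data.frame")
  out
}

#' Write a relation table TSV
#'
#' Leading `#key=value` comment lines preserve the dataset id, tested
#' microbes and parameters so that [read_relation_table()] can restore a
#' table usable by [find_invariants()].
#'
#' @param rt A `"relation_table"`.
#' @param path Output path.
#' @export
write_relation_table <- function(rt, path) {
  p <- attr(rt, "params")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#dataset_id=%s", attr(rt, "dataset_id")),
    sprintf("#n_pairs_tested=%d", attr(rt, "n_pairs_tested")),
    sprintf("#microbes_tested=%s",
            paste(attr(rt, "microbes_tested"), collapse = ",")),
    sprintf("#params=s_min:%g,err_max:%g,min_side_fraction:%g,min_side_count:%g",
            p$s_min, p$err_max, p$min_side_fraction, p$min_side_count)), con)
  utils::write.table(rt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a relation table written by [write_relation_table()]
#'
#' @param path Path to the TSV.
#' @return A `"relation_table"` data.frame with restored attributes.
#' @export
read_relation_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines)
  meta <- sub("^#", "", lines[hdr])
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x)
    paste(x[-1], collapse = "="), character(1)),
    vapply(kv, `[[`, character(1), 1))
  recs <- utils::read.delim(text = lines[-hdr], sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = c(otu_a = "character",
                                           otu_b = "character"))
  pp <- strsplit(strsplit(vals[["params"]], ",")[[1]], ":")
  pl <- stats::setNames(as.numeric(vapply(pp, `[[`, character(1), 2)),
                        vapply(pp, `[[`, character(1), 1))
  new_relation_table(
    recs, vals[["dataset_id"]], as.integer(vals[["n_pairs_tested"]]),
    if (nzchar(vals[["microbes_tested"]]))
      strsplit(vals[["microbes_tested"]], ",")[[1]] else character(),
    character(),
    significance_params(pl[["s_min"]], pl[["err_max"]],
                        pl[["min_side_fraction"]], pl[["min_side_count"]]))
}
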