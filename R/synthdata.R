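# Synthetic OTU tables with planted Boolean implication structure.
#
# Each planted pair lives in log2 space: every sample is assigned to one of
# the four quadrants, and the two microbes draw values around a low or high
# mode according to the quadrant, so per-microbe marginals are bimodal and
# the pair's sparse quadrant(s) carry only the leak mass. Values are
# back-transformed to integer counts so fixtures exercise the real
# I/O + log2 path.

SPARSE_QUADRANTS <- list(
  low_high = "q00", low_low = "q01", high_high = "q10", high_low = "q11",
  equivalent = c("q01", "q10"), opposite = c("q00", "q11"),
  none = character())

#' Specification of one planted microbe pair
#'
#' @param kind Relationship kind to plant (any of the six, or `"none"`
#'   for an independent bimodal pair).
#' @param low_mode,high_mode Centers of the low and high log2-abundance
#'   modes; defaults 2 and 6 (4 log2 units of separation).
#' @param noise_sd Gaussian spread around each mode; default 0.5.
#' @param leak_rate Probability mass placed in the sparse quadrant(s);
#'   default 0.02, so the error-rate test is exercised, not only S.
#' @param quadrant_weights Optional probabilities over the non-sparse
#'   quadrants (named subset of q00, q01, q10, q11, summing to 1 with the
#'   leak); default uniform over the non-sparse quadrants.
#' @return A list of class `"pair_spec"` with the resolved per-quadrant
#'   probabilities in `probs` (ordered q00, q01, q10, q11).
#' @export
pair_spec <- function(kind = "equivalent", low_mode = 2, high_mode = 6,
                      noise_sd = 0.5, leak_rate = 0.02,
                      quadrant_weights = NULL) {
  if (!kind %in% c(RELATION_KINDS, "none"))
    stop_stage("synthdata", "unknown kind '%s'", kind)
  sparse <- SPARSE_QUADRANTS[[kind]]
  dense <- setdiff(QUADRANTS, sparse)
  if (kind == "none") leak_rate <- 0
  probs <- stats::setNames(numeric(4), QUADRANTS)
  if (length(sparse)) probs[sparse] <- leak_rate / length(sparse)
  if (is.null(quadrant_weights)) {
    probs[dense] <- (1 - leak_rate) / length(dense)
  } else {
    if (!all(names(quadrant_weights) %in% dense))
      stop_stage("synthdata", "quadrant_weights must cover only the non-sparse quadrants")
    w <- quadrant_weights / sum(quadrant_weights)
    probs[names(w)] <- w * (1 - leak_rate)
  }
  if (abs(sum(probs) - 1) > 1e-8 || any(probs < 0))
    stop_stage("synthdata", "quadrant probabilities must be nonnegative and sum to 1")
  structure(list(kind = kind, low_mode = low_mode, high_mode = high_mode,
                 noise_sd = noise_sd, leak_rate = leak_rate, probs = probs),
            class = "pair_spec")
}

#' Draw one planted microbe pair in log2 space
#'
#' Uses the current RNG stream; seed at the caller (see
#' [generate_dataset()]).
#'
#' @param spec A [pair_spec()].
#' @param n Number of samples (>= 8).
#' @return A list with numeric vectors `a` and `b` of log2 abundances and
#'   the drawn `quadrant` per sample.
#' @export
plant_pair <- function(spec, n) {
  stopifnot(inherits(spec, "pair_spec"))
  if (n < 8)
    stop_stage("synthdata", "need n >= 8 samples, got %d", n)
  qd <- sample(QUADRANTS, n, replace = TRUE, prob = spec$probs)
  a_high <- qd %in% c("q10", "q11")
  b_high <- qd %in% c("q01", "q11")
  mode_of <- function(high) ifelse(high, spec$high_mode, spec$low_mode)
  list(a = stats::rnorm(n, mode_of(a_high), spec$noise_sd),
       b = stats::rnorm(n, mode_of(b_high), spec$noise_sd),
       quadrant = qd)
}

#' Generate a synthetic OTU count table with known truth
#'
#' Planted pairs occupy consecutive microbe columns; the remaining decoy
#' microbes are independent — drawn from a single log-normal mode, or as
#' shuffled copies of planted columns (bimodal but structure-free), or an
#' even mixture (default). Log2 values v are emitted as integer counts
#' `max(round(2^v - pseudocount), 0)`.
#'
#' @param n_samples Number of samples.
#' @param n_microbes Total microbes (>= 2 x number of planted pairs).
#' @param planted List of [pair_spec()] objects.
#' @param seed Integer seed; the matrix is deterministic given it.
#' @param pseudocount Pseudocount assumed by the downstream log2
#'   transform; default 1.
#' @param decoy One of `"mixed"`, `"lognormal"`, `"shuffled"`.
#' @return A list of class `"synthetic_dataset"`: `counts` (an
#'   `"otu_counts"` matrix), `truth` (data.frame `otu_a`, `otu_b`, `kind`,
#'   `leak_rate`), `seed`.
#' @export
generate_dataset <- function(n_samples, n_microbes, planted = list(),
                             seed = NULL, pseudocount = 1,
                             decoy = c("mixed", "lognormal", "shuffled")) {
  decoy <- match.arg(decoy)
  if (2 * length(planted) > n_microbes)
    stop_stage("synthdata", "%d planted pairs need %d microbes, only %d available",
               length(planted), 2 * length(planted), n_microbes)
  with_seed(seed, {
    ids <- sprintf("OTU_%04d", seq_len(n_microbes))
    vals <- matrix(NA_real_, n_samples, n_microbes,
                   dimnames = list(sprintf("S%04d", seq_len(n_samples)), ids))
    truth <- relation_truth(0)
    for (i in seq_along(planted)) {
      pp <- plant_pair(planted[[i]], n_samples)
      ja <- 2 * i - 1; jb <- 2 * i
      vals[, ja] <- pp$a
      vals[, jb] <- pp$b
      truth <- rbind(truth, data.frame(
        otu_a = ids[ja], otu_b = ids[jb], kind = planted[[i]]$kind,
        leak_rate = planted[[i]]$leak_rate, stringsAsFactors = FALSE))
    }
    decoy_cols <- seq_len(n_microbes)[-seq_len(2 * length(planted))]
    planted_cols <- seq_len(2 * length(planted))
    for (j in decoy_cols) {
      use_shuffle <- length(planted_cols) > 0 &&
        (decoy == "shuffled" || (decoy == "mixed" && j %% 2 == 0))
      vals[, j] <- if (use_shuffle) {
        sample(vals[, sample(planted_cols, 1)])
      } else {
        stats::rnorm(n_samples, stats::runif(1, 3, 5), 1)
      }
    }
    counts <- pmax(round(2^vals - pseudocount), 0)
    structure(list(counts = count_matrix(counts), truth = truth,
                   seed = seed),
              class = "synthetic_dataset")
  })
}

relation_truth <- function(n) {
  data.frame(otu_a = character(n), otu_b = character(n),
             kind = character(n), leak_rate = numeric(n),
             stringsAsFactors = FALSE)
}

#' Generate several datasets sharing the same planted truth
#'
#' Emulates independent validation cohorts: the planted relationships are
#' identical across datasets while noise realizations differ and sample
#' sizes jitter around `n_samples`.
#'
#' @param n_samples Baseline sample count.
#' @param n_microbes Microbes per dataset.
#' @param planted List of [pair_spec()] objects shared by all datasets.
#' @param k Number of datasets (>= 2).
#' @param seed Integer seed.
#' @param size_jitter Relative jitter on the per-dataset sample count;
#'   default 0.2.
#' @param pseudocount,decoy Passed to [generate_dataset()].
#' @return List of `k` `"synthetic_dataset"` objects.
#' @export
generate_multidataset <- function(n_samples, n_microbes, planted = list(),
                                  k = 2, seed = NULL, size_jitter = 0.2,
                                  pseudocount = 1, decoy = "mixed") {
  if (k < 2)
    stop_stage("synthdata", "need k >= 2 datasets")
  with_seed(seed, {
    lapply(seq_len(k), function(d) {
      n_d <- max(8, round(n_samples *
                            stats::runif(1, 1 - size_jitter, 1 + size_jitter)))
      ds <- generate_dataset(n_d, n_microbes, planted, seed = NULL,
                             pseudocount = pseudocount, decoy = decoy)
      ds$dataset_id <- sprintf("synthetic_%d", d)
      ds
    })
  })
}

#' Write the planted truth of a synthetic dataset as TSV
#'
#' Columns: otu_a, otu_b, kind, leak_rate.
#' @param ds A `"synthetic_dataset"`.
#' @param path Output path.
#' @export
write_truth_table <- function(ds, path) {
  utils::write.table(ds$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
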