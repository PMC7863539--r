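# End-to-end pipeline: threshold -> scan -> FDR -> invariants ->
# correlation, with tabular outputs and a provenance manifest.

#' Pipeline configuration
#'
#' Every statistical default equals the published convention: margin 0.5,
#' S > 3, error rate < 0.1, 10 permutation rounds.
#'
#' @param inputs Character vector of OTU-table paths (one or more
#'   datasets).
#' @param metadata Optional mapping-file path.
#' @param out_dir Output directory.
#' @param pseudocount,scaling Log2-transform options.
#' @param margin Discretization noise half-width.
#' @param s_min,err_max,min_side_fraction,min_side_count Significance and
#'   range-filter parameters (see [significance_params()]).
#' @param n_perm Permutation rounds for the FDR.
#' @param subset_size Microbe subset for the correlation summary.
#' @param seed Integer seed governing all randomness in the run.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(inputs = character(), metadata = NULL,
                       out_dir = ".", pseudocount = 1, scaling = "none",
                       margin = 0.5, s_min = 3, err_max = 0.1,
                       min_side_fraction = 0.05, min_side_count = 3,
                       n_perm = 10, subset_size = 500, seed = 1) {
  structure(list(inputs = inputs, metadata = metadata, out_dir = out_dir,
                 pseudocount = pseudocount, scaling = scaling,
                 margin = margin, s_min = s_min, err_max = err_max,
                 min_side_fraction = min_side_fraction,
                 min_side_count = min_side_count, n_perm = n_perm,
                 subset_size = subset_size, seed = seed),
            class = "run_config")
}

#' Run the full Boolean implication pipeline
#'
#' For each input OTU table: read, log2-transform, fit thresholds, scan
#' all pairs, and estimate the permutation FDR. With several inputs,
#' cross-dataset invariants are nominated. Writes, per dataset,
#' `<name>_thresholds.tsv`, `<name>_relations.tsv` and a combined
#' `fdr_report.tsv`, `correlations.tsv`, optional `invariants.tsv`, and a
#' `manifest.json` recording the configuration, seed, package version and
#' drop counts.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the per-dataset `"bia"` fits, FDR
#'   results, the invariant table (or `NULL`) and the written paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (length(cfg$inputs) == 0)
    stop_stage("cli_report", "no input OTU tables given")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- significance_params(cfg$s_min, cfg$err_max,
                                cfg$min_side_fraction, cfg$min_side_count)
  paths <- character()
  fits <- list()
  fdrs <- list()
  for (i in seq_along(cfg$inputs)) {
    inp <- cfg$inputs[i]
    name <- sub("\\.[^.]*$", "", basename(inp))
    counts <- read_otu_table(inp)
    fit <- bia(counts, pseudocount = cfg$pseudocount, scaling = cfg$scaling,
               margin = cfg$margin, params = params, dataset_id = name)
    fdrs[[name]] <- permutation_fdr(fit$thresholds, cfg$margin, params,
                                    n_perm = cfg$n_perm,
                                    seed = cfg$seed + i)
    p1 <- file.path(cfg$out_dir, paste0(name, "_thresholds.tsv"))
    p2 <- file.path(cfg$out_dir, paste0(name, "_relations.tsv"))
    write_threshold_table(fit$thresholds, p1)
    write_relation_table(fit$relations, p2)
    paths <- c(paths, p1, p2)
    fits[[name]] <- fit
  }
  fdr_df <- data.frame(
    dataset = names(fdrs),
    n_original = vapply(fdrs, `[[`, integer(1), "n_original"),
    mean_permuted = vapply(fdrs, `[[`, numeric(1), "mean_permuted"),
    fdr = vapply(fdrs, `[[`, numeric(1), "fdr"),
    n_perm = cfg$n_perm, row.names = NULL)
  p <- file.path(cfg$out_dir, "fdr_report.tsv")
  utils::write.table(fdr_df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  inv <- NULL
  if (length(fits) > 1) {
    inv <- find_invariants(lapply(fits, `[[`, "relations"))
    p <- file.path(cfg$out_dir, "invariants.tsv")
    utils::write.table(inv$invariants, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  cs <- correlate_by_relation(fits[[1]]$abundance, fits[[1]]$relations,
                              subset_size = cfg$subset_size, seed = cfg$seed)
  p <- file.path(cfg$out_dir, "correlations.tsv")
  utils::write.table(cs$pairs, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  manifest <- list(
    config = unclass(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("boolimp")),
    datasets = lapply(fits, function(f) list(
      n_samples = nrow(f$abundance),
      n_microbes = ncol(f$abundance),
      n_tested = length(attr(f$relations, "microbes_tested")),
      n_dropped = length(attr(f$relations, "microbes_dropped")),
      n_relationships = nrow(f$relations))))
  p <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, p)
  invisible(list(fits = fits, fdr = fdrs, invariants = inv,
                 correlation = cs, paths = paths))
}

#' Export a pair's per-sample scatter data
#'
#' One row per sample with the two microbes' log2 abundances (the scales
#' of the scatter plots) and, optionally, a metadata factor column for
#' coloring; missing factor values are emitted as NA with the row
#' retained.
#'
#' @param m Abundance matrix of log2 values.
#' @param otu_a,otu_b Microbe ids (x- and y-axis).
#' @param meta Optional `"sample_metadata"`.
#' @param factor_name Optional metadata column to attach.
#' @param path Optional TSV output path.
#' @return Data.frame with `sample_id`, `x`, `y` and, when requested, the
#'   factor column.
#' @export
export_pair_scatter <- function(m, otu_a, otu_b, meta = NULL,
                                factor_name = NULL, path = NULL) {
  for (id in c(otu_a, otu_b))
    if (!id %in% colnames(m))
      stop_stage("cli_report", "unknown OTU id '%s'", id)
  df <- data.frame(sample_id = rownames(m), x = m[, otu_a], y = m[, otu_b],
                   row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(factor_name)) {
    if (is.null(meta))
      stop_stage("cli_report", "factor requested but no metadata given")
    df[[factor_name]] <- meta[df$sample_id, factor_name]
  }
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    return(invisible(df))
  }
  df
}
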