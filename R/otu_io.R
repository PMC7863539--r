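# Reading OTU tables and sample metadata, and the log2 transform.
#
# Internal orientation convention: samples are rows, OTUs are columns.
# Classic QIIME tables store OTUs as rows, so the reader transposes once
# at the I/O boundary.

#' Construct a validated OTU count matrix
#'
#' A count matrix is a plain numeric matrix with samples as rows and OTUs
#' as columns, carrying unique sample and OTU identifiers in its dimnames.
#'
#' @param values Numeric matrix of nonnegative counts, samples x OTUs.
#' @param sample_ids,otu_ids Optional character vectors overriding the
#'   dimnames of `values`.
#' @return A numeric matrix of class `"otu_counts"`.
#' @export
count_matrix <- function(values, sample_ids = rownames(values),
                         otu_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop_stage("otu_io", "counts must be numeric")
  if (anyNA(values))
    stop_stage("otu_io", "counts contain missing values")
  if (any(values < 0))
    stop_stage("otu_io", "negative count encountered")
  if (is.null(sample_ids) || is.null(otu_ids))
    stop_stage("otu_io", "sample and OTU identifiers are required")
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (length(sample_ids) != nrow(values) || length(otu_ids) != ncol(values))
    stop_stage("otu_io", "identifier lengths do not match matrix dimensions")
  if (anyDuplicated(sample_ids))
    stop_stage("otu_io", "duplicate sample id: %s",
               sample_ids[duplicated(sample_ids)][1])
  if (anyDuplicated(otu_ids))
    stop_stage("otu_io", "duplicate OTU id: %s",
               otu_ids[duplicated(otu_ids)][1])
  dimnames(values) <- list(sample_ids, otu_ids)
  class(values) <- c("otu_counts", class(values))
  values
}

#' Read an OTU table
#'
#' Reads a classic QIIME tab-delimited OTU table (first header cell
#' `"#OTU ID"`, OTUs as rows) or a BIOM file (via the \pkg{biomformat}
#' package), and returns counts oriented samples x OTUs. An optional
#' trailing `taxonomy` column in classic tables is stored as the
#' `"taxonomy"` attribute and excluded from the counts.
#'
#' @param path Path to the table.
#' @param format_hint One of `"auto"`, `"classic_tsv"`, `"biom"`. `"auto"`
#'   treats `.biom` files (or files starting with `{`, BIOM JSON) as BIOM.
#' @return An [count_matrix()] of class `"otu_counts"`.
#' @export
read_otu_table <- function(path, format_hint = c("auto", "classic_tsv", "biom")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path))
    stop_stage("otu_io", "file not found: %s", path)
  if (format_hint == "auto") {
    first <- substr(readLines(path, n = 1L, warn = FALSE), 1, 1)
    format_hint <- if (grepl("\\.biom$", path, ignore.case = TRUE) ||
                       identical(first, "{")) "biom" else "classic_tsv"
  }
  if (format_hint == "biom") read_otu_biom(path) else read_otu_classic(path)
}

read_otu_classic <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#OTU ID\t", lines)
  if (length(hdr) == 0)
    stop_stage("otu_io", "not a classic OTU table: no '#OTU ID' header in %s",
               path)
  hdr <- hdr[1]
  # Leading comment lines (e.g. "# Constructed from biom file") are allowed
  # only before the header.
  body <- lines[hdr:length(lines)]
  tab <- utils::read.delim(text = body, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "",
                           colClasses = "character",
                           na.strings = character())
  names(tab)[1] <- "otu_id"
  tax_col <- which(tolower(names(tab)) %in% c("taxonomy", "consensus lineage"))
  taxonomy <- NULL
  if (length(tax_col)) {
    taxonomy <- stats::setNames(tab[[tax_col[1]]], tab$otu_id)
    tab <- tab[, -tax_col, drop = FALSE]
  }
  if (ncol(tab) < 2)
    stop_stage("otu_io", "OTU table has no sample columns")
  otu_ids <- tab$otu_id
  if (anyDuplicated(otu_ids))
    stop_stage("otu_io", "duplicate OTU id: %s",
               otu_ids[duplicated(otu_ids)][1])
  vals <- suppressWarnings(
    vapply(tab[-1], as.numeric, numeric(nrow(tab))))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(otu_ids, names(tab)[-1]))
  if (anyNA(vals))
    stop_stage("otu_io", "non-numeric count value in %s", path)
  m <- count_matrix(t(vals))                       # transpose: samples x OTUs
  attr(m, "taxonomy") <- taxonomy
  m
}

read_otu_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop_stage("otu_io", "reading BIOM requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  vals <- as.matrix(biomformat::biom_data(b))      # features x samples
  count_matrix(t(vals))
}

#' Write a count matrix as a classic OTU table
#'
#' @param m An `"otu_counts"` matrix.
#' @param path Output path.
#' @export
write_otu_table <- function(m, path) {
  tab <- t(unclass(m))                             # back to OTUs x samples
  df <- data.frame(`#OTU ID` = rownames(tab), tab, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata mapping file
#'
#' Tab-delimited mapping file whose first header cell is `"#SampleID"`.
#' Factor values are kept verbatim as strings; empty cells become `NA`.
#'
#' @param path Path to the mapping file.
#' @return A data.frame of class `"sample_metadata"` with sample ids as row
#'   names and one character column per metadata factor.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path))
    stop_stage("otu_io", "file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "",
                           colClasses = "character", na.strings = "")
  if (names(tab)[1] != "#SampleID")
    stop_stage("otu_io", "not a mapping file: first header cell is '%s', expected '#SampleID'",
               names(tab)[1])
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop_stage("otu_io", "duplicate sample id: %s", ids[duplicated(ids)][1])
  meta <- tab[, -1, drop = FALSE]
  rownames(meta) <- ids
  class(meta) <- c("sample_metadata", "data.frame")
  meta
}

#' Log2-transform an OTU count matrix
#'
#' `value = log2(scaled_count + pseudocount)`. With `scaling = "total_sum"`
#' each sample is first rescaled to a common sequencing depth
#' (`count * depth / sample_total`); with the default `scaling = "none"`
#' the counts are used as-is (appropriate for pre-normalized tables).
#'
#' @param m An `"otu_counts"` matrix (or any nonnegative numeric matrix
#'   with dimnames).
#' @param pseudocount Positive offset added before the log; default 1, so
#'   zero counts map to 0 on the log2 scale.
#' @param scaling `"none"` or `"total_sum"`.
#' @param depth Target depth for `total_sum` scaling; defaults to the
#'   median sample total.
#' @return A numeric matrix of class `"otu_abundance"` with attributes
#'   `pseudocount`, `scaling` and (when scaled) `depth`.
#' @export
transform_log2 <- function(m, pseudocount = 1,
                           scaling = c("none", "total_sum"), depth = NULL) {
  scaling <- match.arg(scaling)
  vals <- unclass(as.matrix(m))
  if (pseudocount <= 0 && any(vals == 0))
    stop_stage("otu_io", "pseudocount must be > 0 when zero counts are present")
  if (scaling == "total_sum") {
    totals <- rowSums(vals)
    if (any(totals == 0))
      stop_stage("otu_io", "sample with zero total count under total_sum scaling: %s",
                 rownames(vals)[totals == 0][1])
    depth <- depth %||% stats::median(totals)
    vals <- vals * (depth / totals)
  }
  out <- log2(vals + pseudocount)
  attr(out, "pseudocount") <- pseudocount
  attr(out, "scaling") <- scaling
  if (scaling == "total_sum") attr(out, "depth") <- depth
  class(out) <- c("otu_abundance", class(out))
  out
}

#' Restrict an abundance matrix and metadata to their common samples
#'
#' Both objects are subset to the intersection of their sample ids, in the
#' order the samples appear in the matrix. Drop counts are reported with a
#' message.
#'
#' @param m An `"otu_abundance"` (or `"otu_counts"`) matrix.
#' @param meta A `"sample_metadata"` data.frame.
#' @return A list with elements `abundance` and `metadata`.
#' @export
align_samples <- function(m, meta) {
  common <- intersect(rownames(m), rownames(meta))
  if (length(common) == 0)
    stop_stage("otu_io", "no samples in common between matrix and metadata")
  drop_m <- nrow(m) - length(common)
  drop_meta <- nrow(meta) - length(common)
  if (drop_m > 0 || drop_meta > 0)
    message(sprintf("align_samples: dropped %d matrix sample(s), %d metadata sample(s)",
                    drop_m, drop_meta))
  at <- attributes(m)
  m2 <- m[common, , drop = FALSE]
  for (a in setdiff(names(at), c("dim", "dimnames")))
    attr(m2, a) <- at[[a]]
  meta2 <- meta[common, , drop = FALSE]
  class(meta2) <- class(meta)
  list(abundance = m2, metadata = meta2)
}
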