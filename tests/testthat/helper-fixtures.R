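# Small fixture builders used across test files.

# Quadrant-count object from four cell counts.
qc <- function(a00, a01, a10, a11) {
  structure(list(a00 = a00, a01 = a01, a10 = a10, a11 = a11,
                 n_used = a00 + a01 + a10 + a11,
                 n_dropped_intermediate = 0L),
            class = "quadrant_counts")
}

# Discrete state vectors realizing the four cell counts of a pair.
states_from_cells <- function(a00, a01, a10, a11) {
  list(dA = rep(c(0L, 0L, 2L, 2L), c(a00, a01, a10, a11)),
       dB = rep(c(0L, 2L, 0L, 2L), c(a00, a01, a10, a11)))
}

# Classic QIIME OTU table fixture on disk (OTUs x samples, counts by row).
write_classic_fixture <- function(path, counts, otu_ids, sample_ids,
                                  taxonomy = NULL, leading_comment = TRUE) {
  lines <- character()
  if (leading_comment) lines <- "# Constructed from biom file"
  hdr <- paste(c("#OTU ID", sample_ids, if (!is.null(taxonomy)) "taxonomy"),
               collapse = "\t")
  rows <- vapply(seq_along(otu_ids), function(i)
    paste(c(otu_ids[i], counts[i, ], if (!is.null(taxonomy)) taxonomy[i]),
          collapse = "\t"), character(1))
  writeLines(c(lines, hdr, rows), path)
  path
}

write_mapping_fixture <- function(path, sample_ids, ...) {
  cols <- list(...)
  hdr <- paste(c("#SampleID", names(cols)), collapse = "\t")
  rows <- vapply(seq_along(sample_ids), function(i)
    paste(c(sample_ids[i],
            vapply(cols, function(v) as.character(v[i]), character(1))),
          collapse = "\t"), character(1))
  writeLines(c(hdr, rows), path)
  path
}
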