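# Reading OTU tables and metadata, log2 transform, sample alignment.

test_that("classic OTU table reads back the values it was written with", {
  counts <- matrix(c(5, 0, 12, 3, 7, 1), nrow = 3, byrow = TRUE)
  f <- write_classic_fixture(tempfile(fileext = ".tsv"), counts,
                             otu_ids = c("4306262", "4350498", "1000001"),
                             sample_ids = c("sampleA", "sampleB"))
  m <- read_otu_table(f)
  expect_s3_class(m, "otu_counts")
  expect_equal(dim(m), c(2L, 3L))                    # samples x OTUs
  expect_equal(rownames(m), c("sampleA", "sampleB"))
  expect_equal(colnames(m), c("4306262", "4350498", "1000001"))
  expect_equal(unname(m["sampleA", "4306262"]), 5)
  expect_equal(unname(m["sampleB", "4350498"]), 3)

  # write -> read round trip is value-identical
  f2 <- write_otu_table(m, tempfile(fileext = ".tsv"))
  m2 <- read_otu_table(f2)
  expect_equal(unclass(m2)[, ], unclass(m)[, ])
})

test_that("taxonomy column is stored as an attribute and kept out of counts", {
  counts <- matrix(c(1, 2, 3, 4), nrow = 2, byrow = TRUE)
  f <- write_classic_fixture(tempfile(), counts, c("o1", "o2"), c("s1", "s2"),
                             taxonomy = c("k__Bacteria; p__A", "k__Bacteria; p__B"))
  m <- read_otu_table(f)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(attr(m, "taxonomy")["o2"]), "k__Bacteria; p__B")
})

test_that("malformed tables are rejected with informative errors", {
  bad <- tempfile()
  writeLines(c("OTU ID\ts1\ts2", "o1\t1\t2"), bad)
  expect_error(read_otu_table(bad), "#OTU ID")

  dup <- write_classic_fixture(tempfile(), matrix(1:4, 2), c("o1", "o1"),
                               c("s1", "s2"))
  expect_error(read_otu_table(dup), "duplicate OTU id")

  neg <- write_classic_fixture(tempfile(), matrix(c(1, -2, 3, 4), 2),
                               c("o1", "o2"), c("s1", "s2"))
  expect_error(read_otu_table(neg), "negative")

  expect_error(read_otu_table(tempfile()), "not found")
})

test_that("BIOM and classic reads of the same table agree", {
  skip_if_not_installed("biomformat")
  counts <- matrix(c(5, 0, 12, 3, 7, 1), nrow = 3,
                   dimnames = list(c("o1", "o2", "o3"), c("s1", "s2")))
  f_classic <- write_classic_fixture(tempfile(fileext = ".tsv"),
                                     counts, rownames(counts), colnames(counts))
  f_biom <- tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(counts), f_biom)
  m_classic <- read_otu_table(f_classic, "classic_tsv")
  m_biom <- read_otu_table(f_biom)                 # auto-detected
  expect_equal(unclass(m_biom)[, ], unclass(m_classic)[, ])
})

test_that("metadata mapping files read back verbatim with NA for empty cells", {
  f <- write_mapping_fixture(tempfile(), paste0("s", 1:4),
                             env_biome = c("soil", "feces", "", "ocean"),
                             host = c("none", "human", "human", "none"))
  meta <- read_metadata(f)
  expect_s3_class(meta, "sample_metadata")
  expect_equal(rownames(meta), paste0("s", 1:4))
  expect_equal(meta[c("s1", "s2", "s4"), "env_biome"],
               c("soil", "feces", "ocean"))
  expect_true(is.na(meta["s3", "env_biome"]))      # empty cell, not ""

  dup <- write_mapping_fixture(tempfile(), c("s1", "s1"), f = c("a", "b"))
  expect_error(read_metadata(dup), "duplicate sample id")

  notmap <- tempfile()
  writeLines(c("SampleID\tf", "s1\ta"), notmap)
  expect_error(read_metadata(notmap), "#SampleID")
})

test_that("log2 transform follows log2(scaled + pseudocount)", {
  m <- count_matrix(matrix(c(0, 7, 2, 2), nrow = 2, byrow = TRUE,
                           dimnames = list(c("s1", "s2"), c("o1", "o2"))))
  a <- transform_log2(m)
  expect_equal(unname(a["s1", "o1"]), 0)           # log2(0 + 1)
  expect_equal(unname(a["s1", "o2"]), 3)           # log2(7 + 1)

  # total-sum scaling: sample (2, 2) at depth 8 -> scaled counts (4, 4)
  a2 <- transform_log2(m[2, , drop = FALSE], scaling = "total_sum", depth = 8)
  expect_equal(unname(a2["s2", ]), rep(log2(5), 2))

  zero_tot <- count_matrix(matrix(c(0, 0, 1, 2), 2, byrow = TRUE,
                                  dimnames = list(c("s1", "s2"), c("o1", "o2"))))
  expect_error(transform_log2(zero_tot, scaling = "total_sum"),
               "zero total")
  expect_error(transform_log2(m, pseudocount = 0), "pseudocount")
})

test_that("log2 transform is monotone per cell and sample-order independent", {
  set.seed(42)
  counts <- matrix(rpois(60, 20), 6, 10,
                   dimnames = list(paste0("s", 1:6), paste0("o", 1:10)))
  a <- transform_log2(count_matrix(counts))
  expect_true(all((counts[, 1] < counts[, 2]) == (a[, 1] < a[, 2]) |
                    counts[, 1] == counts[, 2]))
  perm <- sample(6)
  a_perm <- transform_log2(count_matrix(counts[perm, ]))
  expect_equal(unclass(a_perm)[, ], unclass(a)[perm, ])
})

test_that("align_samples restricts both objects to the common samples", {
  m <- transform_log2(count_matrix(matrix(1:6, 3, 2,
         dimnames = list(c("s1", "s2", "s3"), c("o1", "o2")))))
  meta <- structure(data.frame(f = c("a", "b", "c"),
                               row.names = c("s2", "s3", "s4")),
                    class = c("sample_metadata", "data.frame"))
  expect_message(al <- align_samples(m, meta), "dropped 1 matrix")
  expect_equal(rownames(al$abundance), c("s2", "s3"))
  expect_equal(rownames(al$metadata), c("s2", "s3"))
  expect_s3_class(al$abundance, "otu_abundance")   # attributes survive subsetting
  expect_equal(attr(al$abundance, "pseudocount"), 1)

  meta_same <- structure(data.frame(f = c("a", "b", "c"),
                                    row.names = c("s3", "s1", "s2")),
                         class = c("sample_metadata", "data.frame"))
  al2 <- align_samples(m, meta_same)
  expect_equal(rownames(al2$abundance), rownames(al2$metadata))
  expect_equal(sort(rownames(al2$abundance)), c("s1", "s2", "s3"))

  disjoint <- structure(data.frame(f = "a", row.names = "sX"),
                        class = c("sample_metadata", "data.frame"))
  expect_error(align_samples(m, disjoint), "no samples in common")
})
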