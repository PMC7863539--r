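# All-pairs scan, permutation FDR, invariants, correlation, metadata
# differential.

# small discrete matrix with one planted equivalent pair and noise microbes
toy_discrete <- function(n = 200, seed = 1) {
  set.seed(seed)
  base <- sample(c(0L, 2L), n, replace = TRUE)
  cbind(A = base, B = base,
        C = sample(c(0L, 2L), n, replace = TRUE),
        D = sample(c(0L, 2L), n, replace = TRUE))
}

test_that("scan_pairs finds planted structure and agrees with classify_pair", {
  d <- toy_discrete()
  rt <- scan_pairs(d)
  expect_s3_class(rt, "relation_table")
  expect_equal(attr(rt, "n_pairs_tested"), 6L)
  expect_true(any(rt$otu_a == "A" & rt$otu_b == "B" & rt$kind == "equivalent"))

  # every record matches the scalar classifier after canonicalization
  for (i in seq_len(nrow(rt))) {
    q <- quadrant_counts(d[, rt$otu_a[i]], d[, rt$otu_b[i]])
    rel <- classify_pair(q)
    expect_equal(rel$kind, rt$kind[i])
    expect_equal(c(q$a00, q$a01, q$a10, q$a11),
                 unlist(rt[i, c("a00", "a01", "a10", "a11")],
                        use.names = FALSE))
  }
})

test_that("scan_pairs is invariant to microbe and sample order", {
  d <- toy_discrete(seed = 5)
  rt <- scan_pairs(d)
  rt_cols <- scan_pairs(d[, c(3, 1, 4, 2)])
  rt_rows <- scan_pairs(d[sample(nrow(d)), ])
  for (other in list(rt_cols, rt_rows)) {
    expect_equal(as.data.frame(other), as.data.frame(rt))
  }
})

test_that("independent noise yields no relationships at default parameters", {
  set.seed(33)
  d <- matrix(sample(c(0L, 2L), 500 * 20, replace = TRUE), 500, 20,
              dimnames = list(NULL, sprintf("m%02d", 1:20)))
  expect_equal(nrow(scan_pairs(d)), 0L)
})

test_that("scan warns and returns an empty table when too few microbes survive", {
  d <- matrix(1L, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_warning(rt <- scan_pairs(d), "fewer than 2")
  expect_equal(nrow(rt), 0L)
  expect_equal(attr(rt, "n_pairs_tested"), 0L)
})

test_that("permutation FDR is reproducible, low on structure, undefined on noise", {
  ds <- generate_dataset(500, 30, lapply(1:10, function(i)
    pair_spec(c("equivalent", "high_low", "low_low", "high_high")[(i %% 4) + 1])),
    seed = 21)
  am <- transform_log2(ds$counts)
  f1 <- permutation_fdr(am, n_perm = 10, seed = 9)
  f2 <- permutation_fdr(am, n_perm = 10, seed = 9)
  expect_equal(f1$per_permutation_counts, f2$per_permutation_counts)
  expect_gte(f1$n_original, 10)
  expect_lt(f1$fdr, 0.1)

  # destroying all structure leaves nothing to discover: FDR undefined
  set.seed(4)
  am_perm <- apply(unclass(am), 2, sample)
  rownames(am_perm) <- rownames(am)
  f0 <- suppressWarnings(permutation_fdr(am_perm, n_perm = 3, seed = 2))
  expect_equal(f0$n_original, 0L)
  expect_true(is.na(f0$fdr))

  expect_error(permutation_fdr(am, n_perm = 0), "n_perm")
})

test_that("permuting a microbe's values leaves its StepMiner threshold unchanged", {
  ds <- generate_dataset(200, 8, list(pair_spec("equivalent")), seed = 14)
  am <- transform_log2(ds$counts)
  tm <- threshold_matrix(am)
  set.seed(1)
  am_perm <- apply(unclass(am), 2, sample)
  expect_equal(threshold_matrix(am_perm)$thresholds, tm$thresholds)
})

# relation tables with chosen records/testable sets for invariant logic
fake_table <- function(id, records, microbes) {
  recs <- relation_records(length(records))
  tab <- do.call(rbind, lapply(records, function(r)
    data.frame(otu_a = r[1], otu_b = r[2], kind = r[3],
               stringsAsFactors = FALSE)))
  if (!is.null(tab)) {
    recs <- relation_records(nrow(tab))
    recs[, c("otu_a", "otu_b", "kind")] <- tab
    recs$s00 <- recs$s01 <- recs$s10 <- recs$s11 <- 5
  }
  new_relation_table(recs, id, as.integer(choose(length(microbes), 2)),
                     microbes, character(), significance_params())
}
relation_records <- boolimp:::relation_records
new_relation_table <- boolimp:::new_relation_table

test_that("invariants require identical kind in all datasets, untestable pairs set aside", {
  tabs <- list(
    fake_table("d1", list(c("A", "B", "equivalent"), c("C", "D", "low_low"),
                          c("E", "F", "high_low")), LETTERS[1:6]),
    fake_table("d2", list(c("A", "B", "equivalent"), c("C", "D", "low_low"),
                          c("E", "F", "high_low")), LETTERS[1:6]),
    fake_table("d3", list(c("A", "B", "equivalent"), c("C", "D", "high_high"),
                          c("E", "F", "high_low")), LETTERS[1:6]),
    fake_table("d4", list(c("A", "B", "equivalent")), LETTERS[1:4]))  # E,F untestable
  inv <- find_invariants(tabs)
  # A-B identical in 4/4 -> invariant; C-D conflicting kinds -> out;
  # E-F untestable in d4 -> untestable tally, not invariant
  expect_equal(inv$invariants$otu_a, "A")
  expect_equal(inv$invariants$kind, "equivalent")
  expect_equal(inv$untestable$otu_a, "E")
  expect_equal(inv$untestable$n_testable, 3L)

  # order-independence of the input list
  inv2 <- find_invariants(tabs[c(3, 1, 4, 2)])
  expect_equal(inv2$invariants, inv$invariants)

  expect_error(find_invariants(tabs[c(1, 1)]), "duplicate dataset_id")
  expect_error(find_invariants(tabs[1]), "at least 2")
})

test_that("a pair significant everywhere but kind none in one dataset is not invariant", {
  tabs <- list(
    fake_table("d1", list(c("A", "B", "low_low")), c("A", "B")),
    fake_table("d2", list(c("A", "B", "low_low")), c("A", "B")),
    fake_table("d3", list(), c("A", "B")))        # testable, nothing found
  inv <- find_invariants(tabs)
  expect_equal(nrow(inv$invariants), 0L)
  expect_equal(nrow(inv$untestable), 0L)
})

test_that("correlation summary separates symmetric from asymmetric kinds", {
  ds <- generate_dataset(400, 12,
                         list(pair_spec("equivalent"), pair_spec("equivalent"),
                              pair_spec("high_low"), pair_spec("low_low")),
                         seed = 30)
  fit <- bia(ds$counts)
  cs <- correlate_by_relation(fit$abundance, fit$relations, seed = 2)
  expect_true(all(cs$pairs$r >= -1 & cs$pairs$r <= 1))
  med <- tapply(cs$pairs$r, cs$pairs$kind, median)
  expect_gt(med[["equivalent"]], med[["high_low"]])

  # identical columns correlate perfectly and classify as equivalent
  am <- fit$abundance
  dup <- cbind(unclass(am), DUP = am[, "OTU_0001"])
  tm <- threshold_matrix(dup)
  rt <- scan_pairs(tm$discrete)
  i <- which(rt$otu_a == "DUP" | rt$otu_b == "DUP")
  expect_true(any(rt$kind[i] == "equivalent" &
                    (rt$otu_a[i] == "OTU_0001" | rt$otu_b[i] == "OTU_0001")))
  cs2 <- correlate_by_relation(dup, rt)
  expect_equal(max(cs2$pairs$r), 1, tolerance = 1e-12)
})

test_that("subsampling for correlation is seeded and bounded", {
  ds <- generate_dataset(200, 10, list(pair_spec("equivalent")), seed = 8)
  fit <- bia(ds$counts)
  c1 <- correlate_by_relation(fit$abundance, fit$relations,
                              subset_size = 4, seed = 5)
  c2 <- correlate_by_relation(fit$abundance, fit$relations,
                              subset_size = 4, seed = 5)
  expect_equal(c1$subset, c2$subset)
  expect_length(c1$subset, 4)
})

test_that("metadata differential matches the Welch formulas", {
  am <- structure(
    matrix(c(1, 1.1, 0.9, 1, 5, 5.1, 4.9, 5,
             3, 4, 2, 3, 3.5, 2.5, 3, 3,
             2, 2, 2, 2, 2, 2, 2, 2), ncol = 3,
           dimnames = list(paste0("s", 1:8), c("shift", "null", "flat"))),
    class = c("otu_abundance", "matrix", "array"))
  meta <- structure(data.frame(grp = rep(c("a", "b"), each = 4),
                               row.names = paste0("s", 1:8)),
                    class = c("sample_metadata", "data.frame"))
  dt <- differential_metadata(am, meta, "grp", "a", "b")
  shift <- dt[dt$otu_id == "shift", ]
  expect_equal(shift$mean_diff, -4)

  # textbook Welch statistic for the shifted OTU, recomputed by hand
  xa <- am[1:4, "shift"]; xb <- am[5:8, "shift"]
  t_ref <- (mean(xa) - mean(xb)) /
    sqrt(var(xa) / length(xa) + var(xb) / length(xb))
  expect_equal(shift$t, t_ref, tolerance = 1e-12)
  expect_lt(shift$p, 1e-6)
  expect_equal(shift$neg_log10_p, -log10(shift$p))

  null <- dt[dt$otu_id == "null", ]
  expect_lt(abs(null$mean_diff), 1)
  expect_gt(null$p, 0.3)

  # ranking: most significant first; undefined tests (zero variance in
  # both groups, equal means) carry NA and sort last
  expect_equal(dt$otu_id[1], "shift")
  flat <- dt[dt$otu_id == "flat", ]
  expect_true(is.na(flat$t) && is.na(flat$p))
  expect_equal(dt$otu_id[nrow(dt)], "flat")

  expect_error(differential_metadata(am, meta, "missing", "a", "b"),
               "not found")
  meta_small <- structure(data.frame(grp = c("a", rep("b", 7)),
                                     row.names = paste0("s", 1:8)),
                          class = c("sample_metadata", "data.frame"))
  expect_error(differential_metadata(am, meta_small, "grp", "a", "b"),
               ">= 2 samples")
})

test_that("relation tables survive a TSV round trip with their attributes", {
  d <- toy_discrete(seed = 77)
  rt <- scan_pairs(d, dataset_id = "roundtrip")
  f <- write_relation_table(rt, tempfile(fileext = ".tsv"))
  rt2 <- read_relation_table(f)
  expect_equal(attr(rt2, "dataset_id"), "roundtrip")
  expect_equal(attr(rt2, "n_pairs_tested"), attr(rt, "n_pairs_tested"))
  expect_equal(attr(rt2, "microbes_tested"), attr(rt, "microbes_tested"))
  expect_equal(rt2$kind, rt$kind)
  expect_equal(rt2$s00, rt$s00, tolerance = 1e-6)
  # restored tables feed find_invariants
  inv <- find_invariants(list(rt, structure(rt2, dataset_id = "rt2")))
  expect_equal(nrow(inv$invariants), nrow(rt))
})
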