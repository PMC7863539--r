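# Independent brute-force transcription of the sparse-quadrant test and the
# quadrant -> relationship mapping, written from the printed formulas and
# kept free of any package internals. Used as the oracle that the fast
# implementation must match on every small table.

oracle_quadrant_passes <- function(a00, a01, a10, a11, quad,
                                   s_min = 3, err_max = 0.1) {
  total <- a00 + a01 + a10 + a11
  if (quad == "q00") { obs <- a00; ma <- a00 + a01; mb <- a00 + a10 }
  if (quad == "q01") { obs <- a01; ma <- a00 + a01; mb <- a01 + a11 }
  if (quad == "q10") { obs <- a10; ma <- a10 + a11; mb <- a00 + a10 }
  if (quad == "q11") { obs <- a11; ma <- a10 + a11; mb <- a01 + a11 }
  expected <- (ma / total) * (mb / total) * total
  if (ma == 0 || mb == 0 || expected == 0) return(FALSE)
  s_stat <- (expected - obs) / sqrt(expected)
  err <- 0.5 * (obs / ma + obs / mb)
  s_stat > s_min && err < err_max
}

oracle_classify <- function(a00, a01, a10, a11, s_min = 3, err_max = 0.1) {
  p <- vapply(c("q00", "q01", "q10", "q11"), function(q)
    oracle_quadrant_passes(a00, a01, a10, a11, q, s_min, err_max),
    logical(1))
  if (sum(p) == 1) {
    # one sparse quadrant: the state pair it represents is forbidden, so
    # the A state of that quadrant implies the opposite B state
    switch(names(p)[p],
           q00 = "low_high", q01 = "low_low",
           q10 = "high_high", q11 = "high_low")
  } else if (sum(p) == 2 && p[["q01"]] && p[["q10"]]) {
    "equivalent"
  } else if (sum(p) == 2 && p[["q00"]] && p[["q11"]]) {
    "opposite"
  } else {
    "none"
  }
}
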