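---
title: "Boolean implication analysis of OTU tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean implication analysis of OTU tables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolimp)
```

## The problem and the model

Microbial co-occurrence is usually screened with Pearson correlation,
which is symmetric and favors linear association. Many real
relationships are one-directional rules — "where microbe A is abundant,
microbe B is nearly absent" — that leave a weak correlation signature
but a striking geometric one: an almost empty quadrant in the scatter
plot of the two microbes' log2 abundances. Boolean implication analysis
makes that geometry the test statistic.

The procedure, as `bia()` runs it per dataset:

1. **Log2 transform.** Counts become `log2(count + pseudocount)`
   (default pseudocount 1, so zeros stay at 0). An optional total-sum
   scaling rescales each sample to a common depth first; the default is
   no scaling, appropriate for tables that arrive pre-normalized. The
   choice is recorded on the returned matrix.
2. **StepMiner threshold.** For each microbe the sorted values get a
   one-step fit: every split k defines left/right means m1, m2 and
   `SSE(k) = sum_left (x - m1)^2 + sum_right (x - m2)^2`; the minimizing
   k is chosen and the threshold is `t = (m1 + m2)/2`, the level where
   the fitted step crosses between its two plateaus. On sorted data only
   a step-up fit is meaningful, so no step-down variant is needed.
3. **Discretization.** States are high (`x > t + margin`), low
   (`x < t - margin`) and intermediate otherwise, with `margin = 0.5`
   log2 units by default. Intermediate samples are ignored downstream:
   noise of roughly half a log2 unit could place them on either side.
4. **Sparse-quadrant tests.** For each pair, the non-intermediate
   samples fill a 2x2 table (a00, a01, a10, a11). Each quadrant is
   compared with its expectation under independence of the marginals,
   `expected = row_marginal x col_marginal / total`, via
   `S = (expected - observed)/sqrt(expected)` and the error rate
   `0.5 (observed/row_marginal + observed/col_marginal)`, a maximum
   likelihood estimate of the rate at which the implication is
   violated. A quadrant is sparse when `S > 3` and `error rate < 0.1`.
5. **Classification.** One sparse quadrant yields the corresponding
   asymmetric implication (sparse (A low, B low) means A low implies
   B high, and so on); sparse q01 *and* q10 yield `equivalent`; sparse
   q00 *and* q11 yield `opposite`; anything else — zero passes or an
   over-determined combination of three or four sparse quadrants, which
   violates the implication model — is `none`, with all four tests kept
   for audit.

Each asymmetric implication has a logically identical contrapositive
with the microbes exchanged (A high → B low is B high → A low), so
records are canonicalized to lexicographic pair order, exchanging
`low_low` with `high_high` under a swap and leaving the other kinds
fixed. The all-pairs scan computes every pair's quadrant table with four
cross-products of the low/high indicator matrices; memory is
O(samples x microbes) for the states plus O(microbes^2) for the
quadrant-count blocks, which at desk scale (a few thousand microbes) is
far below the quadratic pair-record worst case.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `pseudocount` | 1 | counts | offset before log2; keeps zeros at 0 |
| `scaling` | `"none"` | — | optional total-sum depth normalization |
| `margin` | 0.5 | log2 units | noise half-width; boundary values count as intermediate |
| `s_min` | 3 | sd of a Poisson-like count | sparsity significance bound |
| `err_max` | 0.1 | fraction | max tolerated implication violations |
| `min_side_fraction`, `min_side_count` | 0.05, 3 | fraction, samples | dynamic-range filter |
| `n_perm` | 10 | rounds | permutation FDR |
| `subset_size` | 500 | microbes | correlation-summary subsample |

The **dynamic-range filter** requires every microbe entering pair
testing to have at least `max(min_side_count, min_side_fraction * n)`
samples on each side of its threshold. Without it a near-constant
microbe — whose "high" side is a handful of samples — produces
spuriously sparse quadrants against almost anything. The filter is a
deliberate guard rather than part of the core statistic, so both knobs
can be set to 0 for a literal all-pairs reading. Whether the non-sparse
quadrants should additionally be required to be well populated is left
to these knobs rather than assumed.

## FDR, invariants, correlation, metadata

**Permutation FDR.** Each microbe's values are shuffled across samples
independently, relationships are recounted with identical parameters,
and the FDR is the mean permuted relationship count over the original
count (undefined when the original count is 0, reported as `NA`). The
step fit depends only on the multiset of values, so thresholds are
provably unchanged by permutation; the implementation therefore permutes
the discretized state columns directly, which is identical to permuting
the raw values and re-discretizing, and skips the refit. A single
integer seed drives all shuffles in fixed microbe order, making runs
reproducible.

**Invariants.** Across several datasets, a pair is a candidate
invariant when it is *testable* (both microbes pass the range filter) in
every dataset and carries the identical kind in every dataset. A strict
reading is used: a pair with a relationship in some datasets and `none`
in another is not an invariant; a pair untestable in any dataset is set
aside in a separate tally rather than counted as inconsistent, since
absence of a microbe is not evidence against the rule.

**Correlation comparison.** For each related pair (subsampled to
`subset_size` microbes for large tables), the Pearson correlation of the
two microbes' log2 values is computed over *all* samples — intermediates
are excluded from the Boolean tests, but correlation is a property of
the full scatter, which is also the scale on which the scatter plots are
drawn. Symmetric `equivalent` pairs concentrate near r = 1 while
asymmetric pairs spread toward weak correlation, which is the motivating
contrast with correlation-based screening.

**Metadata differential.** Welch's unequal-variance t-test per OTU
between two metadata groups (configurable to Student's pooled test),
reporting mean difference in log2 units, t, p and -log10(p). Because
"high mean difference and high -log10(p)" is ultimately a selection on
two axes, the table is ranked by descending -log10(p) with ties broken
by |mean difference| — a documented stand-in for what is otherwise a
visual volcano-plot choice. OTUs with zero variance in both groups and
equal means have no defined t-test; they carry `NA` and sort last.

## The synthetic-data generator

`generate_dataset()` stands in for pooled real studies in every test.
Each planted pair draws a quadrant per sample (default: the leak mass
`leak_rate = 0.02` in the sparse quadrant(s), the rest uniform over the
dense quadrants) and then log2 values around a low or high mode
(defaults 2 and 6, i.e. 4 log2 units of separation, `noise_sd = 0.5`).
Those defaults are the study conditions for all recovery and FDR
checks: separation is 4x the combined noise-plus-margin width, the kind
of clean bimodality a strong real implication shows, and the 2% leak
exercises the error-rate bound rather than only S. Values are
back-transformed to integer counts (`max(round(2^v - pseudocount), 0)`),
so fixtures pass through the real I/O and transform path, including the
coarse integer grid near zero. Decoy microbes are unimodal log-normal
draws, shuffled copies of planted columns (bimodal but structure-free),
or an even mixture (default).

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data — includes 16S compositionality (closure
effects from sequencing depth), correlations among more than two taxa,
depth-dependent zero inflation, and batch structure across studies. The
generator's role is to verify the detector, not to simulate a
microbiome.

`generate_multidataset()` repeats one planted truth across k datasets
with independent noise and sample counts jittered ±20%, the setting for
invariant-recovery checks.

## Numerical choices and degenerate inputs

- Ties among equal-SSE splits go to the smallest k (determinism); the
  SSE is computed via the `sum(x^2) - k m1^2 - (n-k) m2^2` identity and
  clamped at 0 against floating-point cancellation.
- A step fit needs at least 4 non-missing values (one per side plus room
  for a step); constant microbes are flagged degenerate, discretize to
  all-intermediate, and drop out at the range filter.
- Values exactly on `t ± margin` are intermediate (strict inequalities):
  boundary points are exactly the noise-adjacent ones being excluded.
- Quadrant tests with a zero marginal or zero expectation report `NA`
  statistics and fail closed (`passes = FALSE`) instead of erroring, so
  an all-pairs scan never aborts mid-stream; the all-intermediate pair
  table is the one hard error, and only for direct single-pair calls.
- Missing abundances are treated as intermediate at discretization,
  i.e. excluded from pair testing rather than imputed.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on generated
data: recovery rates use 100 replicates of 500-sample two-microbe
tables per relationship kind; the FDR checks use 500 samples x 30–40
microbes with ten planted pairs and 10 permutation rounds; invariant
checks use four jittered datasets of ~400–500 samples. These sizes give
per-quadrant expectations in the tens-to-hundreds, the regime the
statistic is meant for, while keeping a full run to a few minutes.

## Known limitations

- The S statistic is a normal approximation to a hypergeometric tail;
  for very small tables (expectations near 1) it is conservative and
  the 0..6-cell enumeration in the tests documents its exact behavior
  rather than a p-value guarantee.
- Relationship kinds are reported per pair; building and clustering the
  implication *network* over pairs is out of scope.
- `equivalent`/`opposite` require both constituent quadrants to pass
  individually; borderline symmetric pairs may be reported as one
  asymmetric arm.
- Cross-dataset invariance is a same-kind-everywhere criterion; it does
  not model heterogeneous effect sizes or partial support.
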