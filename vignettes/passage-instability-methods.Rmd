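---
title: "Methods: passage instability and passage-robust gene calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: passage instability and passage-robust gene calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metastab)
```

## The problem and the study design

Serially passaged cell lines accumulate expression and copy-number
changes. In a parental/metastatic cell-line system this drift
confounds the search for metastasis-relevant genes: a metastatic vs
parental contrast mixes the selection signal with whatever each line
drifted into by the passage at which it happened to be profiled.

`metastab` assumes the design this package is built around: two (or
more) cell-line systems, each a parental line and a metastatic
derivative, each profiled at an *early* and a *late* passage with
replicate cultures (three per condition by default), on a gene-level
log2 expression platform, optionally with copy-number segment calls
per condition.

## Differential expression

`contrast()` computes, per gene, the log2 fold change (group B minus
group A means) and a two-sided ordinary pooled-variance two-sample
Student *t* test; `bh_fdr()` adds Benjamini–Hochberg step-up q values.
A deliberate design choice is the *ordinary* t statistic rather than
an empirical-Bayes moderated t: the moderated statistic depends on a
variance prior fitted to a whole array, which makes counts of
regulated genes platform- and dataset-specific. With triplicates the
ordinary t is noisier per gene but exactly calibrated (on null
simulations the p < 0.05 rate is 5% to binomial accuracy — this is a
test in the suite), and every downstream statistic only consumes the
resulting regulated sets. Consequences: regulated-gene *counts* from
moderated-t analyses are not directly comparable; the package's
validation therefore rests on in-package arithmetic and on synthetic
recovery rather than on re-deriving any particular count.

Numerical conventions:

* Thresholds are strict: "fold > 2" excludes a gene at exactly 2-fold,
  "p < 0.05" excludes p = 0.05 (`regulated_set()`).
* The fold threshold is applied to the anti-logged mean log2
  difference (the standard reading for log-scale arrays), not to the
  ratio of linear means.
* Zero-variance genes: equal means give p = 1 and fold 0 (conservative
  and total); unequal means with zero variance give p = 0, the limit
  of the statistic.
* Group A is always the reference: "late vs early" and "metastatic vs
  parental" mean second-named-minus-first in log2 units.

`doublings_from_passages()` converts passage counts to population
doublings via log2 of the split ratio (1:20 → 4.32, 1:200 → 7.64
doublings per passage), and `genes_per_doubling()` normalises
regulated-gene counts so lines cultured under different split ratios
are comparable.

## Overlap enrichment

For two regulated sets of sizes `n_a`, `n_b` in a shared universe of
`N` genes, the expectation under independent selection is the product
of the marginal fractions; `common_regulated()` reports
observed/expected fold enrichment. Independence is the only
expectation model implemented: it is the natural null ("the two lines
drift in unrelated genes") and requires no positional input.

Two rounding conventions are emitted because published versions of
such tables are typically computed from pre-rounded percentages. The
*raw* fold is `n_common * N / (n_a * n_b)`. The *printed-style* fold
rounds the marginal percents to 2 decimals, their product to 2
significant digits, the observed percent to 2 decimals, and the
quotient to 1 decimal. The two can differ in the last digit (e.g.
14.4 raw vs 14.5 printed-style); both are reported and neither is
privileged. Degenerate cases: an expected of 0 with observed 0 yields
fold 1 (0/0 convention), with observed > 0 yields `Inf` rather than an
error.

## Positional clustering

`ease_p()` implements the EASE score: the one-sided Fisher exact test
(upper hypergeometric tail) on the 2×2 membership table after
replacing the in-list hit count k by k − 1 (k = 0 gives p = 1). The
decrement is the published DAVID definition; it penalises units
supported by a single gene and makes the score conservative, so
`ease_p ≥ fisher_p` always (asserted property). The unmodified Fisher
p is returned alongside, and it — not the EASE score — is what tracks
the nominal level on null simulations; calibration tests use it.

`cluster_scan()` tests every chromosome or cytoband, separately for
up- and down-regulated lists, against the user-supplied annotation as
background. The background choice matters: a web-service analysis
would use its own internal gene universe; here the universe is
explicitly the supplied genome map, which keeps the statistic
self-contained and reproducible. Raw p values are reported with no
multiple-testing correction across units, because the conventional
presentation of such scans is a raw-p threshold (default alpha 0.01).
At chromosome level a *reporting* filter suppresses chromosomes whose
combined up + down regulated count is ≤ 20 (`min_total`); this is a
display rule, not part of the test, and is exposed as a parameter.

## Copy-number analysis

Segments carry a state in {gain, loss, LOH}, probe support, and a
"known recurrent aberration" flag. `filter_segments()` drops gain/loss
segments failing *either* the 100 kb size or the 50-probe support rule
(disjunctive reading of "smaller than 100 Kb or 50 adjacent probes"),
drops LOH below 3 Mb, drops segments overlapping a supplied CNV
exclusion list, and always retains recurrent-flagged segments. The
filter is idempotent and order-independent (tested properties).

`macro_aberrations()` calls a (cytoband, state) pair exactly when the
union of that state's segments covers the band's full interval —
adjacent segments jointly covering a band count, 99% coverage does
not, and the call is invariant under splitting segments into
contiguous pieces (tested). `gene_cn_status()` assigns each gene the
state of the class covering the majority (> 50%) of its span, neutral
otherwise; LOH is tracked as a separate flag and never overrides
gain/loss. Majority-overlap is deterministic at boundaries; the exact
50/50 tie goes to neutral. `cn_delta()` classifies per-gene change on
the ordinal scale loss < neutral < gain, which is all that state
calls support (integer copy numbers are deliberately not modelled).
Aberrant fractions and deltas are reported as percentages of the
*gene* universe, not of base pairs.

Coordinates are 0-based half-open internally everywhere. On disk, SEG
files are 1-based inclusive (converted at parse/write time,
round-tripping bit-exactly), while UCSC cytoBand and BED-like files
are already 0-based half-open and pass through unchanged.

## CN/expression coincidence

`coincidence()` counts regulated genes in same-direction CN-change
regions and compares with `n_regulated * K / N`, the expectation if
the regulated labels were placed uniformly at random on the gene
universe. That uniform-resampling formalisation matches the marginal
product exactly, and `coincidence_permutation_p()` uses the same
resampling as its null, so the analytic expectation equals the
permutation mean by construction (verified at 3 Monte-Carlo standard
errors in tests). Genome-wide expectation is the default; positional
block-resampling, which would preserve local gene density, is a noted
alternative but not implemented. Hotspot bands require at least 2
coincident genes and a band ratio of at least 2 — below that, a
"hotspot" would rest on a single gene.

## The consistency filter

`build_grid()` forms the four passage-combination contrasts ME/PE,
ML/PE, ME/PL, ML/PL plus the pooled 6v6 contrast.
`consistent_genes()` keeps genes passing the regulation criterion in
the same direction in at least `min_pass` (3 or 4) combinations, with
direction consistency enforced across *passing* combinations even at
min_pass 3: a gene may fail, but not reverse, in its non-passing
combination. The logic of the filter: a pure passage effect (present
in late samples of both lines) cancels in ME/PE and ML/PL but enters
ML/PE and ME/PL with opposite signs, so it cannot pass 3 combinations
in one direction. The suite verifies this rejection at ≥ 95%
frequency over 20 seeded repeats, alongside ≥ 90% recovery of genuine
metastatic effects.

The reported mean fold is the arithmetic mean of the four *signed
linear* fold changes (negative = down), matching how such tables are
conventionally printed; a log2-scale mean is available via
`fold_scale = "log2"`. All four folds enter the mean, including a
non-passing one at min_pass 3 — the alternative (averaging only
passing folds) would make the mean depend on the threshold.
`pathway_filter()` evaluates the survivors against GMT gene sets with
the EASE statistic (set size is taken at face value against the
supplied universe), and `cross_system_intersection()` reports exact
intersections across systems; gene-identifier harmonisation between
species is the caller's responsibility.

## The synthetic-data generator

`generate_expression()` draws per-gene baseline log2 intensities from
N(8, 2) and i.i.d. normal replicate noise (default sd 0.25 log2
units), then adds the requested effects additively in log2 space.
These are stand-in choices: log-intensity microarray data are roughly
normal on the log scale, but the generator makes no attempt to model
the mean–variance relationship, probe effects, normalisation
artefacts, correlated genes, or heavy tails of real arrays. Passing
recovery tests therefore demonstrate that the *procedures* behave as
specified under their nominal model — calibrated nulls, stated power,
correct bookkeeping — not that real-data counts would be reproduced.
`generate_cn_profiles()` plants gain/loss/LOH events (whole cytobands
or explicit intervals, including deliberately sub-threshold segments
to exercise the filters) and couples expression to copy number by
flipping a coin per gene in a gain/loss event (default couple
probability 0.8, shift ±1.5 log2 units, sign following the CN
direction). Every injected effect is recorded in a truth table, and
the count of truth entries is asserted to match the specification
exactly.

Scenario defaults in `simulate_study()` mirror the study conditions:
one parental/metastatic system, triplicates, early/late classes, 2
log2-unit injected effects (4-fold, comfortably above the 2-fold
threshold at sd 0.25), ~2% of the universe as metastatic-effect genes
and ~3.5% as passage-effect genes, one planted cytoband cluster, and
whole-band CN events in the late conditions. Scenario gene identities
sit at deterministic, evenly spaced universe indices so that bundled
gene-set fixtures remain valid under any seed; the seed drives
coordinates, noise and coupling.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations for
sharp checks at interactive runtimes: universes of 50–10,000 genes, 20
seeded repeats for power/rejection rates, 10,000 permutations where a
Monte-Carlo mean is compared with an analytic expectation, and 200–
1,000 permutations inside pipeline runs. All stochastic code paths
take explicit integer seeds and restore the caller's RNG state; a
pipeline rerun with the same config is byte-identical, which the suite
asserts.

## Known limitations

* No probe-level modelling: the package starts from gene-level log2
  matrices and segment calls; array preprocessing, probe-to-gene
  collapsing and segment calling are out of scope.
* The ordinary t differs from moderated-t analyses on the same data;
  see above.
* CN states are categorical; amplitudes and allele-specific events are
  not represented, and LOH never couples to expression in the
  generator.
* The coincidence expectation ignores positional autocorrelation of
  regulated genes; an elevated ratio should be read alongside the
  permutation p value, not alone.
* Only two-snapshot (early/late) designs are supported; longitudinal
  per-passage trajectories are not modelled.
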