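---
title: "Diagnosing differential-expression p-value sets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing differential-expression p-value sets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvalqc)
```

## The problem

A two-group differential-expression (DE) analysis tests tens of
thousands of features at once. If the test is calibrated, the p-values
of the truly null features are Uniform(0, 1), and the full set is a
mixture: a flat uniform floor of height pi0 (the fraction of true
nulls) plus a spike of small p-values from the true effects. Everything
downstream of the p-values — FDR control above all — assumes this
shape. In practice, published DE tables often violate it: discrete
tests on low-count features pile p-values at and near 1, produce atoms
at interior values, and push histograms into conservative, bimodal or
humped shapes that no FDR procedure is built for.

pvalqc implements the machinery to detect this at scale: it mines
p-value and expression columns out of heterogeneous processed tables,
classifies each p-value histogram, estimates pi0 for the well-formed
sets, and measures how much a simple low-expression filter repairs the
malformed ones.

## Histogram classification

A set of m p-values is binned into B = 40 equal-width bins (half-open
on the right; p = 1 belongs to the last bin). Under uniformity each bin
count is Binomial(m, 1/B), so a bin is called a *peak* when its count
strictly exceeds the Bonferroni-corrected binomial quantile

    c = min{ c : P(Binomial(m, 1/B) <= c) >= 1 - alpha/B },

with alpha = 0.05 by default. The familywise probability of any false
peak on a uniform set is then at most alpha. `qc_threshold()` computes
c with `qbinom()`; the test suite verifies it against a brute-force
summation of the binomial pmf over a grid of (m, B, alpha).

The class is a total function of the flagged bins:

* no peak: **uniform**;
* peaks forming one run anchored at the left edge, spanning at most a
  third of the unit range (13 bins of 40): **anti-conservative**;
* the mirror image at the right edge: **conservative**;
* boundary runs at both edges and nothing in between: **bimodal**;
* anything with an interior run, or a boundary run longer than a third
  of the range: **other**.

Decision order matters only for composite patterns, and we resolve it
as: interior runs always force *other*, even when boundary runs are
also present; bimodal has no run-length cap. "Over threshold" is
strict inequality. Sets smaller than B are reported *unclassifiable*
rather than guessed at. These choices (alpha, the strictness, the
1/3-range cap as `floor(B/3)`, the closed last bin) are exposed as
arguments, with the defaults above.

The geometry has a direct scientific consequence: with B = 40 the first
bin covers p < 0.025 and already holds m/40 null p-values — 500 of
20,000. A few hundred true effects drown in that floor, so an
experiment with around 100 true effects out of 20,000 features is
typically still classified uniform. The acceptance script recomputes
this detection limit by simulation: across effect counts
{25, 50, 100, 200, 400, 800} with z-test alternatives of effect size
delta = 2 (per-test power about 0.52 at the 0.025 edge), 100 is the
largest count whose sets are majority-uniform.

## Estimating the proportion of true nulls

Two estimators, deliberately different in mechanism, are applied to
uniform and anti-conservative sets only (for the other classes the
number has no meaning, since the mixture assumption is visibly broken):

**Rank-based local-FDR average** (`pi0_lfdr()`). With p-values sorted
in decreasing order and i_j = n + 1 - j the rank from the top, each
q_j = min(n p_(j) / i_j, 1) and pi0 = 2 sum(i_j q_j) / (n (n + 1)),
clamped to [0, 1]. The spec of this rule is frozen by a hand-worked
example in the tests ({0.01, 0.02, 0.5, 0.8, 1.0} gives 0.77666...),
and the implementation is additionally cross-checked against an
independent loop-order re-implementation and against
`limma::propTrueNull(method = "lfdr")`.

**Storey's smoother** (`pi0_storey()`). The raw estimates
pi0(lambda) = #{p > lambda} / (n (1 - lambda)) are computed on the grid
lambda = 0.05, 0.10, ..., 0.95, a natural cubic smoothing spline with
df = 3 is fitted through them, and the estimate is the spline value at
lambda = 0.95, clamped to [0, 1]. Ties at a grid point count as
"below" (strict inequality). The grid and df are arguments; the
defaults follow the standard smoother convention. Below 100 p-values
the smoother is refused rather than returned unstably; the rank-based
rule only needs two values.

Both estimators are permutation invariant and always land in [0, 1].
On z-test mixtures with delta = 3 and n = 20,000 both recover true
pi0 in {0.2, 0.5, 0.8, 0.95} with median absolute error at or below
0.05 (50 replicates each in the acceptance suite). Under low power the
small-p spike thins out and both methods overestimate pi0; the count
simulator reproduces the expected direction, with median estimates at
2 replicates per group clearly above those at 10.

## Table mining

Column roles are assigned deterministically from lower-cased names:
p-value columns match `p[^a-z]{0,4}val`; among the matches, those also
matching `adj|fdr|corr|thresh` are adjusted and excluded. Canonical
adjusted names that the p-value pattern cannot reach (`padj`,
`q_value`, `FDR`, `adj.P.Val`) are additionally recognised as adjusted
so that every column receives exactly one role. Expression columns
match `basemean`, `value`, `fpkm`, `logcpm`, `rpkm` or `aveexpr`, the
longest match winning when several apply; a column already claimed as a
(adjusted) p-value is never an expression column, which is what keeps
`p_value` out of the `value` metric.

Mined sets are validated before classification: any finite value
outside [0, 1], all-NaN vectors, truncated exports (max p below 0.9 —
the signature of a "significant genes only" table), and sets piled up
against 1 (last decile both the global maximum and larger than the
first decile by a one-sided binomial test at 1e-3) are disqualified.
The truncation and skew thresholds are arguments; note that the skew
rule is intentionally strict enough to also catch extreme conservative
sets, which is why the classifier itself never calls the validator.

The DE tool is inferred from free text when available (a single
regular expression over lower-cased text, covering deseq/deseq2,
cuffdiff/cufflinks, edger, limma/voom, sleuth, and a dozen others),
otherwise from column heuristics: FPKM-scale expression (including
cuffdiff's `value_1`/`value_2` columns) plus `p_value` means cuffdiff;
`basemean` plus `pval` or `pvalue` means DESeq or DESeq2; `logcpm`
means edgeR; `aveexpr` plus `p.value` plus a publication date after
2014-01-01 means limma. Text evidence outranks column heuristics, and
without a date the limma heuristic refuses to fire. Balanced per-group
sample sizes are n_samples / (n_pvalue_sets + 1) when the division is
exact, undefined otherwise.

## Low-count filtering and rescue

Features are removed when their expression falls below the
metric-specific threshold: basemean 10 (normalised mean counts),
logcpm 1, rpkm 1, fpkm 1, aveexpr 3.32 (log2 CPM units; 3.32 =
log2(10)); `value` columns are treated on the FPKM scale. When a table
carries several columns of the governing metric (one per contrast or
sample), the row mean is taken within that metric; when several metric
types coexist, the priority is basemean > logcpm > aveexpr > fpkm >
rpkm > value. Boundary values are kept (>= threshold); missing
expression drops the feature. Filtering is deterministic and monotone
in every threshold.

`rescue_set()` classifies and pi0-estimates a set before and after
filtering; `transition_summary()` tabulates the class transitions over
a corpus. On simulated experiments with 60% low-count features the
unfiltered sets are overwhelmingly bimodal/other/conservative and the
filtered sets overwhelmingly anti-conservative, while conservative
sets whose shape is unrelated to expression are almost never rescued —
subsampling cannot reshape a histogram.

## The synthetic-data generators

The generators are first-class, tested code; every downstream claim in
the test suite is anchored to their known ground truth.

`generate_pvalue_set()` draws round((1 - pi0) n) alternatives and the
rest Uniform(0, 1). The default alternative is the one-sided z-test
transform p = 1 - pnorm(z), z ~ Normal(delta, 1), chosen because its
per-test power at level a is the closed form pnorm(delta - qnorm(1 -
a)), which makes scenario calibration exact arithmetic rather than
guesswork; a Beta(a, b) alternative (a < 1 <= b) is available. The
shape of real DE alternatives is unknowable in general; this choice is
ours and is stated, not inferred.

`generate_malformed_set()` produces the four pathological shapes seen
in published tables: conservative (15% of values exactly 1 plus 10%
stacked in [0.9, 1] — the ties-at-one artifact of exact tests),
bimodal (mass in both outermost bins), hump (a Beta(20, 20) bump at
0.5), and spiky (atoms at 0.15, 0.35, 0.65). At 20,000 features each
lands in its nominal class essentially always.

`simulate_count_experiment()` works at the count level: negative
binomial counts (dispersion 0.1 by default, a typical bulk-RNA-seq
biological-replicate value), log2 mean expression Uniform(3, 12) for
ordinary features and Uniform(-2, 2.3) for low-count features (group
mean below ~5), median-of-ratios size factors with a total-count
fallback when fewer than 100 features have all-positive counts, DE
fold changes 2^(+-lfc) with the sign drawn per feature, and a
self-contained per-feature test: Welch's t on log2(normalised + 0.5)
for two or more replicates per group, and the exact two-sample Poisson
(conditional binomial) test for single pairs. Degenerate Welch cases
are resolved deterministically — both groups constant and equal gives
p = 1, constant but different gives p = 0 — which is precisely the
discrete-p pathology that makes unfiltered low-count sets bimodal or
conservative and lets the filter rescue them.

What the simulator does *not* emulate: read-level noise, alignment and
quantification error, correlated features, outlier samples, and the
idiosyncrasies of real DE engines. The Welch t on log-counts is only
approximately calibrated: at 20,000 features a pure-null simulation at
5 replicates per group is classified uniform in roughly 90–95% of
runs rather than the nominal 95%, with failures being single stray
interior bins. Passing tests therefore demonstrate that the pipeline's
logic is correct on data with known truth, not that any particular
real dataset is well behaved.

## Numerical choices and degenerate inputs

* p = 1.0 belongs to the last bin; bin edges are otherwise half-open.
* `qc_threshold` uses `qbinom` directly; the oracle tests sum the pmf.
* The exact pair test accumulates two-sided tail mass with a 1e-7
  relative tie guard and clamps at 1 (floating-point sums can
  otherwise exceed 1 by ~1e-16).
* Both pi0 estimators clamp to [0, 1] after estimation; the smoother
  returns 0 with a warning when every p-value lies below the smallest
  lambda, since the tail then carries no information.
* All RNG goes through a single seed argument per generator
  (`withr::with_seed`), so identical seeds give bit-identical outputs
  and the global RNG state is never disturbed.
* Import never crashes a corpus scan: undecodable bytes, missing
  delimiters and unsupported containers (.rtf, .tar) become
  import-failure records.

## Problem sizes in the test suite

The acceptance-level checks run at their full stated replication: 200
replicates per effect count for the detection-limit search, 500
pure-null sets for the familywise-error bound, 50 replicates per true
pi0 for recovery, 100 seeds per group size for the small-N direction,
and 200 simulated experiments for the rescue direction. Module-level
variants of the same claims run at 10–50 replicates with majority-style
assertions, which keeps the default suite under two minutes without
weakening the full-scale claims.

## Known limitations

* Histogram classes depend on the bin count; B = 40 is the package
  default and anything it reports should be read relative to it.
* The classifier's decision order for composite flag patterns
  (interior runs force *other* even alongside boundary runs) is a
  documented convention, not the only defensible one.
* The validator's right-skew rule overlaps the conservative class by
  design; pipelines that want to classify conservative sets should
  classify first and validate for mining hygiene only.
* pi0 estimates are only meaningful for uniform / anti-conservative
  sets, and even there both estimators inherit the usual upward bias
  under low power.
* Excel import goes through `readxl` and is only as good as the sheet
  layout; multi-header sheets will mine poorly.
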