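---
title: "Per-sample differential expression and consensus fusion calling: methods and design"
author: "PCompFusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-sample differential expression and consensus fusion calling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PCompFusion)
```

# The problem

Cohorts of tumors with complex structural variants (cSVs) — chromothripsis
being the prime example — are biologically heterogeneous by construction:
each case carries rearrangements at different loci with different
consequences, so there is no replicate group to contrast against.
Conventional differential-expression frameworks (limma, DESeq2, edgeR)
model two or more groups with uniform within-group profiles and are a poor
fit when the question is "which genes are deregulated *in this one
sample*?". The same cohorts raise a second question: which fusion genes
did the rearrangements create? Individual fusion callers have notoriously
high false-positive rates, and their errors are largely tool-specific.

This package implements two statistics for these questions: **PComp**, a
per-sample differential-expression call built from all pairwise
regressions of the cohort, and a **meta-caller** that intersects
confidence-filtered reports of three fusion callers and validates the
consensus against genomic-array breakpoints.

# The PComp statistic

## Normalization

Input is a gene-level read-count table (htseq-count layout; summary rows
prefixed `__` are dropped and do not enter library sizes). Genes must
have a count of at least `minCount` (default 1) in at least `minSamples`
(default 6) samples; the default reflects a ten-sample cohort where a
gene informative for pairwise comparison should be observed in most
samples. Counts are then normalized as

$$\mathrm{RPKM}(g,s) = \frac{\mathrm{counts}(g,s)\cdot 10^9}
{\mathrm{length}(g)\cdot \mathrm{librarySize}(s)}$$

and transformed to $\log_2(\mathrm{RPKM} + c)$ with offset $c = 1$ by
default, so a zero count maps to exactly 0 and all values stay finite.

Two definitions deserve explicit statement because they are easy to get
silently wrong:

* **Library size** is the column sum of the count matrix *at load time*,
  before low-expression filtering, and is carried unchanged through all
  later subsetting. Normalization denominators must not drift with filter
  settings.
* **Gene length** is the union-exon length from the GTF (overlapping
  exons merged), computed with `GenomicRanges::reduce()`. A user-supplied
  length column in the simplified gene table overrides it.

## Pairwise bands

For target sample $y$ and comparator $x$, the per-gene log2 values are
fit by ordinary least squares across the $m$ retained genes. Every gene
is classified against a band around the fitted line at level $1-\alpha$
(default $0.999$, i.e. $\alpha = 0.001$): side $+1$ above, $-1$ below,
$0$ inside. The default band is the pointwise **prediction interval**,
with half-width at $x_g$

$$t_{1-\alpha/2,\,m-2}\; s\,
\sqrt{1 + \tfrac1m + \tfrac{(x_g-\bar x)^2}{S_{xx}}}.$$

A mean-confidence band (the same expression without the leading 1) is
available via `bandType = "confidence"`, but it shrinks like $1/\sqrt m$
with the number of genes and would flag nearly every gene in a
transcriptome-sized matrix; only the prediction form makes
individual-point outlier calls statistically coherent, which is why it is
the default.

The orientation is fixed: the target sample is always the response ($y$),
each comparator the regressor ($x$), so "above the band" always means
over-expressed in the target. Without a fixed orientation the calls would
depend on an arbitrary pair ordering.

One operating characteristic worth knowing: a single displaced gene at an
*extreme* of the x-range partially masks itself. Its leverage inflates
both the residual SD and its own band width, and the studentized ratio
$\sqrt{(m-2)(1-h)/(1+h)}$ can stay below the 99.9 % t quantile for small
$m$ regardless of how large the displacement is. With transcriptome-sized
gene sets the effect is negligible, but on toy examples an outlier
planted at the end of the range may legitimately stay inside the band.

## Consensus and confirmation

A gene is a candidate for the target sample when its side is non-zero and
*identical* in at least $n-1-\texttt{allowedShared}$ of the $n-1$ pairwise
fits and never the opposite sign in the rest. The strict default
`allowedShared = 0` is the all-pairs rule; raising it admits cohorts in
which a few samples share expression similarities. Down- and
up-regulation are never mixed: a gene above the band in eight pairs and
below it in one is not reported at any setting.

Each candidate is confirmed with a two-sided one-sample t-test of the
non-target samples' values against the hypothesized mean equal to the
target's value ($n-2$ degrees of freedom in an $n$-sample cohort; only
the target is excluded from "the rest"). Degenerate cases are fixed by
convention: zero variance in the rest gives $p = 1$ when their common
value equals the target's and $p = 0$ otherwise, flagged as degenerate.
The reported direction always comes from the regression side, not from
the t statistic's sign. Calls with $p$ below `testAlpha` are reported,
sorted by $p$ within sample. The package default is `testAlpha = 0.05`;
a stringent cohort-level analysis uses 0.001, and the package's own
calibration runs use that value. No multiple-testing correction is
applied — the statistic is reported at raw p thresholds, and the all-pairs
consensus is itself a severe filter (see the calibration below).

## Direction concordance

`concordanceWithReference()` overlaps the calls with an external
per-sample list (for example a transcriptomic-array analysis) and
reports, per sample, the overlap counts and
$100 \times \#\{\text{identical direction}\} / \#\{\text{overlap}\}$,
rounded half-up to two decimals, `NA` on an empty overlap.

# The fusion meta-caller

## Per-caller confidence filters

* **EricScript**: keep calls with Eric score strictly over 0.90.
* **JAFFA**: keep calls whose classification equals `HighConfidence`
  exactly (whitespace-trimmed, case-sensitive).
* **FusionCatcher**: the tool publishes no single high-confidence column,
  so the filter is an explicit, overridable predicate: a call passes when
  its description field contains none of a blacklist of artifact tags
  (defaults: `banned`, `readthrough`, `read_through`, `adjacent`,
  `conjoing`), matched case-insensitively as fixed substrings.

The only evidence threshold applied at parse time is spanning reads
$\ge 1$: lowly expressed fusions are deliberately not pre-filtered, so
weakly transcribed chimeras remain detectable.

## Consensus and flags

Calls are matched **across callers by the unordered, uppercased
gene-symbol pair** (`fusionKey()`), not by coordinates — the three tools
disagree on junction coordinate conventions more often than on partner
identity. Orientation and per-caller coordinates are retained as
evidence; the representative junction is the supporting call with the
most spanning reads (ties broken by caller-name lexical order). A key
supported by at least `minCallers` (default 2) distinct callers becomes a
consensus fusion. Intragenic keys (both partners identical) are kept but
flagged.

Two artifact flags annotate, and never delete, consensus fusions:

* **read_through**: partners on one chromosome whose gene spans are
  separated by at most `maxGap` (default 100 kb, inclusive; overlapping
  spans count as gap 0). Adjacent-gene chimeras are the classic
  transcriptional read-through false positive.
* **recurrent**: the same key in at least `minRecurrentSamples` (default
  2) distinct samples. In cohorts whose rearrangements are private per
  case, recurrence across cases points to an artifact rather than
  independent identical breakage. A companion column
  (`partner_recurrent`) marks fusions one of whose partners recurs with a
  *different* partner; these are reported but not auto-labelled FP, since
  arrays can miss balanced events.

## Breakpoint concordance

Array segments (copy-number variants and losses of heterozygosity)
contribute their start and end positions as breakpoints; BED-dialect
input is converted from 0-based half-open to 1-based inclusive. A fusion
is classified **TP** when either junction lies within $\pm$`window`
(default 100 kb, boundary inclusive) of a breakpoint on the same
chromosome in the same sample. The generous window absorbs both array
resolution and the systematic offset between exonic fusion junctions and
possibly intronic genomic breakpoints; no gene-model snapping is
attempted. Among unmatched fusions, those flagged read-through or
recurrent — or carrying a `manual_label` of `"FP"`, which lets users
reproduce hand-curated labels exactly — are **FP**; the remainder stay
**unvalidated**. Matching is restricted to the fusion's own sample, and
any segment boundary counts, whether or not the segment belongs to a
chromothripsis-classified region.

Rate tables round half-up to two decimals, and totals rows are always
computed from summed counts, never from averaged rates.
`callerOverlapTable()` does the TP/FP/FN bookkeeping against a truth
universe, satisfying identified = TP + FP and |truth| = TP + FN by
construction.

# The synthetic cohort

The generators emulate the structure the pipelines assume, not any real
biology:

* **Counts**: negative binomial per gene and sample (dispersion 0.05)
  with log-normal gene means (meanlog 4, sdlog 1.2) and mild
  library-size variation (±20 %). Default cohort: 10 samples × 5000
  genes. Each sample receives 20 private spikes at ±4 log2 units; spiked
  genes are drawn among genes with baseline mean ≥ 50 so both directions
  stay detectable after normalization.
* **Log-expression**: a direct Gaussian generator
  (`simulateLogExpression()`) for calibrating the statistic without the
  count layer — gene baselines (SD 2 around 5), i.i.d. noise, optional
  spikes. Setting the baseline SD to 0 gives a pure i.i.d. null matrix.
* **Toy genome**: non-overlapping gene models on four chromosomes,
  ~300–400 kb apart, with twelve deliberately adjacent pairs (gap
  2–40 kb) that seed read-throughs; exported as GTF.
* **Caller reports**: each true fusion (default 5 per sample, partners on
  different chromosomes) is detected by each caller independently with
  its sensitivity (default 0.95) and written with a passing confidence
  value; caller-specific false positives (default 30 per caller) carry
  passing confidence for half and failing for the other half, so the
  filters are exercised in both directions; read-through chimeras of
  adjacent pairs are written by two callers so they reach the consensus,
  where the gap flag must catch them; the first adjacent pair recurs in
  two samples to exercise the recurrence flag.
* **Segments**: each true fusion's 5' junction receives a segment
  boundary jittered by a truncated Gaussian (SD 25 kb, truncated at the
  100 kb window, so a planted truth always validates); unrelated segments
  are placed beyond the simulated gene territory so the planted truth
  labels stay exact.

All generators are deterministic given the spec's seed (each draws from
its own substream at a fixed offset) and restore the caller's RNG state.

What the simulation does **not** model: read-level noise, mapping
artifacts shared between callers (caller errors are independent here,
which flatters the consensus), correlated gene expression, batch
effects, or count-level mean–variance trends beyond a single dispersion.
Passing calibration on this cohort shows the statistics behave as
designed under their own assumptions; it does not certify performance on
real data.

# Operating characteristics

The test suite measures (at fixed seeds):

* **Null calibration**: on i.i.d. Gaussian matrices (2000 genes × 10
  samples, 10 replicates) the mean per-sample call rate at
  `testAlpha = 0.001` stays below $2\alpha$ — empirically around
  $8\times10^{-4}$, i.e. the all-pairs consensus makes the procedure
  conservative relative to the nominal t-test level.
* **Spike recovery**: with ±4 log2 private spikes over SD 0.5 noise
  (5000 genes × 10 samples, 20 spikes per sample), mean sensitivity is
  ≈ 0.907. A single 200-spike replicate fluctuates by ±0.02–0.03 around
  that value, so the suite averages 40 replicates; the quantity asserted
  is the mean. Essentially all misses are band-consensus misses — the
  spiked gene lands inside the band in one of the nine pairs — not
  t-test failures; the residual SD of a pair is inflated both by the
  two samples' noise ($0.5\sqrt2$) and by the other planted spikes.
* **Fusion consensus recall**: with per-caller sensitivity $p$,
  a truth reaches the two-of-three consensus with probability
  $3p^2(1-p)+p^3$ (0.972 at $p=0.9$); the simulated recall over 200
  planted truths sits within three binomial SDs of that value.
* **Concordance**: with zero breakpoint jitter every true consensus
  fusion classifies TP at the 100 kb window, and every planted
  read-through is flagged at the default gap.

These problem sizes (50 × 6 for brute-force equivalence checks, 2000 ×
10 for null calibration, 5000 × 10 for spike recovery, 200 planted
truths for recall) were chosen to make Monte Carlo error small relative
to the asserted margins while keeping the full suite around a minute.

# Known limitations

* PComp's strict all-pairs rule loses sensitivity as cohorts grow: one
  noisy comparator vetoes a call (`allowedShared` mitigates this at the
  cost of specificity).
* Matching fusions by symbol pair cannot separate distinct junction
  isoforms of the same gene pair, and symbol drift between caller
  annotation versions will break matches.
* The FusionCatcher high-confidence predicate is a documented blacklist,
  not the tool's internal notion; users should adjust it to their
  FusionCatcher version.
* Breakpoint validation can only confirm unbalanced events; balanced
  translocations and inversions legitimately stay unvalidated.
* The one-sample t-test treats the non-target samples as exchangeable;
  shared structure among them (batches, subtypes) is not modelled.
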