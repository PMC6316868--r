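---
title: "Detecting B-chromosome sequence from coverage ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting B-chromosome sequence from coverage ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

B chromosomes are dispensable supernumerary chromosomes carried by some
individuals of a population. Their sequence is largely copied from the
ordinary (A) chromosomes, so reads sequenced from a B-carrying individual
mostly align to the homologous A-genome positions of a standard reference
assembly. A region that exists in `c` extra copies on a haploid B therefore
shows *elevated read depth* in a B carrier relative to a B-lacking
individual. `bblockr` implements that comparison end to end: per-base
scaled coverage, the scaled coverage ratio statistic, a per-base binomial
test, merging and filtering of significant positions into "B blocks",
multi-sample "core" intersection, copy-number estimation, A-space/B-space
length accounting, and gene-overlap reporting — together with a paired
coverage simulator that plants known B segments so every stage can be
validated without any sequencing data.

## The model

Let `d_F(i)` and `d_M(i)` be the deduplicated per-base read depths of the
B-carrying female and the B-lacking male reference at base `i`, and
`mu_F`, `mu_M` their genome-wide mean depths (total depth over total
genome length, zero-depth bases included). Scaled coverages are
`s_F(i) = d_F(i) / mu_F` and `s_M(i) = d_M(i) / mu_M`; each averages to
exactly 1 over the genome. The scaled coverage ratio is

    SCR(i) = s_F(i) / s_M(i).

The carrier's A genome is diploid while the B is haploid, so a segment
with `c` B-located copies has expected carrier depth proportional to
`(2 + c) / 2` of baseline and expected SCR of `(2 + c)/2` (for a single B
per cell; with `b` Bs, `(2 + b c)/2`). A simple duplication *within* the
carrier's diploid A genome instead gives SCR = 2, which is why the
calling threshold is set at SCR >= 3 — at that ratio a region must carry
at least 4 B-located copies, and A-genome duplications cannot reach it.

Depth ratios alone are noisy where coverage is thin, so each base is also
tested with an exact binomial: conditional on the total depth
`n = d_F + d_M`, the carrier's depth `X = d_F` is Binomial(`n`, `p`) under
the no-difference null, with `p = mu_F / (mu_F + mu_M)` fixed genome-wide
from the relative mean depths. `binom_upper_tail()` returns
`P(X >= x)`, computed through the regularized incomplete beta function,
which is stable far beyond the depths this assay produces. The test is
one-sided (upper tail): only carrier *excess* can indicate B sequence,
and a base must simultaneously clear SCR >= 3, so a lower tail could
never contribute a call; a two-sided test would merely double the
p-values of the kept positions.

## Block calling

Bases with `SCR >= 3` **and** `p <= 0.001` (both comparisons inclusive,
as the thresholds are stated) are merged whenever consecutive passing
positions lie within 300 bp of one another — positions exactly 300 bp
apart merge. A merged interval spans the first through the last passing
base. Intervals of length <= 500 bp are then removed, and so are
intervals where <= 10% of the spanned positions pass both per-base
thresholds (both removals inclusive, so retained blocks are >= 501 bp
with passing fraction strictly above 0.10). The passing fraction is
computed over the final block span. The block-level SCR is the ratio of
the *mean* scaled coverages over the block, not the mean of per-base
ratios; ratios of means are robust to per-base zeros and are what the
copy-number arithmetic below inverts.

The merge rule is deliberately equivalent to clustering 1-bp features
with a maximum merge distance: the independent oracle used in the test
suite is both a naive O(n^2) clustering and `IRanges::reduce()` with
`min.gapwidth` equal to the gap. Note that `bedtools merge -d g` on
1-bp features links positions up to `g + 1` apart (it measures the gap
*between* features); this package follows the position-difference rule
(`p2 - p1 <= g`), which is what the stated worked behaviour of the
thresholds implies.

## Core blocks and turnover

With N carrier samples, a base is *core* when the called blocks of at
least `k` samples cover it (the classic choice is all-but-one,
`k = N - 1`). Support counting is at base resolution; maximal runs of
qualifying bases form core intervals with no re-merging and no length
re-filter, so core intervals may be shorter than any single sample's
blocks — large blocks legitimately fragment where sample support
changes. The reported `support` of an interval is the minimum per-base
sample count within it. Comparing each sample's total called B space
with the B space of the core set measures sequence turnover: the
fraction of a carrier's B content that is shared ancestrally versus
private to lineages (or false positive).

## Copy number, A space and B space

Where the reference's block-mean scaled coverage is at least 1,

    copies = 2 * block_SCR - 2

(the factor 2 converts the haploid-B/diploid-A comparison; subtracting 2
removes the two A-genome copies). Where the reference's scaled coverage
falls below 1 — poorly aligning regions, where dividing by a small
denominator would inflate the ratio — a single reference copy is assumed
and `copies = 2 * carrier_scaled_mean` is used instead. Estimates stay
fractional in all sums and are clamped at zero. A sample's *A space* is
the summed block length on the reference; its *B space* is the sum of
length x copies, the blocks' total contribution to the B chromosome.
Core intervals carry no global copy number: each sample re-estimates
copies over the core intervals from its own coverage, because the SCR of
a shared block varies strongly among individuals.

Two numerical consequences are worth knowing:

* **Estimator-switch ambiguity.** In ordinarily mappable regions the
  reference's block-mean scaled coverage concentrates around exactly 1,
  so sampling noise makes the regime choice a near coin flip there — and
  the two estimators differ by exactly 2 copies (`2*SCR - 2` versus
  `2*carrier_scaled`, which coincide only when the reference mean is
  exactly 1 and SCR equals the carrier mean). Per-block copy numbers for
  low-copy blocks therefore carry an intrinsic ~2-copy uncertainty; the
  test suite bounds recovery error accordingly.
* **Genome-mean inflation.** The B's own reads inflate `mu_F`, deflating
  every scaled value and hence every SCR by `1 + I`, where
  `I = sum(len_j * c_j) / (2G)` is the planted (or real) B content
  relative to the diploid genome. In the real system `I` is a few
  percent and routinely ignored. At aggressive desk scales it is not:
  planting multi-megabase B content into a 2 Mb toy genome halves every
  SCR, pushes 4-copy segments (expected SCR 3) below the calling
  threshold and biases copy estimates low by the same factor. The
  simulator makes no hidden correction — it reproduces exactly what
  genome-mean scaling does — so simulated study designs should keep the
  planted B space near a realistic fraction (~5%) of total coverage, as
  the package's own recovery tests do.

## The simulator

`simulate_pair()` draws per-base depths around an expected coverage
surface: reference expectation `mu_M` everywhere (times a mappability
retention factor inside configured dropouts), carrier expectation `mu_F`
times `(2 + b c)/2` inside planted segments, times 2 inside A-genome
duplications, with retrogene artifacts raising carrier depth over exons
only (`true_retrogene`) or both samples' depth over a whole gene
(`divergent_intron`, the signature of an old full-length copy whose
introns diverged too far for short reads to align). Noise is Poisson by
default; a negative-binomial option (variance `mu + phi mu^2`, default
`phi = 0.1`) reflects the overdispersion of real short-read depth, and
`noise = "none"` gives the rounded expectation for analytic checks.
Everything planted is recorded in a truth table, and the same seed gives
bit-identical tracks.

Default depths are 15x (carrier) and 25x (reference pool), within the
~12-52x range typical of the resequencing experiments this analysis is
applied to. Mappability dropouts scale *both* samples but are the route
by which the reference's scaled coverage dips below 1, exercising the
low-mappability copy estimator.

What the simulator does *not* emulate: read-level artifacts (mapping
quality, GC bias, alignability as a function of read length), sequence
content, or B sequence with no A-genome homolog — the latter is
undetectable by any coverage-ratio analysis, simulated or real. Passing
recovery tests therefore demonstrate the statistical machinery, not
robustness to alignment pathology; on real data the multi-sample core
set is the main defence against both.

## Parameters and defaults

| parameter   | default | meaning                                              |
|-------------|---------|------------------------------------------------------|
| `scr_min`   | 3       | minimum per-base SCR (inclusive); 4+ B copies        |
| `alpha`     | 0.001   | maximum per-base binomial p (inclusive), uncorrected |
| `merge_gap` | 300 bp  | maximum distance between passing positions merged    |
| `min_len`   | 500 bp  | blocks `<= min_len` are removed                      |
| `min_frac`  | 0.10    | blocks with passing fraction `<= min_frac` removed   |
| `core_k`    | N - 1   | samples required per core base (all-but-one)         |

No multiple-testing correction is applied across bases; the fixed
per-base `alpha` is part of the procedure being reproduced, with the
block filters and the core intersection doing the error control. Raising
`scr_min` or lowering `alpha` never increases the called footprint
(verified as a property test).

## Degenerate inputs and tie-breaks

* Reference scaled coverage 0 with carrier coverage > 0 gives SCR = +Inf:
  the ratio is undefined there, the sentinel passes any SCR threshold,
  and the binomial test alone gates the call. 0/0 gives SCR = 0, and a
  base with no reads in either sample gets p = 1.
* An empty block set quantifies to an all-zero report; the core percent
  of B space is reported as `NA` rather than 0/0.
* Copy estimates below zero (possible for re-quantified core intervals
  with block SCR < 1) clamp to 0.
* Depth files may omit zero-depth bases; absent bases are depth 0 and
  *do* count toward the scaling mean. Depth inputs are assumed already
  deduplicated upstream; the package begins at the per-base depth
  contract and exposes no switch for read-level filtering.

## Problem sizes used in the tests

The test suite validates the binomial tail against exact pmf summation
up to n = 1000 (tolerance 1e-12), the interval engines against
brute-force per-base oracles on a thousand randomized toy instances
(chromosomes up to 100 kb), and full-pipeline recovery on simulated
2 x 1 Mb genomes: a realistic design planting ~5% B content (all
segments recovered, breakpoint error well under the merge gap, copy
estimates within the estimator-switch ambiguity) and the aggressive
design discussed above, which documents how genome-mean inflation
degrades recovery when planted content rivals the genome itself.
Control pairs with nothing planted are required to stay under 0.1% of
the genome in falsely called footprint; in practice they call no blocks
at all at default depths.

## Known limitations

* Sequence unique to the B (no A homolog) is invisible, as are segments
  with fewer than 4 B-located copies (SCR below 3), including 2-copy
  segments and A-genome duplications — by design.
* Gene overlap is counted at gene level against distinct gene ids; an
  intronic insertion can make a gene *look* B-located, which the package
  flags (`intron_only`) but deliberately does not remove, reproducing
  the reporting semantics of the underlying analysis.
* Copy numbers inherit the ~2-copy estimator-switch ambiguity and the
  genome-mean deflation factor described above.
* The per-base binomial treats bases independently; neighbouring bases
  share reads, so per-base p-values are correlated over ~read-length
  scales. The merge/filter stages absorb this; the p-values themselves
  should not be interpreted marginally.
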