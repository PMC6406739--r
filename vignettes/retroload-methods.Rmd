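---
title: "Quantifying retroelement-linked TFBS regulatory load: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retroelement-linked TFBS regulatory load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroload)
```

## The problem and the scores

Retroelements (SINEs, LINEs, LTR retrotransposons and endogenous
retroviruses) cover roughly 40% of the human genome and are a major donor
of transcription factor binding sites (TFBS). Because an RE insertion drops
a block of pre-made regulatory sequence into a locus, the *fraction* of a
gene's TFBS that sit inside REs can be read as a marker of how fast that
gene's regulation has been rewired in recent evolution: a high RE-linked
share suggests a quickly reshaping regulatory module, a low share a
conserved one.

`retroload` computes this load from three standard inputs: a RepeatMasker
repeat annotation, a refGene-style gene table, and thresholded ChIP-seq
peak sets (narrowPeak or bedGraph) per transcription factor per cell line.
For each gene the 10 kb neighborhood of the transcription start site (5 kb
each side, the region densest in promoters and enhancers) is scanned; a
peak contributes one *hit* located at its summit, and a hit is RE-linked
when its summit falls inside a repeat interval. Writing $S_g$ for the
RE-linked hit weight and $T_g$ for the total hit weight in gene $g$'s
window, the per-gene scores are

$$\mathrm{GRE}_g = \frac{S_g}{\overline{S}}, \qquad
  \mathrm{NGRE}_g = \frac{S_g/\overline{S}}{T_g/\overline{T}},$$

where bars are means over all genes under study. GRE measures the RE-linked
load relative to the average gene (its mean over genes is exactly 1); NGRE
additionally divides out the gene's *total* regulatory load, so it isolates
the RE-specific share: a gene whose $S_g/T_g$ ratio equals the all-gene
average scores exactly 1, whatever its coverage. A gene with no hits at all
($T_g = 0$) is given NGRE 0 by convention — it has no measurable RE share —
and NGRE is invariant under any global rescaling of hit weights.

At the pathway level the analogues are additive:

$$\mathrm{PII}_p = \sum_{g \in p} \mathrm{GRE}_g, \qquad
  \mathrm{NPII}_p = \frac{\sum_{g \in p} S_g \,/\, \overline{S}}
                         {\sum_{g \in p} T_g \,/\, \overline{T}}.$$

PII is the pooled RE-linked load of the member genes; NPII is the pooled
relative share (a pathway whose pooled ratio equals the genome average
scores 1, and a single-gene pathway scores that gene's NGRE). These verbal
definitions admit small algebraic variants — PII as a size-normalized mean,
NPII as a sum of member NGREs — and both variants are implemented and
selectable (`pii(mode=)`, `npii(mode=)`); the defaults are the minimal
algebra consistent with the definitions above, and the package's headline
checks are insensitive to the choice. Scores are computed per cell line and
then aggregated as unweighted per-id means across cell lines, regardless of
how many TFs were profiled in each line.

### Repeat age fractions

Repeat families are split into evolutionary age classes by their mean
percent divergence from the RepeatMasker consensus: a family averaging
strictly below 8% is *young*, corresponding roughly to activity since the
human / New World monkey split; the *all* fraction reflects genome shaping
since the major eutherian radiations. The threshold comparison is strict
(`< 8`), the averaging unit is the RepeatMasker subfamily (`repName`), and
both choices are configurable (`young_threshold_pct`, and `level = "copy"`
for per-copy classification). Young-RE coverage is sparse — most genes can
have zero young-RE hits — so every scoring step tolerates and flags
zero-hit genes rather than failing on them; only a table with *no*
RE-linked hits anywhere is an error.

### Hit model choices

The unit of binding signal in thresholded ENCODE-style peak files is
ambiguous (peaks, reads, signal mass), so the hit model is explicit and
configurable (`hit_model()`): the default counts one peak = one hit at its
summit (the least ambiguous reading), with `signal_weighted` (weight =
signal value) and `any_overlap` (interval overlap instead of summit
location) as alternatives. bedGraph intervals get a synthetic summit at
their midpoint so both formats feed one model. Hits are summed across all
TFs profiled in a cell line. A summit inside two overlapping gene windows
counts for both genes (no splitting rule is imposed), and when repeats are
nested the *smallest* containing repeat supplies the class attribution
(the most specific annotation), while RE-linkage itself is a boolean.

## Extreme-set selection

Genes and pathways are ranked on a scatter of (GRE, NGRE) or (PII, NPII).
For genes, 1000 random subsets of 500 points are each fitted by ordinary
least squares (with intercept); the fits with the maximum and minimum slope
bound the cloud. The `floor(0.05 N)` points strictly above the max-slope
line with the largest Euclidean point-to-line distance are *RRE-enriched*;
the same count strictly below the min-slope line are *RRE-deficient*. On
24,389 genes this yields 1219 + 1219; on 3123 pathways (single fit, no
subsetting) it yields 156 + 156.

Two readings had to be fixed where the procedure is described loosely:

* *"above the line"* is defined by the sign of the vertical residual
  $y - (\hat a x + \hat b)$, and the Euclidean distance is used only to
  rank candidates — this is the only reading under which "lying above ...
  with maximal distance" is well defined;
* the quota is `floor(fraction * N)` (consistent with 1219/24,389 and
  156/3123); if fewer candidates lie on a side than the quota, all are
  returned and a shortfall flag is raised (exactly collinear points, within
  a relative tolerance of 1e-9, belong to neither side).

Ties in distance break lexicographically by id, subset draws are keyed to
the canonical ordering of ids, and one seed governs all 1000 draws, so a
selection is reproducible from (scores, seed) and invariant to input row
order. Axes are used raw; `standardize = TRUE` rescales both axes to unit
variance for sensitivity analysis.

A note on geometry that matters for interpretation: since
$\mathrm{NGRE}_g = \mathrm{GRE}_g \cdot \overline{T}/T_g$, every gene lies
on a ray through the origin whose slope is the reciprocal of its relative
total coverage. The upper-ray (enriched) extreme therefore consists of
genes with a high RE share relative to a modest total load, and the lower
ray of heavily covered genes with a low RE share — not simply of genes
with many or few RE hits.

## Enrichment statistics

Gene-class tests (e.g. miRNA-like and lncRNA-like content of the extreme
sets) are exact hypergeometric tail probabilities computed in log space
(`lchoose` + log-sum-exp over the exact support), accurate to at least 12
significant digits even at magnitudes of $10^{-18}$. The enrichment test is
the upper tail $P(X \ge k)$; the depletion test ("the class is *not*
over-represented") is the strict lower tail $P(X < k)$ — its exact
complement. The strict convention is deliberate: it is the one under which
the reference class-depletion probabilities reproduce from their
contingency counts, and it keeps the two one-sided tests summing exactly
to 1; an `inclusive` flag gives $P(X \le k)$ for users who want it.

Term enrichment over a GMT annotation uses the one-sided Fisher's exact
test (identical to the upper hypergeometric tail) or its conservative EASE
variant (overlap decremented by one before taking the tail), with every
term intersected with the background universe first and zero-overlap terms
omitted. Raw p-values with a 0.05 cutoff are the default (the convention of
DAVID-style annotation tools); Benjamini–Hochberg adjustment is available
(`adjust = "BH"`). The background for class tests is all annotated genes
and the selection universe is all scored genes; both are arguments, never
constants.

## Permutation confidence

The randomness control asks: could extreme sets as functionally coherent
as the observed ones arise from scores with no gene-specific structure?
Each of $B = 500$ iterations randomly reassigns the (GRE, NGRE) pairs of
the aggregated table to gene ids, reruns the full subset-based selection
with the *same* selection seed (so only the labeling varies), runs term
enrichment on both extreme sets, and keeps the 100 smallest p-values. The
empirical q-value of a set is the fraction of iterations whose best
(minimum) p-value is at least as small as the observed one; zero beating
iterations is reported as $q < 1/B$ (0.002 at $B = 500$), with the
conservative $(x+1)/(B+1)$ estimator available via a flag. Permutation is
applied to the averaged table by default; a per-cell-line mode (permute,
then average) is the documented alternative.

Two properties of this construction are worth knowing. First, the selected
*points* are identical in every iteration — permuting labels cannot change
the score multiset — so the null distribution of the minimum p-value is
driven purely by which ids land in the extreme sets, and at small scales it
is strongly discrete (a handful of overlap values). A single null q is
therefore not approximately uniform in any useful sense; the meaningful
guarantee, which the test suite checks over replicated null draws, is
super-uniformity: $P(q \le \alpha) \le \alpha + 1/B$. Second, because the
selection seed is held fixed, q measures exactly the contribution of the
label assignment, not of selection randomness.

## The synthetic-data generator

Real inputs at the original scale (hundreds of ENCODE TF profiles on hg19)
are not shippable, so the package generates complete, parseable bundles
with known planted structure: a UCSC-rmsk-style repeat table whose
families' divergences straddle the 8% boundary, a refGene-style gene table
with non-overlapping TSS windows on a fixed grid, narrowPeak files per TF
per cell line, GMT pathways, gene-class lists, and a truth JSON. Peak
placement is a two-step draw: a peak targets a gene window with probability
`p_window` (0.85) and otherwise an inter-window gap; within a window the
summit lands inside a repeat segment with the gene's probability
$\theta_g$. Background genes have $\theta = 0.3$; a planted 5% have
$\theta = 0.9$ and a disjoint 5% have $\theta = 0.05$. Repeat segments
cover 40% of each window's bases, decoupling $\theta$ from repeat
coverage. Peak widths are uniform on 200–400 bp with the summit at 30–70%
of the width. Everything is reproducible byte-for-byte from the seed.

Per-gene total coverage is deliberately heterogeneous — lognormal weights
with `coverage_sdlog = 0.5` — and the planted groups carry coverage
factors 0.5 (enriched) and 2 (deficient). This follows from the ray
geometry above: with equal coverage everywhere all genes collapse onto one
ray and the extreme-set rule has nothing to rank; real TFBS loads vary
over orders of magnitude across genes. Planted annotation terms cover 60%
of each planted group, for *both* directions, because the confidence claim
being mirrored concerns the enriched and the deficient set alike.

Named profiles (`scale_profile()`) pin the id-universe sizes used by the
full-scale class tests and selections: `table5` (25,075 background genes,
class sizes 1865 and 1505), `paper_scale` (24,389 genes, 3123 pathways, 13
cell lines), and `desk` (300 genes, 3 cell lines, seconds to run —
the default test scale). For checks that only need the (GRE, NGRE) cloud,
`simulate_score_table()` draws $T_g$ and $S_g \sim \mathrm{Bin}(T_g,
\theta_g)$ directly, which is how the 24,389-point selection-quota check
runs in well under two minutes.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: sequence content and mappability, realistic RE
phylogenies and nested insertions, correlated TF binding (peaks are placed
independently), tissue-specific binding differences (cell lines are i.i.d.
replicates of one $\theta$ vector), and the V-shaped score distribution of
the real genome (the synthetic cloud is a fan of rays with planted
outliers). Conclusions about statistical machinery transfer; conclusions
about biology do not.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; conversion
  happens only at I/O boundaries (RepeatMasker `.out` begin columns are
  1-based inclusive; UCSC `genoStart` is already 0-based; `milliDiv` is
  percent × 10).
* UCSC `repClass` strings map SINE→SINE, LINE→LINE, LTR→LTR/ERV, all
  else→other; LTR retrotransposons and endogenous retroviruses are one
  class throughout.
* Gene identity is the gene table's `name` column verbatim; duplicate ids
  collapse to the first occurrence with a warning; no symbol aliasing.
* OLS fits use the closed-form covariance/variance expressions, vectorized
  over all subsets; subsets with zero x-variance are skipped.
* The hypergeometric tail rejects inconsistent counts
  ($k > \min(n, K)$, $k$ below the support, $K > N$, $n > N$) rather than
  clamping them; the EASE decrement is clamped to the support's lower end.
* Pathways with no scored member, or zero pooled $T$, get `NA` scores and
  a flag — never a silent zero.
* Pearson correlations across cell lines drop ids pairwise (no
  imputation) and flag pairs sharing fewer than 3 ids; p-values come from
  the exact t-distribution via `cor.test`.
* Pipeline runs (`run_pipeline()`) write every intermediate as a
  deterministic `#`-headed TSV plus a JSON manifest recording parameters
  and seeds; on a stage failure, outputs written so far are renamed
  `.partial` and the manifest records the failing stage.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on generated data at
these scales, chosen so the full suite completes in a few minutes on one
core: interval-assignment cross-checks at $10^3$ peaks × $10^3$ repeats;
selection quotas at the full-scale universes (24,389 genes, 3123
pathways) via direct score simulation; the permutation confidence run on a
5,000-gene bundle with ~300,000 peaks and $B = 500$; and null calibration
of q at $B = 50$ over 200 replicated draws of a 150-gene universe.

## Known limitations

The four scores are implemented as the minimal algebra consistent with
their verbal definitions, with the documented alternative modes as
insurance against a different reading. Because the hit unit in thresholded
peak releases is ambiguous, absolute hit totals are not comparable across
hit models — only normalized scores are. Young-RE analyses typically want
a smaller extreme-set quota than 5% of all genes (most genes have zero
young-RE hits), and the right quota depends on the dataset; it is an
explicit parameter rather than a derived one. Multi-mapping reads, IDR
itself, and upstream peak calling are out of scope: the package starts
from thresholded peak files.
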