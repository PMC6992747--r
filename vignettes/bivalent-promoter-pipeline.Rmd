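---
title: "Promoter chromatin states, bivalent domains and RNAPII pause release"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter chromatin states, bivalent domains and RNAPII pause release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivalomics)
```

## The analysis this package implements

Endothelial cells respond to growth-factor stimulation (e.g. VEGFA) with a
rapid, partly transient transcriptional program. A recurring observation in
such systems is that many responsive genes carry a *bivalent domain* (BD)
at the promoter — the simultaneous presence of the activating H3K4me3 and
the repressive H3K27me3 mark — and that their activation proceeds through
release of promoter-proximally paused RNA polymerase II rather than removal
of H3K27me3. `bivalomics` implements the desk-side computational layer of
such a study as a tested, reusable pipeline:

1. **Signal quantification**: input-normalized ChIP signal over
   strand-aware windows anchored at the TSS, TES or gene body, from
   bedGraph coverage tracks of arbitrary bin width.
2. **Promoter-state clustering**: K-means over a genes x marks matrix of
   promoter signal (TSS ± 1 kb), with the number of clusters selected by
   the mean silhouette width, and per-cluster gene-set enrichment by the
   one-sided exact test.
3. **Bivalent-domain calling**: a gene is bivalent iff its promoter
   overlaps at least one H3K4me3 peak *and* one H3K27me3 peak
   (blacklist-filtered upstream).
4. **Expression classes**: expressed-gene filter (FPKM ≥ 1 at any time
   point), DEG rule (fold change ≥ 2 or ≤ 0.5 *and* FDR ≤ 0.1 at 1, 4 or
   12 h versus 0 h, boundaries inclusive), and temporal classes
   (early-up / late-up / down).
5. **RNAPII pausing**: the pausing index (PI), i.e. the ratio of
   input-normalized RNAPII density at the TSS window (−50, +300 bp) to the
   input-normalized density over the gene body, and time-course summaries
   of pause release.
6. **ChIP-qPCR occupancy**: the delta-delta-Ct occupancy formula and
   two-group comparisons (exact Mann–Whitney, Student's t).
7. **Synthetic data**: a deterministic generator that plants all of the
   above structure into a toy genome, so every stage is validated by
   parameter recovery rather than by eye.

Differential-expression model fitting, read alignment, duplicate marking
and peak calling are out of scope: the pipeline consumes gene models,
coverage tracks, peak calls and differential tables.

## Coordinate and container conventions

All coordinates are 0-based half-open (`[start, end)`, the BED
convention), everywhere — windows, peaks, bins. Chromosome names are
matched as exact strings; `check_chrom_namespace()` reports chromosomes
present in one input but missing from another, which is the classic silent
failure mode when mixing references. Coverage tracks are sorted,
non-overlapping `(start, end, value)` bins with implicit zero elsewhere;
no fixed bin width is assumed. Overlap machinery is delegated to
`GenomicRanges`/`IRanges` (with the half-open to 1-based-closed shift
applied at one single point).

## Signal model and normalization

The signal total of a window is the sum over bins of value × overlap
length (signal·bp); the density divides by window length. Input
normalization is the ratio

$$r = \frac{d_\text{ChIP} + \varepsilon}{d_\text{input} + \varepsilon}$$

with the pseudocount ε (default **0.01 signal/bp**) applied symmetrically
to numerator and denominator: jointly empty windows give exactly 1, and
ratios remain bounded in sparsely covered regions. Ratio (rather than
subtraction) was chosen because the pausing-index formula divides two
normalized densities, which is only scale-free for the multiplicative
form. Tracks are assumed depth-matched; the package applies no
library-size factor between ChIP and input (the generator emits tracks on
a common scale, and external tracks should be scaled upstream).

Profile matrices (`profile_matrix()`) come in two flavours:
`tss_centered` (flank of ±5 kb by default, equal bins) and
`genebody_scaled`, where each flank receives `round(nbins/4)` bins and
the body the remainder, so genes of different lengths align. Rows of
minus-strand genes are reversed so transcription runs left to right; no
per-row rescaling is applied, so matrices from different time points share
one scale and their column means can be overlaid directly. Genes whose
body is shorter than the number of body bins are flagged and excluded
from the column means rather than interpolated.

## Promoter-state clustering

The clustering matrix holds, per gene and mark, log2 of the
input-normalized promoter ratio (TSS ± 1 kb), with each column z-scored
(`transform = "log_z"`). Raw ratios are dominated by the highest-signal
mark; the log/z transform is the standard remedy and `transform = "raw"`
is available for sensitivity analysis. By default the matrix uses the
pre-stimulation (hour-0) tracks: the cluster identity is the chromatin
state a promoter is *in* when the stimulus arrives; clustering on the full
time course is possible by passing additional named tracks.

K-means uses Euclidean distance with `nstart = 25` restarts and a recorded
seed; for each candidate K in 2–10 the mean silhouette width is computed
(on the full matrix up to 5000 rows, above that on a seeded subsample,
since silhouette cost grows quadratically) and the K with the largest mean
silhouette wins. Identical inputs and seed give bit-identical labels. A
matrix of identical rows is rejected ("no cluster structure") rather than
partitioned arbitrarily.

Per-cluster gene-set enrichment uses the one-sided (greater)
hypergeometric tail — identical to the one-sided Fisher exact test on the
2×2 table — implemented via `phyper` so that large batches of tables can
be evaluated; the enrichment score is observed/expected with
`expected = n_cluster · |set| / N`, and both that score and the sample
odds ratio are reported because "enrichment score" is used for either in
the literature. P-values are reported raw together with the cluster count;
users who need family-wise control can adjust afterwards. Set-versus-set
overlap (`overlap_test()`) uses the Pearson chi-square without continuity
correction (toggleable), plus the expected overlap `|A||B|/N`.

Two statistical caveats discovered while validating, worth knowing:

* The exact one-sided test is **conservative at small counts**: with
  N = 1000 genes, six clusters and a 100-gene set its exact size at
  α = 0.05 is ≈ 0.036, because the discrete hypergeometric support
  rarely places a p-value just below the threshold. The test-suite
  calibration check therefore runs at a geometry chosen by analytic
  size computation (N = 5000, |set| = 500, exact size 0.0493) and
  separately asserts that the small-count regime errs on the
  conservative side. The calibration estimate treats the *replicate* as
  the binomial unit: the six cluster tests within one replicate are
  dependent because their overlap counts sum to the set size.
* For a 2×2 overlap test, printed marginals alone do not determine the
  p-value that a study reports: the choice of background universe
  changes it by orders of magnitude. `overlap_test()` is therefore
  validated against hand-coded chi-square and enumeration oracles, not
  against any published bound.

## Bivalent-domain calling

`call_bivalent()` marks a gene bivalent iff its promoter (TSS ±
`half_width`, default 1000 bp, clipped at the chromosome start) overlaps a
peak in each of the two sets by ≥ 1 bp (`min_overlap` configurable).
Half-open adjacency does not count as overlap. Each call carries evidence:
per mark, the overlapping peak with the largest overlap, ties broken by
leftmost start. One promoter per gene — multi-TSS isoforms are out of
scope, matching the gene-model input. Calls are symmetric in the two
marks and monotone in `half_width` (both properties are tested). Peak
calling itself and the choice of time point for the peak sets are
upstream decisions; the default study design uses the hour-0 (unstimulated)
peak sets, since bivalency is a property of the resting state.

## Pausing index

$$\mathrm{PI} = \frac{(\text{RNAPII}/\text{input})\ \text{density, TSS window}}
                     {(\text{RNAPII}/\text{input})\ \text{density, body window}}$$

with the TSS window (−50, +300) bp around the TSS and the body window from
`body_start_offset` (default **+300 bp downstream** of the TSS) to 2 kb
past the TES, both strand-resolved, and each window's ChIP density
normalized by the input density over the *same* window. The default body
start makes the two windows disjoint; the alternative reading that starts
the body 300 bp *upstream* of the TSS (which double-counts the pause peak)
is selectable via `body_start_offset = -300` for comparability with
descriptions that use it. Genes with a resolved body shorter than 300 bp
are flagged `short_gene`; genes with zero raw RNAPII in both windows are
flagged `no_signal` and excluded from summaries — a silent gene has no
defined pausing state, and reporting PI = 1 for it would fabricate one.
The body's normalized density is floored at ε so the ratio is finite.

`pi_timecourse()` joins per-time-point records, computes Δlog2 PI columns
versus the first time point, and reports the fraction of a supplied gene
set with decreasing PI between the first two time points — the
pause-release summary.

## ChIP-qPCR occupancy

`chromatin_occupancy()` computes `2^(ΔCt_test − ΔCt_ctrl)` with
`ΔCt = Ct_ChIP − Ct_input` at each site. Note the sign: under this
convention ("site", the default) stronger enrichment at the test site
(lower ChIP Ct) yields occupancy **below** 1, which is inverted relative
to the conventional 2^−ΔΔCt. The formula is implemented exactly as the
assay sheet states it, and `convention = "ddct"` selects the conventional
sign; the two are reciprocal. Replicates are summarized by the geometric
mean (occupancy is a log-scale quantity). Group comparisons use the exact
Mann–Whitney U test when both groups have ≤ 8 observations (falling back
to the mid-rank normal approximation with a warning when ties make the
exact distribution unavailable) or the equal-variance two-tailed t-test.

## The synthetic study

`synth_config()` defaults define the study conditions the tests and the
acceptance script run under:

| parameter | default | meaning |
|---|---|---|
| genome | 2 × 2.5 Mb | one gene slot per 10 kb, genes 2–6 kb |
| `n_genes` | 500 | |
| time points | 0/1/4/12 h | stimulation course |
| marks | H3K4me2, H3K4me3, H3K27ac, H3K27me3, RNAPII, input | |
| promoter states | 6 | empty, weak-K27ac, strong bivalent, fully active, repressed, weak bivalent |
| state sd | 0.25 log2 | neighbouring state means ≥ 5–6 sd apart |
| `n_bd_genes` | 120 | drawn from the two bivalent states; both peak types at the promoter |
| `n_deg` | 90 | P(DEG given BD) = 3 × P(DEG given not BD) |
| temporal mix | 45/30/25% | early-up / late-up / down |
| `pause_spec` | 30%, median 8, 4× | paused fraction, PI log-normal median, release fold at 1 h |
| `noise_sd` | 0.01 | input-track block noise (1-kb blocks) |
| bins | 10 bp | coverage emission grid |

Key generator mechanics: promoter mark signal is log-normal around the
gene's state mean; BD genes receive both peak types (±400/±600 bp around
the TSS) and lower planted FPKM (log-normal median 4 versus 20); DEG
membership is planted by exact counts so the BD enrichment fold is
realized deterministically; planted DEGs get FDR in [0, 0.1] and fold
changes ≥ 2.2 (or ≤ 0.5), non-DEGs get FDR in [0.2, 1] and fold changes in
[0.75, 1.35] — the generator does not simulate a differential-test null,
because the DEG *rule*, not the differential model, is in scope. One
early-up DEG and one down DEG are planted exactly at the FC = 2.0 /
FDR = 0.1 boundary so the inclusive thresholds are exercised. RNAPII
tracks realize each gene's planted PI as a TSS pulse over a body plateau
(pulse height solved from the PI formula including ε); pause-release
genes (paused ∩ DEG, exactly 30% of DEGs) quadruple their body plateau at
1 h, which both drops PI 4-fold and raises body occupancy, as pause
release does. Every file is a deterministic function of the config seed;
two runs with the same seed are byte-identical.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: read-level sampling noise and mappability
structure, fragment-length effects, copy-number and GC bias, peak-caller
false positives/negatives, multi-isoform promoters, inter-replicate
variance, and chromatin dynamics over the time course (histone-state
tracks are held constant; only RNAPII changes). Recovery being exact on
synthetic data shows the *computations* are right, not that the
biological thresholds are optimal.

## Numerical choices and degenerate inputs

* ε = 0.01 signal/bp everywhere a ratio is formed; invariance properties
  (scaling, strand mirroring) are tested at ε = 1e−9 where the
  pseudocount's bias would otherwise dominate.
* K-means ties and restarts: `nstart = 25`, `iter.max = 100`, per-K seed
  derived from the recorded seed; silhouette ties resolve to the smaller K.
* Overlapping bedGraph bins are an error, not silently merged;
  out-of-order bins are sorted.
* Windows clipped at the chromosome start keep their nominal length in
  profile densities (off-genome positions contribute zero signal), so a
  promoter at position 0 is not artificially inflated.
* Expression classes: a gene significant in both directions across
  comparisons is assigned by its earliest significant comparison
  (matching the early/late precedence); the down threshold is the
  symmetric FC ≤ 0.5.
* `write_tsv()`/`write_bedgraph()` format numerics with `%.8g`, making
  generated fixtures byte-stable and round-trips exact to 1e−8.

## Problem sizes

The test-suite and acceptance-script defaults are desk-scale by design:
500 genes on a 5-Mb toy genome, 10-bp coverage bins, 200-replicate
calibration loops, and full-enumeration oracles up to N = 60 (2×2 tables)
and n = 6 per group (Mann–Whitney). The full suite runs in well under a
minute per stage; the end-to-end pipeline on the default fixture takes a
few seconds and is checksum-reproducible.

## Limitations

* Peak-based BD calling inherits the upstream peak caller's sensitivity;
  signal-ratio-based BD calling is deliberately not implemented.
* The PI is descriptive; no significance test for PI shifts is provided
  beyond the fraction-decreasing and Δlog2 summaries.
* No multiple-testing correction is applied across clusters (raw exact
  p-values are reported with the cluster count).
* bigWig, BAM and GTF inputs are not parsed; convert to
  bedGraph/BED/TSV upstream.
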