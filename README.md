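# bivalomics

Promoter chromatin-state and RNAPII-pausing analysis for stimulus-response
ChIP-seq time courses.

## What problem this addresses

In differentiated cells responding to an acute stimulus (the motivating
setting is endothelial cells under VEGFA), many responsive genes carry a
*bivalent domain* (BD) at the promoter — H3K4me3 and H3K27me3 together —
and are activated through release of promoter-proximally paused RNA
polymerase II rather than loss of H3K27me3. Testing that picture
computationally requires a chain of small, error-prone steps:
input-normalized window signal, promoter-state clustering, peak-overlap BD
calling, DEG classification over a time course, pausing indices, and
ChIP-qPCR arithmetic. `bivalomics` implements that chain as one tested R
package for analysts working with gene models (TSV), coverage tracks
(bedGraph), peak calls (BED/narrowPeak), differential-expression tables
and Ct tables. Alignment, peak calling and differential-model fitting are
upstream and out of scope.

## The statistics at the core

* **Input normalization**: density ratio with a symmetric pseudocount,
  r = (d_ChIP + eps) / (d_input + eps), eps = 0.01 signal/bp.
* **Promoter states**: K-means on the genes x marks matrix of
  log2-ratio promoter signal (TSS +/- 1 kb, columns z-scored), K selected
  by mean silhouette width over K = 2..10; per-cluster gene-set
  enrichment via the one-sided hypergeometric (Fisher) test, enrichment
  score = observed/expected.
* **BD call**: promoter (TSS +/- 1 kb) overlaps >= 1 bp with at least one
  peak of *each* mark, after blacklist filtering.
* **DEG rule**: (FC >= 2 or FC <= 0.5) and FDR <= 0.1 at 1, 4 or 12 h
  versus 0 h (boundaries inclusive); expressed = FPKM >= 1 at any time
  point; temporal classes early-up / late-up / down.
* **Pausing index**: PI = (normalized RNAPII density, TSS −50..+300 bp) /
  (normalized density, gene body +300 bp..TES + 2 kb), each window
  normalized by input over the same window; pause release = PI drop at
  1 h.
* **ChIP-qPCR occupancy**: 2^(dCt_test − dCt_ctrl) with
  dCt = Ct_ChIP − Ct_input (conventional 2^−ddCt sign selectable).

A deterministic synthetic-data generator (`synth_generate()`) plants all
of this structure — six promoter states, 120 BD promoters, 90 DEGs with a
3-fold BD enrichment, log-normal pausing with 4-fold release at 1 h — into
a toy genome with a ground-truth manifest, so every stage is validated by
parameter recovery. See the vignette
(`vignettes/bivalent-promoter-pipeline.Rmd`) for the model details and
design choices.

## Worked example

```r
library(bivalomics)

bundle <- synth_generate(synth_config(seed = 7))

k4  <- filter_blacklist(bundle$peaks$H3K4me3,  bundle$peaks$blacklist)
k27 <- filter_blacklist(bundle$peaks$H3K27me3, bundle$peaks$blacklist)
calls <- call_bivalent(bundle$genes, k4, k27, half_width = 1000)

classes <- classify_expression(bundle$expression)
venn <- intersect_with_set(calls, classes$gene_id[classes$is_deg])
ov <- overlap_test(sum(classes$is_expressed), sum(classes$is_deg),
                   nrow(calls), length(venn$bd_and_set))

marks0 <- lapply(bundle$tracks[c("H3K4me2", "H3K4me3", "H3K27ac", "H3K27me3")],
                 `[[`, "0")
cl <- select_k_and_cluster(
  build_promoter_matrix(marks0, bundle$tracks$input[["0"]], bundle$genes),
  k_range = 2:10, seed = 11)

recs <- lapply(c("0", "1", "4", "12"), function(tp)
  pausing_index(bundle$tracks$RNAPII[[tp]], bundle$tracks$input[[tp]],
                bundle$genes))
names(recs) <- c("0", "1", "4", "12")
tc <- pi_timecourse(recs,
                    release_set = bundle$manifest$gene_id[bundle$manifest$is_release])
```

This prints (exactly, given the seeds):

```
bivalent promoters called: 120
expressed genes: 450 | DEGs: 90
DEG/BD overlap: 44 observed vs 24.0 expected (chi2 = 28.4, p = 9.8e-08)
<promoter_clusters> K = 6 over 500 genes (seed 11)
cluster
 1  2  3  4  5  6
84 84 83 82 84 83
pause release: 100% of the 27 planted release genes drop PI at 1 h
median PI of paused genes at 0 h: 7.43
```

Reading it: the caller recovers all 120 planted bivalent promoters; DEGs
overlap BD promoters almost twice as often as independence predicts (44
vs 24, a planted 3-fold conditional enrichment); the silhouette scan
picks the planted six promoter states; every planted pause-release gene
drops its pausing index at 1 h; and the measured median PI of paused
genes matches the planted log-normal (median 8) within sampling error.

The whole chain also runs as one call — `run_pipeline(config, outdir)`
with a YAML or list config (see `fixture_pipeline_config()`) — writing
one TSV per stage plus a JSON run manifest with parameters, seeds and MD5
checksums; reruns with the same config are byte-identical. A thin CLI
over the same functions is installed at `exec/bivalomics`
(`simulate`, `signal`, `cluster`, `enrich`, `bdcall`, `degclass`, `pi`,
`qpcr`, `run-all`).

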