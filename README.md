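# bivalscape

Downstream chromatin analysis around transcription start sites (TSSs)
for CUT&RUN / ChIP-seq / ATAC-seq coverage tracks, written for
epigenomics analysts who have tracks (bedGraph), peaks (BED), a gene
table (refGene dialect) and an expression table, and who need the
promoter-level arithmetic between those files and a figure:

* **Promoter-TSS catalog** — protein-coding (`NM_`) genes longer than
  2 kb, transcripts merged by exact TSS (strand-aware), with a
  transcription-oriented −500/+1000 bp quantification window.
* **Quartile classification** — promoters split into H3K4me3-Low,
  H3K4me3-Only and bivalent states: with Q1/Q3 thresholds over the
  whole catalog and strict inequalities,

  ```
  t_low  = Q1(H3K4me3),  class = Low       if  K4  < t_low
  t_high = Q3(H3K27me3), class = Bivalent  if  K27 > t_high   (else Only)
  ```

  using the interpolated quantile `h = 1 + (N − 1)q`. With 23,927
  distinct intensities this convention forces exactly 5,982 Low
  promoters.
* **TSS architecture** — Upstream/Center/Downstream subregions
  bracketing the −1/+1 nucleosomes and the nucleosome-free region;
  per-region 1.5-fold change calls between control and knockdown
  occupancy; a five-cluster taxonomy of (upstream, downstream) change
  pairs; selection of TSSs with decreased occupancy.
* **Peak algebra** — merging (bookended intervals coalesce), nearby
  assignment within 2 kb with deliberate anchor duplication, equal
  High/Low splits (`floor(N/2)` high: 34,771 → 17,385/17,386), binomial
  annotation enrichment.
* **Expression linkage** — DEG thresholding (`p ≤ 0.05`, fold change
  ≥ 1.5, inclusive), closest-peak linkage to down-regulated TSSs
  (2 kb / 500 bp), mean differential log2 intensities, Wilcoxon
  rank-sum / signed-rank tests.
* **Synthetic study** — a seeded simulator that generates gene tables,
  eight structured coverage tracks (per-class mark plateaus, Gaussian
  −1/+1 occupancy bumps, NFR accessibility, per-cluster knockdown
  effects, Poisson fragment noise), matched peak sets, an expression
  table and a ground-truth table — so the entire pipeline is testable
  offline.

All coordinates are 0-based half-open throughout (BED/bedGraph
native).

## Worked example

```r
library(bivalscape)

st <- simulate_chromatin(synthetic_config(seed = 1))
cfg <- pipeline_config(
  genes = st$genes,
  h3k4me3 = st$tracks$h3k4me3_control, h3k27me3 = st$tracks$h3k27me3_control,
  brg1_control = st$tracks$brg1_control, brg1_kd = st$tracks$brg1_kd,
  atac_control = st$tracks$atac_control, atac_kd = st$tracks$atac_kd,
  brg1_peaks = st$peaks$brg1, atac_peaks = st$peaks$atac,
  expression = st$expression)
res <- run_pipeline(cfg)
print(res)
#> promoter chromatin pipeline
#>   promoters: 420  (H3K4me3_LOW=105, H3K4me3_ONLY=214, BIVALENT=101)
#>   decreased TSSs: 192; merged peaks: 840; assignments: 840 (high 420 / low 420)
#>   DEGs: 14 up, 123 down; mean log2FC at down-DEG peaks: BRG1 -0.485, ATAC 0.000
```

Reading the output: 600 simulated gene records collapse to 420
eligible promoters; the quartile rule recovers the three chromatin
classes; 192 TSSs lose ≥ 1.5-fold remodeler occupancy on at least one
flank upon knockdown and each receives one of the five clusters; the
840 occupancy peaks all have an accessibility peak within 2 kb and
split 420/420 by control intensity; and at the peaks closest to the
TSSs of the 123 down-regulated genes, remodeler occupancy drops by
about 0.5 log2 units on average while the (unperturbed, in this
simulation) accessibility stays near 0.

A command-line wrapper with the same stages is installed as
`exec/bivalscape` (subcommands `simulate`, `catalog`, `normalize`,
`quantify`, `classify`, `cluster-tss`, `merge`, `assign`, `split`,
`run-all --config pipeline.yaml`).

## Documentation

The methods vignette
(`vignettes/promoter-chromatin-analysis.Rmd`) documents the model and
every convention in detail: the quantile and split conventions and the
counts they force, the pseudocount and fold-change rules, tie-breaks,
what the simulator does and does not emulate, and known limitations.
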