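# gsrkit

Integrative analysis of **G9a/GLP-sensitive H3K9me2 chromatin domains** and
their relation to nuclear-lamina association and 3D genome
compartmentalization.

H3K9me2 is a repressive histone mark written mainly by the G9a/GLP
methyltransferases and forms megabase-scale domains overlapping
lamina-associated domains (LADs) and B compartments. When G9a/GLP is
chemically inhibited (e.g. with UNC0638), the mark is erased preferentially
from a distinct set of regions — *G9a/GLP-sensitive regions* (GSRs) — and
this reshapes chromatin-lamina contacts and A/B compartment segregation.
`gsrkit` implements the full quantitative pipeline for this analysis:

- **Spike-in calibration** of ChIP-seq signal between conditions with the
  exogenous read fraction ρ = h / (h + m), so global loss of the mark is
  measurable.
- **GSR calling**: per-bin difference d = DMSO − UNC0638 at 1 kb, converted
  to a moving-window one-sample t-statistic (40 kb window),
  t = m / (s / √n); threshold chosen by a **mirrored-null empirical FDR**,
  FDR(c) = #{t ≤ −c} / #{t ≥ c} < 0.01 (the opposite tail as null);
  runs above threshold merged when closer than 10 kb and kept when ≥ 50 kb.
- **LAD analysis**: smoothed-threshold segmentation of Lamin B1 DamID log
  ratios, bp-exact classification of LAD switching (stable/loss/gain), and
  Wilcoxon rank-sum association with expression changes.
- **Hi-C statistics**: distance-expected O/E matrices; compartment PC1 from
  the correlation-matrix eigenvector with gene-density sign orientation;
  saddle enrichment of PC1-ranked bin pairs; **compartmentalization
  strength** = median(AA, BB) / median(AB) over the top/bottom 20% of bins
  by PC1; per-section **interaction scores** CS_x = C_x / C_total; and
  insulation-based TAD boundary strength.
- **Gene-centric integration**: promoter (TSS ± 2.5 kb) changes of
  H3K9me2, PC1, DamID and ATAC (log2 ratios for coverage assays,
  differences for signed scores), K-means (k = 4) clustering of expressed
  genes (baseMean ≥ 10.30), and per-cluster expression / genome-section
  statistics.
- A fully seeded **synthetic multi-omic generator** that plants GSRs, LADs,
  A/B checkerboard Hi-C and DE genes with known ground truth, so every
  stage has a recovery test without any external download.

## Worked example

```r
library(gsrkit)

# synthetic study: 2 chromosomes x 20 Mb, erasure depth 1.0 at noise 0.3,
# checkerboard contrast 1.5 (control) vs 1.7 (treated)
truth <- simulate_multiomics(sim_config(seed = 1))
report <- run_all(truth)

round(100 * report$gsr$genome_fraction, 1)      # 35.9  (% of genome in GSRs)
round(100 * report$gsr$fraction_in_ilad, 1)     # 65.6  (% of GSR bp in iLADs)
round(100 * report$lad$coverage_control, 1)     # 50.0  (% LAD coverage, control)
round(100 * report$lad$coverage_treated, 1)     # 38.0  (%, after treatment)
round(report$hic$strength_median_control, 2)    # 2.14  (compartment strength)
round(report$hic$strength_median_treated, 2)    # 2.66  (stronger after treatment)
round(report$genes$pct_up, 1)                   # 72.9  (% of DE genes up)
```

The numbers tell the study's story on planted ground truth: GSRs occupy
about a third of the genome and sit mostly in iLADs/A compartments; after
G9a/GLP inhibition LAD coverage drops, compartmentalization strength rises
(~24% here), and differential expression is dominated by up-regulation.
The K-means step isolates a gene cluster with ΔH3K9me2 < 0, ΔPC1 > 0 and
ΔDamID < 0 — promoters losing the mark and lamina contact while gaining
A-compartment character — which is strongly up-regulated
(`report$genes$cluster_expression`) and concentrated in GSR/iLAD regions
(`report$genes$cluster_sections`).

A thin shell wrapper for the common entry points is installed at
`inst/scripts/gsrkit` (`gsrkit sim|run|gsr ...`).

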