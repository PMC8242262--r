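---
title: "Methods: calling G9a/GLP-sensitive H3K9me2 domains and measuring genome compartmentalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling G9a/GLP-sensitive H3K9me2 domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsrkit)
```

`gsrkit` analyses what happens to the H3K9me2 chromatin landscape — and to
the nuclear architecture coupled to it — when the G9a/GLP
methyltransferases are inhibited. This vignette is the package's own
account of the statistical procedures, the choices that were genuinely
open, and what the accompanying synthetic data do and do not establish.

## Coordinate frame and missing data

All tracks, interval sets and contact matrices share a `GenomeLayout`:
0-based half-open coordinates (BED convention), bins anchored at
coordinate 0 of each chromosome, the final partial bin kept with its true
width for bp-weighted statistics. Bin counts are therefore
`ceiling(length / bin_bp)` and deterministic.

Missing data are first-class: a masked (`NA`) bin is excluded from every
mean, median, correlation and window statistic. Windowed statistics
additionally report missing when less than half of the window's
in-chromosome bins are unmasked (`min_frac = 0.5`), so sparse
microarray-style gaps cannot fabricate smoothed signal. Windows never
cross chromosome boundaries. For an even window of k bins the centered
window extends one bin further to the left (offsets `-k/2 … k/2 - 1`);
this convention matters only at domain edges and is fixed for
reproducibility.

## Spike-in calibration

Exogenous chromatin mixed into each sample before ChIP calibrates signal
across conditions. The scale factor is the exogenous fraction of
unique-mapping reads, ρ = h / (h + m), and coverage tracks are divided by
ρ *before* log-ratio formation — scaling raw signal, not ratios, is what
makes a genome-wide loss of the mark visible instead of being normalized
away. The cell-mixing proportion (1:4 in the emulated design) is metadata;
calibration uses read counts only. In the pipeline each track is scaled by
ρ_sample / ρ_control so the control condition is the reference; windowed
t-statistics are invariant to this common scale, but absolute difference
summaries are not, which is why the reference is pinned.

## GSR calling

The caller works on the per-bin difference d = control − treated at 1-kb
resolution, so *loss* of H3K9me2 is positive. Each bin is then assigned a
moving-window one-sample t-statistic over a 40-kb window:

t_i = m_i / (s_i / √n_i)

with m the window mean of d, s the window SD (n − 1 denominator) and n
the unmasked bin count. The published description ("converted the smoothed
signals into t-statistics") does not pin the exact construction; the
windowed one-sample t both smooths and standardizes in one step, matches
the probe-level language of broad-domain (LOCK-style) callers, and is
exposed as its own function (`t_statistic_track`) so an alternative can be
substituted. Degenerate windows follow explicit rules: fewer than two
unmasked bins → masked; zero variance with zero mean → masked; zero
variance with non-zero mean → signed infinity.

The threshold comes from a mirrored empirical null. With signal on the
positive tail, candidate cutoffs c are scanned on a fixed grid (step 0.1,
from 0 to max |t|) and

FDR(c) = #{t ≤ −c} / max(1, #{t ≥ c}).

The smallest c with FDR(c) below the target (default 0.01) is used.
Inclusive tail counts are used on both sides; with strict inequalities a
probe exactly at −c would never count as null, which contradicts the
count arithmetic the procedure is meant to implement. The original
analysis reported a fixed threshold of |t| = 8; `gsr_params(fixed_threshold
= 8)` reproduces that path, bypassing the search. When the FDR target is
unreachable — a pure-noise difference has symmetric tails — the threshold
search raises a typed error; the composed caller (`call_gsrs`) converts it
into a warning plus an empty domain set, which is the operationally correct
answer for "no real signal".

Segmentation keeps maximal runs with t strictly above the threshold,
*first* merges runs separated by less than 10 kb (masked gaps count toward
the distance: unmappable bins should not split biological domains), and
only then drops domains shorter than 50 kb. Merge-before-filter is the
order under which two sub-50-kb runs can legitimately survive as one
domain. Finally the mappable genome — the union of bins with data in the
difference track — is partitioned into the four sections GSRs/LADs,
GSRs/iLADs, non-GSRs/LADs, non-GSRs/iLADs.

## LAD calling and switching

The DamID LAD caller is a transparent smoothed-threshold segmentation:
moving average (default 120 kb — the emulated study shows smoothed tracks
without stating the window, so it is pinned here and exposed), bins
strictly above 0 on the smoothed log2 ratio, merge gaps under 40 kb, keep
domains of at least 100 kb. Switching between conditions is bp-exact set
algebra (stable-LAD = a∩b, loss = a∖b, gain = b∖a, stable-iLAD =
complement), and expression association assigns genes by TSS
(strand-aware: the annotated end coordinate for minus-strand genes) and
uses two-sided Wilcoxon rank-sum tests, with fully tied comparisons
reported as p = 1.

## Hi-C statistics

Expected counts are per-chromosome means along each diagonal; O/E divides
by them, and O/E of an O/E matrix is itself (a tested idempotence).
Compartment PC1 is computed per chromosome as the leading eigenvector of
the Pearson correlation matrix of O/E columns, **scaled by the square root
of the leading eigenvalue**. The scaling choice is deliberate: a unit
eigenvector has the same norm at any compartment contrast, so
between-condition PC1 *differences* would carry no amplitude information;
the eigenvalue-scaled form grows with compartment segregation, making
ΔPC1 a meaningful promoter feature. The sign is oriented per chromosome so
gene density is higher on the positive (A) side, the standard resolution
of eigenvector sign ambiguity.

All pairwise compartment statistics are cis-only and exclude pairs closer
than `min_sep = 2` bins, where self-ligation artifacts dominate O/E.
Compartmentalization strength is computed per chromosome — strong A = top
20% of bins by PC1, strong B = bottom 20%, ties broken by bin index for
determinism — as median(AA ∪ BB) / median(AB), and reported as a
distribution across chromosomes. Whether the original analysis pooled
pairs genome-wide before the median is not stated; per-chromosome values
match the across-chromosome box-plot presentation and are what the
pipeline reports. Saddle plots rank bins genome-wide by PC1 into
equal-size quantiles and average O/E per quantile pair; the pipeline
computes them at 240 kb (counts summed, PC1 bp-averaged), the closest
multiple of the 40-kb matrix resolution to the classic 250-kb choice.
Interaction scores are per-bin: CS = (mean O/E with same-section bins) /
(mean O/E with all bins) on the same chromosome, masked where a section
has fewer than two bins.

TAD calling itself is out of scope; boundary *strength* comparisons use
the insulation square: the mean count in the window crossing the diagonal,
log2-normalized to the chromosome mean. Boundaries are local insulation
minima, their strength the depth below the nearest flanking maxima (mean
of the two sides), and they are classified within-A / within-B / A–B by
the flanking compartment labels.

## Gene-centric integration

Genes pass an expression filter (baseMean ≥ 10.30; the boundary value is
kept because the published rule removes "less than"). Promoter features
are means over a TSS-centered 5-kb window (± 2.5 kb — the description
fixes the window size but not its anchoring, so centering is pinned and
configurable): log2 ratios (pseudocount 1) for coverage assays (ChIP,
ATAC), differences for signed scores (PC1, DamID). Rows with any missing
feature are dropped with a recorded count, since K-means needs complete
rows.

Columns are z-scored before clustering — the features mix log2 ratios and
differences with different spreads, and without standardization the
clustering would be dominated by whichever unit happens to be widest.
K-means uses Lloyd's algorithm with squared-Euclidean distance, 20 seeded
restarts and a fixed default seed, then relabels clusters in canonical
order (descending mean ΔPC1) so "cluster 1" means the same thing across
runs. Per-cluster expression shifts are two-sided rank-sum tests against
all other clustered genes; section composition assigns each gene to the
section containing its TSS.

## The synthetic generator

`simulate_multiomics()` plants a ground truth with the study's qualitative
architecture: alternating A/B blocks (2 Mb); LADs covering 80% of B and
sized so that the A share of LAD bp is 20% (which makes total LAD bp equal
to |B|, about half the genome); GSRs covering 60% of each A block plus a
10% minority of each B block (≈ 35% of the genome, mostly iLAD/A — the
planted analogue of the reported GSR geography); H3K9me2 at a higher base
level in B, with the treated condition erased by δ = 1.0 inside GSRs under
per-bin Gaussian noise σ = 0.3 (δ/σ > 3); Hi-C expected counts with
power-law decay times κ^±1 for same/cross-compartment pairs (κ = 1.5
control, 1.7 treated — chosen once to mirror the direction and rough size
of the reported strength increase), log-normal multiplicative noise,
Poisson sampling, and a small masked-bin fraction; DamID at +1/−1 with
full lamina loss over GSR∩LAD and a mild (−0.3) detachment over GSR∩iLAD
in the treated condition; and genes placed with a 3:1 A:B density ratio
(gene-rich A compartments are what powers the PC1 orientation rule), with
up-regulation concentrated in GSRs and promoter ATAC doubled at
up-regulated genes. All randomness flows from one seed with fixed
per-component offsets, so identical configs are byte-identical.

What the generator does **not** emulate: read-level noise and mappability
structure, replicate variability beyond i.i.d. noise, fragment-level Hi-C
artifacts, copy-number and GC effects, partial (quantitative) H3K9me2
loss, and compartment switching (planted A/B labels are fixed across
conditions). Passing recovery tests therefore demonstrates the estimators'
correctness and calibration under the planted model, not their robustness
to every artifact of real sequencing data.

## Problem sizes and numerical conventions

The test suite and the acceptance analysis run on desk-scale genomes
chosen so the whole suite completes in minutes on one CPU: 2 × 20 Mb
(40,000 ChIP bins, 500 Hi-C bins per chromosome) for the end-to-end
analysis, 2 × 10^4 bins for null calibration of the caller, and ≤ 200-bin
matrices for the brute-force oracle checks (agreement to 1e−9). Other
fixed conventions: strict `>` at segmentation thresholds (bins exactly at
a threshold are excluded); quantile ties broken by position; symmetric
matrices validated to 1e−9 relative tolerance; division-free guards for
degenerate medians (an error rather than an infinite strength).

## Known limitations

The t-statistic construction and the DamID smoothing window are pinned
choices where the emulated analysis is underspecified; both are exposed as
parameters for sensitivity analysis. The mirrored null assumes the
negative tail is signal-free — a treatment that *gains* H3K9me2 somewhere
would inflate the null and make the caller conservative. Balancing is a
plain iterative row/column scaling, adequate for the simulated matrices
but not a research-grade normalization. Trans-chromosomal contacts,
subcompartments and loop-level structure are out of scope.
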