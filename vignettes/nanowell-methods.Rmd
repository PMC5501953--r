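---
title: "Methods: simulating and analysing nanowell single-cell RNA-seq"
author: "nanowell package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing nanowell single-cell RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanowell)
library(data.table)
```

## The system being modelled

A nanowell microchip carries 5184 reaction chambers (150 nl each) in a
72 × 72 grid. Every well is preprinted with an oligo-dT primer, an
11-base well barcode identifying the well (hence the cell), and a
10-base unique molecular identifier (UMI) marking the individual mRNA
molecule. Cells are dispensed by limiting dilution, so the number of
cells landing in a well is Poisson: at a mean of λ = 1 cell/well,
a fraction $e^{-1} \approx 36.8\%$ of wells hold exactly one cell.
Two-channel fluorescence imaging (Hoechst stains all cells, propidium
iodide only dead ones) identifies wells holding exactly one live cell;
only those wells receive reverse-transcription reagent. Sequencing
produces read pairs in which read 1 (25 bp) is barcode + UMI (+ 4
ignored bases) and read 2 (50 bp) is cDNA.

The package implements the complete computational stack around this
design — a ground-truth simulator, image-based well selection, barcode
demultiplexing, UMI-cluster transcript counting, QC/normalization,
species-mixing (barnyard) analysis, expression clustering, and
dispenser checkerboard QC — so that every analysis step can be
validated against known truth.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the rest of the package is validated under.

**Chip and dispense.** `chip_layout()` builds the 72 × 72 grid with
per-well 11-mers generated by rejection sampling to a minimum pairwise
Hamming distance of 3. That separation is what justifies *perfect-match*
demultiplexing: one sequencing error can never turn one valid barcode
into another, so unmatched barcodes are dropped, not rescued.
`simulate_dispense()` draws i.i.d. Poisson(λ) cells per well (default
λ = 1, the practical operating point) with each cell independently
viable with probability `live_fraction` (default 0.9, a typical
healthy-culture viability).

**Expression.** `simulate_expression()` draws counts from a negative
binomial (default dispersion 0.25, mid-range for UMI counts) around a
gamma-shaped baseline profile. Cell types are defined by
`markers_per_type` marker genes elevated `fold_change`-fold in their
own type. Marker genes share a common baseline so that comparing
marker sets on the raw expression scale is meaningful — matching real
cell-type markers (islet hormones, hemoglobins), which are solidly
expressed. Mitochondrial genes carry an `mt-` prefix and are scaled to
a 6% expected share of each cell's transcripts, the level typical of
healthy cells.

**Reads.** `emit_reads()` assigns every true molecule a UMI uniform
over the $4^{10}$ 10-mers *with replacement*: UMI collisions are
possible and deliberately observable, as in a real library. PCR
duplication is 1 + Poisson(mean − 1) reads per molecule (the
distribution of reads per UMI is a modelling choice; the shifted
Poisson guarantees every molecule is sequenced at least once).
Substitution errors apply per base to barcode, UMI and cDNA; chimeric
reads re-attach a barcode+UMI to a random gene's cDNA; ambient reads
come from the pooled expression profile with fresh UMIs. Reads shorter
than the transcript are filled with poly-A, mirroring oligo-dT priming.
Every read keeps a provenance record, and output is byte-reproducible
given a seed.

**Images.** `render_well_images()` tiles the chip into fields of 6 × 6
wells (a 72 × 72 chip → 144 fields per channel, 288 images) and draws
each cell as a Gaussian blob (σ = 2 px in a 24 px well) with background
noise at amplitude/SNR. Cells are placed on four jittered quadrant
slots per well rather than uniformly: cells are rigid bodies that
cannot overlap, and a placement model that lets two cells coincide
would make even a perfect detector unable to separate them. Beyond
four cells per well, cells stack on occupied slots, as piled-up cells
do. This is the main idealization of the image model — no optical PSF,
no debris, no intensity gradients — so image tests validate the
detector's logic, not its robustness to microscope artifacts.

**Barnyard.** `simulate_barnyard()` emulates a one-to-one two-species
mixture: each well is a doublet with probability `doublet_rate`, the
second cell's species drawn uniformly, so about half of doublets are
cross-species (the observable kind). Contamination (`impurity`,
defaults 3%/6%) is drawn per *well*, not per cell: ambient RNA scales
with well volume, so a doublet well does not carry double
contamination. That detail matters — per-cell contamination at doublet
depth would sit above the classification cutoffs and inflate the
apparent multiplet rate.

**Checkerboard.** `simulate_checkerboard()` lays out the standard QC
chip (2520 no-template wells on one half; 1024 lambda-DNA positives and
1496 no-template test wells alternating on the other; 144 wells left
for fiducials). Misaligned dispensing contaminates test wells with
positive mix (positive-like melt temperature); background spurious
signal (off-target products, Tm ≈ 78 °C vs ≈ 85 °C) hits test and NTC
wells equally — which is exactly the error the Test-minus-NTC
difference estimator removes.

## Well selection from images

Detection follows scale-space blob detection: a scale-normalized
Laplacian-of-Gaussian response (sign-fixed so bright blobs peak
positive), thresholding, connected components, then size and shape
classification. The discrete kernel is mean-subtracted so a constant
image yields an exactly zero response. The auto threshold is
median + k·MAD of the response (k = 5 by default) with a small floor
relative to the response range so that exactly noiseless images (MAD
= 0) threshold above FFT ripple; all terms scale with the image, making
selection invariant to affine intensity rescaling. Eccentricity comes
from the second central moments of each component. A well is selected
iff it has exactly one kept channel-1 object and no channel-2 object;
wells with a bright object that fails the size/shape bounds (debris)
are excluded. On noiseless rendered chips the selection equals the
truth's single-live-cell wells exactly, and at SNR 10 recall stays
above 99% (verified in the test suite at a 24 × 24 chip; the full
72 × 72 chip costs only seconds more but adds nothing statistically).

## Demultiplexing and transcript counting

Demultiplexing requires a perfect match of read-1 bases 1–11 against
the barcode map; bases 12–21 are the UMI; bases 22–25 are ignored.
Reads are conserved: assigned + unassigned + too-short = input pairs.

Counting proceeds per (cell, gene): identical UMIs collapse with
summed read counts; UMIs within Hamming distance 1 (configurable) are
merged into clusters by *connected components* — the minimal reading
of "clustering with 1 mismatch"; directional schemes exist but are out
of scope. Components are computed by a union-find in C++ and verified
in the tests against an independent brute-force adjacency + graph
oracle. A cluster's read support sums all member reads, so two 1-read
UMIs at distance 1 form a support-2 cluster that survives the default
`min_reads_per_umi = 2` singleton filter — the interpretive reading of
"clusters represented by at least two reads". The transcript count is
the number of surviving clusters.

Two monotonicity caveats discovered while testing, both consequences
of that support rule rather than bugs: counts are guaranteed
non-increasing in the mismatch radius only at `min_reads = 1` (merging
can only reduce the number of clusters); at `min_reads = 2` the
singleton-rescue effect can locally raise counts when the radius
widens. Similarly the downsampling curve is superlinear at very low
depth under `min_reads = 2` (surviving a duplicate pair scales like
the square of the sampling fraction) and saturates sublinearly near
full depth.

Gene assignment is by interval overlap against a single-interval,
non-overlapping gene model (GRanges/`findOverlaps`; 1-based closed
coordinates throughout, the native R convention): a read maps to a
gene iff it overlaps exactly one gene under the strand policy
(default sense). Reads overlapping two genes are ambiguous and
unassigned; only uniquely mapping reads (NH = 1) are counted; UMIs
containing N are excluded.

## QC, normalization, saturation

Per-cell QC reports total reads, alignment rate (uniquely mapped /
total demultiplexed), mapped reads, total transcripts, % mitochondrial
transcripts (0 with a warning for empty cells), and detected genes.
The QC filter is a data-set-specific minimum transcript count chosen
by inspection; automated cutoff selection is out of scope.

Normalization divides each cell by total(cell)/median(totals), so all
normalized totals equal the median raw total and re-normalization is
the identity; chips are normalized jointly in one pass. Zero-total
cells have an undefined factor and are excluded with a warning.

The saturation curve re-runs the entire counting chain on a per-cell
subsample of gene-aligned reads — a fraction d/D without replacement
(hypergeometric; Bernoulli thinning available), where sampling
precedes UMI collapsing so duplicates thin realistically. The
singleton filter is re-applied after sampling.

## Barnyard analysis

Reads mapped independently to both genomes are discarded when both hits
have ≤ 3 mismatches (ambiguous); otherwise a read belongs to a genome
where it maps within the budget. Per-cell cutoffs are median + 5·IQR
of the minority-species transcript count among cells dominated by the
other species; quantiles use linear interpolation (R type 7) — the
rule is sensitive to this choice, so it is pinned and documented.
Classification is by strict exceedance; exceeding both cutoffs is a
cross-species multiplet; equality classifies as neither. The overall
multiplet rate doubles the observed cross-species percentage, valid
for a one-to-one mixture where half of multiplets are same-species and
invisible. Purity is the median own-species transcript fraction over
classified cells, by default over all classified cells including
pure-sample controls (restrictable to mixture wells).

## Clustering

Variable genes rank by variance of log2(x+1) normalized counts (ties
broken lexicographically; presets 500 for PCA, 100 for clustering and
heatmaps), computed on QC-passing cells. The clustering matrix is
log2(x+1)-transformed and gene-centered. PCA uses the exact SVD with a
deterministic sign convention (largest-magnitude loading positive).
Cell-cell distance is 1 − Pearson correlation with average-linkage
agglomeration; constant-profile cells have undefined correlation and
are removed with a warning; the dendrogram cut k is user-set (4 for
islet data). Clusters are labelled by the marker set with the highest
mean normalized expression in the cluster; exact ties give
"unresolved".

## Dispenser QC

Signal is a recorded Ct at or below `max_ct` (default 35; the real
instrument threshold is not published, so it is exposed as
configuration). The melt filter keeps Test/NTC signal only when its Tm
falls within mean ± 3 sample SD (n − 1) of the Positive wells' Tm.
Filtered wells leave both numerator and denominator. Misalignment % =
% Test wells with signal − % NTC wells with signal; negative values
are reported as computed.

## Problem sizes and numerical choices

The test-suite and acceptance workloads were sized for a desk-scale
run: end-to-end recovery uses 50 cells × 200 genes at ~200k reads
(100 molecules/cell, ~40 reads per molecule — the realistic
duplication regime); barnyard and checkerboard recovery average 50
simulated chips; clustering recovery uses 468 cells at the islet
abundances 38/26/22/14% with fold-change 8. Oracle equivalence for UMI
clustering runs 1000 random instances of up to 200 UMIs with lengths
4–10 and radii 0–2. UMI collisions at the end-to-end scale are
expected ~0.04 merged pairs per run; the identity test therefore
checks the pipeline against the realized molecules (exact regardless
of collisions) as well as against the nominal truth.

Degenerate inputs are handled explicitly: λ ≤ 0 is rejected; empty
FASTQ yields an all-zero report; empty wells give noise-only images
and an empty truth table; cells with zero transcripts or constant
profiles are excluded with warnings at the step where the statistic
becomes undefined; mixed-length or non-ACGT UMIs are hard errors.

## Known limitations

The simulator has no quality-score model, no indels, no isoforms, no
optical PSF, no debris, and uniform per-base error rates; passing its
tests shows the analysis logic is correct under the stated generative
model, not that the pipeline is robust to every real-data artifact.
Real-data anchors that require the original sequencing data (pairwise
cell correlation medians, absolute genes-at-depth, the published
classification cutoffs) are covered qualitatively by simulation
properties, not reproduced numerically.
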