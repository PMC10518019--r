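---
title: "scMST: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scMST: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science and the engineering choices behind the
package: what each stage of the single-cell Multiplex Spatial
Transcriptomics (scMST) pipeline computes, what the synthetic phantom does
and does not emulate, and why the defaults are what they are. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The measurement scMST makes

scMST decodes per-cell transcript counts from serial rounds of
single-molecule FISH on a tissue cryosection. Five genes are imaged per
hybridization round on a six-channel microscope (the sixth channel carries
the nuclear stain used for registration); after each round the signal is
enzymatically stripped and five new genes are probed. A 30-gene panel
therefore takes six rounds, followed by an immunostained membrane round
used for 3D cell segmentation, and optionally a repeat of the first probe
set as an RNA-integrity control. Each section is acquired as three fields
of view (FOVs) that are analyzed *unstitched*: counting happens per FOV,
and a display mosaic is assembled only after the analysis is finished, so
stitching artifacts can never move a transcript between cells.

Each mRNA appears as a diffraction-limited "dot". The pipeline's task is:
find the dots, decide which are real, assign them to cells, and normalize,
cluster and select cells by their expression profile.

## Phantom: synthetic acquisitions with ground truth

`phantom_config()` + `simulate_fov()` generate complete multi-round
acquisitions with known truth at every level (cell labels, per-cell counts,
every rendered dot with its class and owner, true round shifts). All
downstream guarantees in the test suite are measured against this truth;
no external data is needed.

What the phantom emulates, and the defaults:

* **Tissue**: a smooth band (an idealized ectoderm cross-section) filled
  with a nearest-seed tessellation in anisotropy-scaled coordinates —
  connected, convex-ish cells of realistic packing. Default
  12 × 192 × 192 voxels at (0.5, 0.206, 0.206) µm and ~50 cells per FOV:
  desk scale, chosen so the full two-embryo, six-FOV pipeline runs in
  about two minutes on one CPU. Note the miniaturization: real cells at
  this pixel size are ~100 px across, the phantom's are ~18 px.
* **Expression**: four subpopulations (two committed domain programmes, a
  transitioning stem-cell group co-expressing pluripotency genes with
  domain markers, and an undecided group dominated by pluripotency
  factors), mixing 0.30/0.30/0.25/0.15, with Poisson counts
  (negative binomial available via `count_model = "nb"`). Marker means of
  4/3/4 per gene keep the per-channel dot density low enough that two
  transcripts rarely land within one point-spread function of each other —
  at the phantom's miniaturized cell size a higher density would fuse
  dots at a rate real acquisitions do not show.
* **Optics**: dots are Gaussian blobs with PSF sigma (0.7, 1.0, 1.0)
  voxels, consistent with a 63×/NA 1.27 objective sampled at 0.206 µm and
  0.5 µm z steps. Amplitude classes: true signal N(250, 20), non-specific
  binding N(60, 12), bright artifacts N(1000, 100), over a camera
  background of 100 with read noise sd 3. Per-channel shading is a smooth
  multiplicative field (±25%); each round carries an integer stage shift
  (up to ±1 z, ±8 lateral). The stage shift moves the *tissue signal*;
  background, shading and noise are full-frame optics properties — this
  matters for flat-field estimation, which would otherwise see bogus
  zero-filled margins.
* **Not emulated**: camera noise calibration (no Poisson shot noise or
  gain model), stripping chemistry, autofluorescence, optical sectioning
  artifacts, subvoxel dot positions. Passing tests show the pipeline's
  logic is correct under a faithful geometric/intensity model; they do not
  certify performance on any particular microscope.

## Pre-processing and registration

The fixed per-channel order is flat-field correction, then a 3 × 3 × 3
3D median filter, then detection. `estimate_flatfield()` is a robust
surrogate for retrospective shading correction: the per-pixel median
across z (pooled over a channel's dot-bearing rounds) captures the smooth
multiplicative background, which is then heavily smoothed (sigma 20 px)
and normalized to mean exactly 1. The membrane round is excluded from the
pooled estimate of channels it shares with gene probes, because its
sheet-like structure would bias the baseline.

Rounds are aligned on the nuclei channel by `register_rounds()`: the
integer shift maximizing cross-correlation (FFT on zero-meaned,
zero-padded volumes, ±(2, 8, 8) search radius by default), with near-ties
resolved toward the smaller absolute shift. Sub-voxel registration is out
of scope; the acquisition protocol (sealed chambers) keeps real shifts
small and integer alignment was sufficient in the original workflow.

## Spot calling and K-means triage

Detection (`detect_dots()`) is deliberately high-recall: local maxima of a
difference-of-Gaussians band-pass at the PSF scale, with minimal
suppression distance (1 lateral voxel by default). The intensity floor is
the larger of a response quantile and a robust noise ceiling
(`median + 6 × MAD` of the response). The MAD term is the load-bearing
one: a pure quantile floor moves with blob density, and if it drops to the
noise level the detector emits hundreds of camera-noise maxima that form a
fourth population and destabilize a three-class triage. Detected maxima
are then refined (`refine_dots()`) to the brightest voxel of the
*unfiltered* volume within ±1 voxel, undoing the ~1-plane z displacement
the median filter can introduce.

Per-dot features are the mean and the population standard deviation of the
voxel intensities over a 1-sigma ellipsoid support, computed on the
corrected but **unfiltered** volume. This choice is deliberate: after a
3 × 3 × 3 median the blob profile is flattened and the "variability"
feature degenerates to read noise, losing the class structure the triage
relies on.

`kmeans_triage()` clusters dots on standardized (mean intensity,
variability) with a seeded, 10-restart K-means and keeps the "middle
band": the lowest-mean cluster is rejected as non-specific binding; any
cluster above the 0.995 intensity quantile, or with the maximal
variability centroid exceeding twice the median centroid variability, is
rejected as an artifact; everything else is kept. `select_k()` offers a
silhouette default with the elbow curve as a diagnostic, but the cluster
count is ultimately a config input (`triage_k`, default 3) — automated
criteria do not always reflect dataset complexity, and the original
workflow relied on inspection for exactly this reason. Dots are pooled per
gene across an embryo's FOVs before triage so each K-means sees a few
hundred dots.

The repeat of round 1 feeds `recovery_rate()`: kept-dot yield per gene in
the repeat relative to the original round, with an overall PASS/FAIL at
70%. The phantom's repeat round re-probes the same molecules with a
retention of 0.8, placing a healthy run inside the 70–90% band.

## Segmentation and counting

`segment_cells()` is a classical seeded 3D watershed standing in the role
of the original machine-learning segmenter: seeds are local maxima of the
smoothed nuclei volume (minimum separation about one cell radius,
anisotropy-aware), the elevation surface is the smoothed membrane
composite (the two membrane channels summed), and the flood is restricted
to a tissue mask built as membrane walls ∪ nuclei (each thresholded a
small fraction above background) with laterally enclosed cytoplasm filled
in (complement components that never reach a y/x border are interior
holes). The hole-filling matters because cytoplasm carries no stain at
all; intensity thresholds alone cannot claim it. Aligned membrane volumes
use edge-replicated fill for the margins the stage shift vacated, so the
elevation surface has no artificial zero trenches. Components under
`min_cell_volume` (150 voxels) are dropped; border-touching cells are
removed by default (`drop_edge_cells()`), since a cell cut by the FOV edge
carries partial counts and FOVs are never merged.

Kept dots are mapped into the reference frame by subtracting their round's
estimated shift, rounded to the nearest voxel, and assigned the label at
that voxel (`assign_dots()`); background dots are dropped. The count
matrix conserves exactly: its total equals the number of kept, assigned
dots, and zero-count cells are retained and flagged.

## Normalization, clustering, selection

Normalization is two-stage z-scoring on raw integer counts (a `log1p`
option exists): per gene within each embryo (its FOVs pooled), then per
gene across the pooled embryos of a stage. Sample standard deviations
(n − 1) are used; a gene with zero spread in a group scores 0 for that
group, which keeps cells rather than dropping genes. Pooled columns are
mean 0, sd 1 to 1e−9.

Cross-stage comparison (`zscore_cross_stage()`) pools the cells of all
stages and standardizes each gene **once** over the pooled raw counts.
It does not run the per-embryo pass first: every embryo belongs to one
stage, so centering each embryo would subtract away precisely the
between-stage level differences this normalization exists to expose.

Cells are clustered by `hcluster()`: cosine distance
(`1 − u·v/(|u||v|)`; a zero profile against a non-zero one is assigned
distance 1, two zero profiles 0) with average linkage, cut at a
config-chosen k — cluster counts were chosen by heatmap inspection in the
original workflow, so no automatic k is imposed. Genes are clustered the
same way to give the two-dimensional heatmap leaf order.

`select_coexpressing()` implements the co-expression rule: a cell is
selected when its z-score is strictly above 0 for *every* gene of the set
(per-gene filters intersected over cell ids). Strict inequality follows
the "z-score > 0" rule; adding genes can only shrink a selection.

## Back-mapping and stitching

`backmap()` paints each analyzed cell's voxels with its group's
pseudo-color (unanalyzed cells gray, background black), projected over z
by per-pixel label majority. `stitch()` pastes FOV images at acquisition
offsets with a last-wins (or error-on-overlap) policy. Both are pure
views: they never feed back into counts, clusters or selections.

## Numerical and reproducibility choices

* Every stochastic step derives its seed from the config seeds via a
  deterministic mixer; K-means uses 10 restarts under a fixed seed.
  Re-running a pipeline with the same config reproduces the tabular
  artifacts byte for byte.
* Registration ties (within 1e−8 of the correlation maximum) resolve to
  the smallest `(|z|, |y|, |x|)` lexicographically.
* Median-filter borders replicate edges; Gaussian smoothing likewise.
* The kept mask of the triage is invariant to dot ordering (dots are
  sorted internally before K-means) and clusters are relabelled by
  increasing mean intensity so cluster ids are stable.
* Problem sizes: unit tests run on 8 × 96 × 96 phantoms with ~12 cells;
  the acceptance checks run the full default acquisition (2 embryos ×
  3 FOVs × 12 × 192 × 192, 30 genes, 8 rounds) once, plus a second run
  for the byte-identity check — the package's chosen desk scale.

## Known limitations

* Integer-voxel registration and dot placement; no subvoxel localization.
* The watershed replaces the original machine-learning segmenter; it
  inherits the usual failure mode of merging cells whose nuclei fall
  within one seed-suppression radius.
* Triage assumes at least two intensity populations; a channel with only
  true signal and `k = 2` will sacrifice its dimmest dots (roughly half),
  which is why `triage_k` should match the number of populations actually
  present.
* Counts lost to dot fusion (two transcripts within one PSF) are
  irrecoverable by design; at the phantom's default density this is a
  few percent, and it shrinks with cell size in real data.
* Cells spanning adjacent FOVs are not merged; edge-cell dropping is the
  mitigation.
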