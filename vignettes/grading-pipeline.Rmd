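---
title: "From slide to pathology report: the PathPlexus methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From slide to pathology report: the PathPlexus methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PathPlexus)
```

PathPlexus implements, at desk scale, the computational stack of an AI
system that emulates a genitourinary pathologist's evaluation of H&E
prostate slides: tiling and quality control, patch classification with a
compact multigraph CNN family, threshold calibration, Gleason/ISUP
grading, tumor-volume planimetry, slide sorting, capsule-proximity
zoning, and the agreement statistics used to evaluate all of it. This
vignette explains the models and the numerical choices; it states no
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The patch as the atomic unit

Whole-slide images are gigapixel rasters. All analysis happens on
512 × 512-pixel patches at 1 µm/pixel (≈10× objective; 0.5 µm/pixel
≈ 20×). `tileSlide()` resamples a slide to the working resolution
(bilinear interpolation — chosen because EBImage provides no
area-average filter and the down-sampling factors here are ≤ 2), lays a
row-major grid of half-open boxes from the top-left corner, and keeps
patches whose tissue fraction against the Otsu foreground mask reaches
5% (the published pipeline excludes "white areas outside the background
tissues" without quantifying the cut; 5% retains any patch with more
than trivial tissue). With an overlap fraction of 0.5 the stride halves,
which is the biopsy-core setting.

`otsuForeground()` delegates the threshold to `EBImage::otsu` on the
256-bin grayscale histogram; the suite checks it against an exhaustive
between-class-variance search. Because the histogram of a
tissue-on-white slide has an empty gap between its modes, any threshold
inside the gap maximises the criterion — the tests therefore compare
the induced foreground **split**, not the numeric threshold.

## Patch quality control

Blur is scored by the variance of the 3 × 3 Laplacian
(`[[0,1,0],[1,-4,1],[0,1,0]]`) of the grayscale patch over interior
pixels — the one-pixel border is excluded so that no padding convention
enters the score. The published reference range for acceptable patches
is 112–124. A patch outside the range receives one unsharp-mask pass
(amount 1, Gaussian σ = 1; the source pipeline does not name its
operator) and is excluded if it still fails.

Illuminance is the mean Rec. 709 relative luminance
(0.2126 R + 0.7152 G + 0.0722 B); the published reference range
144.4–165.3 only makes sense on the 0–255 scale, which fixes the
otherwise unstated convention. Out-of-range patches are corrected by
CLAHE (clip limit 2, 8 × 8 tiles, on the CIELAB lightness channel)
followed by a reference-free Macenko stain normalization: optical
densities `OD = -log((I+1)/256)`, stained pixels are those with all
channels above β = 0.15, the stain plane is the span of the top two
eigenvectors of the *uncentered* OD second moment (centring would let
projection angles wrap around ±π and break the percentile construction),
stain vectors sit at the 1st/99th percentile angles, and concentrations
are rescaled so their 99th percentiles hit fixed canonical H&E targets.
"Reference-free" means reconstruction uses the canonical H&E stain
matrix rather than a reference image. Hematoxylin is identified as the
vector with the larger red-channel OD. Degenerate inputs are handled
explicitly: a near-white patch (< 1% stained pixels) and a gray patch
(collinear stain vectors) are returned unchanged with a flag. The
Macenko stage is idempotent within ~2 intensity units on a two-stain
patch; CLAHE re-equalises on every call, so only the normalization
stage carries that guarantee.

## Labeling patches from annotation masks

Each slide has an integer-coded annotation mask on the same grid. A
patch is positive for a finding when its positive-area fraction reaches
the published rule: prostate cancer strictly above 1%; Gleason patterns
3–5 and HGPIN at 10%; ductal morphology at 40% with at most 60% white
background (ductal glands are lumen-rich; "white" is all RGB channels
≥ 220, a configurable stand-in for the source's manual lumen exclusion);
cribriform at 50%; nerves and vessels at 5% (small structures);
inflammation at 3%; 5% for anything else. Patches may be positive for
several findings at this stage — exclusivity is resolved only when
grading tallies are formed.

## The PlexusNet multigraph family

The classifier family is a directed acyclic multigraph. Its complexity
is governed by the **depth** (levels, minimum 2), the **width**
(end-to-end paths), the number of **weighted junctions** (cross edges
between two paths — 1 × 1 convolutions added into the target path's
next level), and **transitory short paths** that branch from the stem
and channel-concatenate into the root path at a seeded-random level.
Blocks (VGG, inception, residual, soft attention; one type per model)
are connected by 2 × 2 average pooling that halves the spatial
dimensions, and all end-to-end path outputs are concatenated before
global pooling and the fully connected head.

Three structural details are open in the published description and are
fixed here as package design choices:

* **Channel schedule.** Channels grow per level by
  `initial_filter_factor × γ` with round-half-up (γ = 0.5 by default,
  the DenseNet-style compression the block figures reference). A factor
  of 2 therefore keeps the width constant, which reproduces the order of
  magnitude of the published per-model capacities; exact capacities are
  not reproducible because they vary with the seeded-random short-path
  depth, and only the ensemble bound (far below one ResNet-18, ~11 M
  parameters) is asserted.
* **Block internals.** Inception blocks use 1/3/5-pixel branches of
  `round_half_up(γ·C)` channels each with a 1 × 1 compression to C;
  residual blocks are 1–3–1 bottlenecks with a projection skip; soft
  attention multiplies the feature map by a sigmoid 1 × 1 attention map.
  Convolutions carry biases.
* **Short paths and junctions.** A short path of seeded-random depth
  *d* inserts at a seeded-random level ℓ (d < ℓ), pooling as needed so
  resolutions match; a junction connects a random ordered path pair at a
  random level. Both are recorded in the graph metadata, so a build is
  bit-reproducible from its seed.

The input layer applies the trainable interpolation
$\hat X = -2 e^{-2X^2}\,[\cos(90\omega_1) + X \sin(90\omega_2)]$
followed by min–max scaling onto $[-1, 1]$. The angle $90\omega$ is
read in **degrees**: the factor 90 is natural only there, with
$\omega \in [-1,1]$ sweeping a quarter period of smooth monotone
interpolation. A constant batch cannot be min–max scaled and is mapped
to zeros with a warning rather than NaN. During training the rescale
min/max are treated as constants (stop-gradient); $\omega_1, \omega_2$
receive gradients through the interpolation itself.

Transformer blocks (used by three catalogue models) follow the
published reshape contract — `(B, H, W, C) → (B, H·W, C)`, standard
encoder blocks, reshape back before global pooling. They are
implemented for the forward pass and parameter counting; the toy
trainer rejects transformer specs, since the package's training scope
is deliberately a plain cross-entropy trainer for synthetic textures,
not the published large-scale schemes.

The whole engine — im2col convolution, batch/layer normalisation,
pooling, attention, backpropagation, Adam — is written in base R
linear algebra. The test suite validates every block type's gradients
against central finite differences at relative errors around 1e-10.

`configs/table3.yaml` transcribes the 17 published model
configurations (prostate cancer, three GP3/six GP4/two GP5 ensemble
members, ductal, cribriform, HGPIN, vessel, nerve, inflammation).
Ensembles average per-model positive-class scores with equal weights.

## Threshold calibration

Patch-level operating points come from a brute-force search: thresholds
0.10–0.99 in steps of 0.01, each scored by the median Cohen kappa over
bootstrap resamples (10,000 in the published setting; the median
mitigates outlier resamples). The classification rule is
`score ≥ threshold`, matching the published "49% or above" prostate
cancer operating point. Package choices where the source is silent:
the grid ends at 0.99; ties break toward the lowest threshold
(favouring sensitivity); resamples in which kappa is undefined
(single-class draw) are skipped rather than scored zero, which keeps
the median meaningful at small n; one resample-index set drawn from the
seed is shared across the grid, making the trace comparable point to
point and the search deterministic. The shipped configuration also
carries the published operating points (PCa 0.49; GP3/GP4/GP5
0.35/0.65/0.93; ductal 0.90; cribriform 0.65; nerve 0.35; vessel 0.50;
inflammation 0.705; HGPIN 0.65).

## Gleason tallies and ISUP grading

`tallyCase()` counts tumor patches per Gleason pattern across a case's
slides. The default mode counts each patch once for the *highest*
pattern it passes, so proportions sum to one; an independent mode is
available. Proportions are tumor-relative (the ISUP percentages
describe tumor composition; TuVol% separately uses the tissue
denominator). Frequency ties break toward the higher pattern —
clinically conservative.

For prostatectomy specimens the second most common pattern becomes the
secondary pattern only if its tumor fraction reaches the threshold —
5% in the reporting guideline, 10% after correcting for the documented
human underestimation of tumor size by roughly half; below the
threshold the secondary repeats the primary and the second pattern is
recorded as tertiary. For biopsy cores the secondary is simply the
second most common pattern (the published sentence is ambiguous; the
second-most-frequent reading is the default and the
highest-remaining-pattern variant is a visible alternative through the
same function). Grade groups map as 3+3→1, 3+4→2, 4+3→3, sum 8→4,
sums 9–10→5, binarised into GG1–2 vs GG3–5. The suite verifies the
whole chain against an independent transcription of the verbal rules
over every tally composition with at most 60 patches, at both
thresholds.

## Tumor volume, sorting, capsule proximity

TuVol% is grid planimetry: each patch is one cell, and the
PCa-positive cell count is divided by the tissue cell count pooled over
the case. The acceptance comparison against pixel planimetry uses
grid-aligned synthetic masks, which isolates the planimetric
bookkeeping from the separate (documented) bias of the >1% labeling
rule on lesion-boundary patches.

A slide is sorted as cancer-positive when at least two patches reach
the 0.49 operating point; the published wording mixes "exceeded" and
"or above", harmonised here as `≥`. Case-level sorting metrics report
the clinically relevant quantity — how many patients have at least one
falsely sorted slide — alongside per-case error rates.

Zone 1, the capsule border zone, is the boundary band holding 10% of
the tissue area. It is extracted by iterated 3 × 3 diamond erosion;
the erosion count whose interior is *closest* to 90% of the area is
chosen (stopping at the first drop below the target can overshoot the
band by more than a percentage point at moderate resolutions — on a
radius-100 disk the first-drop rule yields an 11.6% band, the
closest-count rule 9.75%). Fragmented tissue is processed per connected
component. Capsule proximity is true when any cancer pixel lies in the
zone.

## Agreement statistics

Cohen kappa, quadratic-weighted kappa (which reduces exactly to Cohen
kappa for two categories), rank-based AUROC with tie correction, exact
Clopper–Pearson intervals from beta quantiles, Bayes-rule predictive
values at arbitrary prevalence, per-slide aggregation (mean per-slide
AUROC; median and range of per-slide kappa; single-class slides skipped
and counted), and percentile bootstrap intervals (100,000 replications
in the published setting, configurable down). The verbal agreement
bands are: <0 less than chance, 0.01–0.20 slight, 0.21–0.40 fair,
0.41–0.60 moderate, 0.61–0.80 substantial, 0.81–0.99 almost perfect.
The published table leaves exactly 0 and (0.99, 1] unassigned; the
package assigns 0 to the slight-band floor and values above 0.99 to
almost perfect. The chance-concordance helper returns the probability
that two independent uniform raters both select one designated group,
$(1/k)^2$ — 4% for five grade groups, 25% for two — with a simulation
mode that converges to the analytic value.

## What the synthetic data emulate — and what they do not

The generators produce tissue-on-white slides (textured ellipse on a
white background), compact disk lesions whose pixel areas are tuned by
bisection to requested fractions of the tissue area, band-limited-noise
textures whose classes differ in dominant spatial frequency but share
their mean intensity exactly (so a linear classifier on mean intensity
is at chance while a tiny CNN or a Laplacian-variance statistic
separates them), binormal score distributions with a chosen AUROC
($\mu = \sqrt2\,\Phi^{-1}(\mathrm{AUROC})$, logistic squashing
preserves ranks), and multi-slide cases whose truth tables (pattern
counts, TuVol%, grades under both thresholds, sorting and capsule
flags) are derived by running the labeling machinery on the generated
masks — so patch-quantization effects are part of the recorded truth.

The default case emulates the canonical threshold-flip composition:
four 1024-pixel whole-mount slides, 35% tumor, pattern mix 92/7/1
(GP3/GP4/GP5), labeled on a 32-pixel truth grid. At that grid the
GP4 patch fraction lands stably between 5% and 10%, so the case grades
GG2 under the 5% rule and GG1 under the 10% rule — the mechanism
behind the published threshold correction, demonstrable without any
clinical data.

Passing on these fixtures shows the machinery is correct; it does not
show clinical performance. Real H&E tissue has stain variability,
scanner differences, heterogeneous morphology and annotation noise that
procedural textures do not model, and the published accuracy and
concordance figures rest on trained weights and patient cohorts that
are out of scope here.

## Problem sizes and determinism

The test suite and acceptance script run everything at desk scale: the
full 512 × 512 forward pass once; toy training on 160 patches of
32 × 32 for 8 epochs (held-out AUROC reaches 1.0 within minutes on one
CPU); the grading sweep over all ≈39,700 tally compositions with ≤ 60
patches at both thresholds; 50-instance oracle equivalence for the
threshold search at 25 bootstrap resamples; 10⁶-draw concordance
simulations. Every stochastic component takes an explicit seed:
graph topology and weights from the architecture seed, training shuffles,
bootstrap draws, and all generators are bit-reproducible.

## Known limitations

* Training supports the convolutional block types, not transformer
  specs; published training schemes (contrastive, multitask) are out
  of scope by design.
* Published per-model parameter capacities are order-of-magnitude
  comparable but not exactly reproducible (seeded-random short paths;
  unpublished block internals).
* The pure-R engine is intended for correctness and desk-scale
  experiments, not throughput.
* Slide I/O covers PNG/TIFF rasters; pyramidal WSI container formats
  are not parsed.
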