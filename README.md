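# PathPlexus

Desk-scale digital pathology for prostate cancer grading, built around
the PlexusNet multigraph CNN family. The package is aimed at
computational-pathology researchers and methodologists who need the
*computational* half of an AI "digital twin" of a pathologist — slide
tiling and quality control, patch labeling, network construction,
threshold calibration, Gleason/ISUP grading, tumor-volume planimetry,
slide sorting, capsule-proximity zoning, and the agreement statistics
that evaluate all of it — runnable and testable on synthetic slides
without clinical data, trained weights or a GPU.

## What it computes

* **Tiling & QC** — Otsu foreground, 512 × 512 patches at 1 µm/px,
  variance-of-Laplacian blur scoring (reference range 112–124),
  Rec. 709 illuminance (144.4–165.3), unsharp sharpening, CLAHE +
  reference-free Macenko stain normalization.
* **PlexusNet** — directed acyclic multigraphs parameterised by depth,
  width (end-to-end paths), weighted junctions and transitory short
  paths, with VGG/inception/residual/soft-attention blocks, optional
  transformer blocks, and the trainable input interpolation
  `X̂ = −2e^(−2X²)[cos(90ω₁) + X·sin(90ω₂)]` followed by min–max
  scaling to [−1, 1]. Built graphs are seeded and bit-reproducible;
  the 17-model catalogue ships as `configs/table3.yaml`. A pure-R
  engine (im2col convolution, backprop, Adam) trains toy models on
  synthetic textures.
* **Calibration** — brute-force threshold search (0.10–0.99, step
  0.01) maximising the bootstrap-median Cohen kappa.
* **Grading** — per-pattern patch tallies; primary/secondary/tertiary
  assignment with the 5% secondary-pattern rule and its 10% corrected
  variant; ISUP grade groups (3+3→1, 3+4→2, 4+3→3, sum 8→4,
  sums 9–10→5) and GG1–2/GG3–5 binarisation.
* **Quantification** — grid-method TuVol%, the two-positive-patch
  slide-sorting rule at the 0.49 operating point, case-level sorting
  error rates, and the 10%-area capsule border zone.
* **Metrics** — AUROC, Cohen and quadratic-weighted kappa with the
  verbal agreement bands, Clopper–Pearson intervals, predictive values
  at prevalence, per-slide aggregation, bootstrap CIs, and the
  (1/k)² chance-concordance of two independent raters.
* **Synthetic data** — slides, masks, score distributions and whole
  cases with exact ground-truth tables, so every pipeline stage has an
  oracle.

## Worked example

Generate a four-slide prostatectomy case whose tumor is 92% Gleason
pattern 3, 7% pattern 4 and 1% pattern 5, then assemble its report:

```r
library(PathPlexus)

cs  <- generateCase(seed = 7)   # 4 slides, 35% tumor, GP mix 92/7/1
rep <- assembleCaseReport("RP-007", cs$labels,
         tissue_masks = lapply(cs$slides, `[[`, "tissue_mask"),
         cancer_masks = lapply(cs$slides, function(s) s$mask > 0))
print(rep)
#> CaseReport RP-007: 4 slides, TuVol 38.00%
#>   ISUP 2 (5% rule) / 1 (10% rule), patterns 3+3
patternCounts(cs$truth$tally)
#> gp3 gp4 gp5
#> 853  85  17
```

Of 955 tumor patches, 85 (8.9%) carry pattern 4: above the 5%
reporting threshold the case is Gleason 3+4 (ISUP grade group 2), but
under the corrected 10% threshold pattern 4 drops to tertiary and the
case is 3+3 (grade group 1) — the threshold-correction mechanism in
action. TuVol 38% is the PCa-positive share of the 2,624 tissue grid
cells pooled over the four slides.

Building and querying a published network configuration:

```r
spec  <- table3Specs(seed = 1)$pca     # inception, depth 7, width 2
graph <- buildArchitecture(spec)
countParameters(graph)                  # ~3e5 trainable scalars
scores <- predictGraph(graph, batch)    # (n, 2) softmax rows
```

A thin command-line front end over the same functions is included at
`inst/scripts/pathplexus-cli.R` (subcommands `fixtures`, `tile`, `qc`,
`label`, `train-toy`, `predict`, `calibrate`, `grade`, `volume`,
`sort`, `metrics`, `report`).

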