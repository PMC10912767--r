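Package: PathPlexus
Title: Desk-Scale Digital-Pathology Toolkit for Prostate Cancer Grading with
    PlexusNet Multigraph Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for whole-slide-image tiling and quality control,
    mask-based patch labeling, PlexusNet directed-acyclic-multigraph
    convolutional networks with a trainable input-interpolation layer,
    bootstrap-kappa decision-threshold calibration, Gleason pattern and ISUP
    grade-group aggregation for biopsy and prostatectomy specimens,
    grid-method tumor volume estimation, slide sorting, capsule-proximity
    zoning, and the agreement and accuracy statistics used to evaluate them.
    Synthetic slide, mask and score generators with known ground truth make
    the whole pipeline exercisable without external data or a GPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, Pathology, CellBasedAssays
Collate: 
    'PathPlexus-package.R'
    'AllClasses.R'
    'calibration.R'
    'configs.R'
    'grading.R'
    'interpolation.R'
    'labeling.R'
    'metrics.R'
    'nn-graph.R'
    'nn-layers.R'
    'nn-train.R'
    'preprocess.R'
    'quantification.R'
    'report.R'
    'stain.R'
    'synthetic.R'
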