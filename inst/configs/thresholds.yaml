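# Published per-finding operating points (patch-level decision thresholds
# on the [0, 1] confidence score; classification rule is score >= threshold)
# and mask-labeling rules (minimum positive area fraction per patch, plus a
# white-area ceiling where lumen-rich morphologies require one).
decision_thresholds:
  pca: 0.49
  gp3: 0.35
  gp4: 0.65
  gp5: 0.93
  ductal: 0.90
  cribriform: 0.65
  nerve: 0.35
  vessel: 0.50
  inflammation: 0.705
  hgpin: 0.65
labeling_rules:
  pca:          {min_positive_fraction: 0.01, strict: true}   # strictly more than 1%
  gp3:          {min_positive_fraction: 0.10}
  gp4:          {min_positive_fraction: 0.10}
  gp5:          {min_positive_fraction: 0.10}
  hgpin:        {min_positive_fraction: 0.10}
  ductal:       {min_positive_fraction: 0.40, max_white_fraction: 0.60}
  cribriform:   {min_positive_fraction: 0.50}
  nerve:        {min_positive_fraction: 0.05}
  vessel:       {min_positive_fraction: 0.05}
  inflammation: {min_positive_fraction: 0.03}
default_rule:   {min_positive_fraction: 0.05}
grading:
  secondary_min_fraction_reported: 0.05
  secondary_min_fraction_corrected: 0.10
slide_sorting:
  score_threshold: 0.49
  min_positive_patches: 2
qc:
  blur_range: [112, 124]
  illuminance_range: [144.4, 165.3]
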