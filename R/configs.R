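#' Load the packaged architecture catalogue
#'
#' Reads the 17 published PlexusNet model configurations shipped with the
#' package (one row per detection model: prostate cancer, Gleason patterns
#' 3-5, ductal morphology, cribriform pattern, HGPIN, vessels, nerves,
#' inflammatory infiltration) and returns them as
#' [ArchitectureSpec-class] objects. Because junction positions and
#' short-path depths are seeded-random, `seed` offsets the per-model seeds;
#' published parameter capacities therefore vary with the seed while the
#' ensemble stays far below the capacity of a single ResNet-18 (~11 M).
#'
#' @param seed base seed; model `i` is built with seed `seed + i`.
#' @param file YAML catalogue; defaults to the packaged `configs/table3.yaml`.
#' @return named list of [ArchitectureSpec-class] objects.
#' @examples
#' specs <- table3Specs(seed = 1)
#' length(specs)   # 17
#' @export
table3Specs <- function(seed = 1,
                        file = system.file("configs", "table3.yaml",
                                           package = "PathPlexus")) {
  cfg <- yaml::read_yaml(file)
  specs <- lapply(seq_along(cfg$models), function(i) {
    m <- cfg$models[[i]]
    architectureSpec(
      block_type = m$block_type, depth = m$depth, width = m$width,
      n_junctions = m$n_junctions, n_short_paths = m$n_short_paths,
      c1 = m$c1, k1 = m$k1, crop_center = m$crop_center,
      initial_filter_factor = m$initial_filter_factor,
      normalization = m$normalization, global_pooling = m$global_pooling,
      fc_channels = m$fc_channels, output = m$output,
      n_classes = if (is.null(m$n_classes)) 2 else m$n_classes,
      transformer = unlist(m$transformer), seed = seed + i,
      label = m$label)
  })
  names(specs) <- vapply(cfg$models, `[[`, "", "label")
  specs
}

#' Packaged thresholds and rules
#'
#' Returns the packaged configuration: published per-finding decision
#' thresholds (operating points), the mask-labeling area-fraction rules,
#' grading secondary-pattern thresholds (5% reported, 10% corrected),
#' slide-sorting rule, and the QC reference ranges.
#'
#' @param file YAML file; defaults to the packaged `configs/thresholds.yaml`.
#' @return nested list mirroring the YAML structure.
#' @export
defaultConfig <- function(file = system.file("configs", "thresholds.yaml",
                                             package = "PathPlexus")) {
  yaml::read_yaml(file)
}
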