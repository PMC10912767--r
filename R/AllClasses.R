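#' @include PathPlexus-package.R
NULL

VALID_BLOCKS <- c("vgg", "inception", "residual", "soft_attention")
VALID_FINDINGS <- c("pca", "gp3", "gp4", "gp5", "hgpin", "ductal",
                    "cribriform", "nerve", "vessel", "inflammation")

#' PlexusNet architecture hyperparameters
#'
#' One full hyperparameter description of a PlexusNet model: the block type
#' shared by all paths, graph depth (levels), width (number of end-to-end
#' paths), number of weighted junctions (cross edges between two paths),
#' number of transitory short paths, the stem (feature population) layer,
#' optional central crop, the per-level channel growth factor, global pooling
#' flavor, fully-connected width, output head, optional transformer blocks,
#' and the seed that fixes junction/short-path placement.
#'
#' @slot block_type one of `"vgg"`, `"inception"`, `"residual"`,
#'   `"soft_attention"`.
#' @slot depth integer number of levels (>= 2).
#' @slot width integer number of end-to-end paths (>= 1).
#' @slot n_junctions integer count of weighted cross edges (0 when width < 2).
#' @slot n_short_paths integer count of transitory short paths.
#' @slot c1 stem output channels.
#' @slot k1 stem kernel size (odd).
#' @slot s1 stem stride (default 2).
#' @slot crop_center logical; take the central 256x256 crop of a 512x512
#'   input before the stem.
#' @slot initial_filter_factor integer channel growth factor per path.
#' @slot gamma compression rate in (0,1] used inside bottlenecks and the
#'   per-level channel schedule.
#' @slot normalization `"batch"` or `"layer"`.
#' @slot global_pooling `"max"` or `"avg"`.
#' @slot fc_channels width of the first fully connected layer.
#' @slot output `"softmax"` or `"sigmoid"`.
#' @slot n_classes number of output categories (softmax) -- 1 for sigmoid.
#' @slot transformer integer length-2 vector `c(n_blocks, n_heads)`;
#'   `c(0L, 0L)` disables transformer blocks.
#' @slot seed integer seed fixing random graph topology and weight init.
#' @slot label free-text label (e.g. the finding the model targets).
#' @export
setClass("ArchitectureSpec",
  representation(
    block_type = "character", depth = "integer", width = "integer",
    n_junctions = "integer", n_short_paths = "integer",
    c1 = "integer", k1 = "integer", s1 = "integer",
    crop_center = "logical", initial_filter_factor = "numeric",
    gamma = "numeric", normalization = "character",
    global_pooling = "character", fc_channels = "integer",
    output = "character", n_classes = "integer",
    transformer = "integer", seed = "integer", label = "character"))

setValidity("ArchitectureSpec", function(object) {
  msg <- character()
  if (!object@block_type %in% VALID_BLOCKS)
    msg <- c(msg, sprintf("block_type must be one of %s",
                          paste(VALID_BLOCKS, collapse = ", ")))
  if (object@depth < 2L) msg <- c(msg, "depth must be >= 2")
  if (object@width < 1L) msg <- c(msg, "width must be >= 1")
  if (object@width < 2L && object@n_junctions > 0L)
    msg <- c(msg, "junctions require width >= 2")
  if (object@n_junctions < 0L || object@n_short_paths < 0L)
    msg <- c(msg, "junction and short-path counts must be nonnegative")
  if (object@c1 < 1L) msg <- c(msg, "c1 must be >= 1")
  if (object@k1 %% 2L != 1L) msg <- c(msg, "k1 must be odd")
  if (object@s1 < 1L) msg <- c(msg, "s1 must be >= 1")
  if (object@gamma <= 0 || object@gamma > 1)
    msg <- c(msg, "gamma must be in (0, 1]")
  if (!object@normalization %in% c("batch", "layer"))
    msg <- c(msg, "normalization must be 'batch' or 'layer'")
  if (!object@global_pooling %in% c("max", "avg"))
    msg <- c(msg, "global_pooling must be 'max' or 'avg'")
  if (!object@output %in% c("softmax", "sigmoid"))
    msg <- c(msg, "output must be 'softmax' or 'sigmoid'")
  if (object@output == "softmax" && object@n_classes < 2L)
    msg <- c(msg, "softmax head needs n_classes >= 2")
  if (object@output == "sigmoid" && object@n_classes != 1L)
    msg <- c(msg, "sigmoid head has n_classes = 1")
  if (length(object@transformer) != 2L || any(object@transformer < 0L))
    msg <- c(msg, "transformer must be c(n_blocks, n_heads) >= 0")
  if (length(msg)) msg else TRUE
})

#' Built PlexusNet model graph
#'
#' A directed acyclic multigraph materialised from an [ArchitectureSpec-class]:
#' an ordered list of primitive nodes (stem, block layers, pooling, weighted
#' junctions, short-path merges, concatenation, transformer, head) whose
#' order is a topological sort, plus the trainable input-interpolation
#' weights and build metadata (sampled junction/short-path positions).
#'
#' @slot spec the [ArchitectureSpec-class] the graph was built from.
#' @slot nodes ordered list of primitive nodes.
#' @slot interp numeric `c(omega1, omega2)` of the input interpolation layer.
#' @slot meta list: sampled junction positions, short-path levels/depths,
#'   per-level channel schedule.
#' @export
setClass("ModelGraph",
  representation(spec = "ArchitectureSpec", nodes = "list",
                 interp = "numeric", meta = "list"))

setValidity("ModelGraph", function(object) {
  if (length(object@interp) != 2L) return("interp must be c(omega1, omega2)")
  if (any(abs(object@interp) > 1)) return("omega weights must lie in [-1, 1]")
  TRUE
})

#' Tile grid over a slide
#'
#' Row-major grid of half-open `[x0, x0 + patch_px)` pixel boxes covering a
#' slide at the working resolution, after background exclusion. Coordinates
#' are 0-based with the origin at the top-left corner.
#'
#' @slot slide_id slide identifier.
#' @slot patch_px patch edge length in pixels (default 512).
#' @slot stride_px stride between box origins (`patch_px` when no overlap).
#' @slot microns_per_pixel resolution the grid was computed at.
#' @slot coords data.frame with columns `row`, `col`, `x0`, `y0`,
#'   `tissue_fraction`, `retained`.
#' @export
setClass("TileGrid",
  representation(slide_id = "character", patch_px = "integer",
                 stride_px = "integer", microns_per_pixel = "numeric",
                 coords = "data.frame"))

setValidity("TileGrid", function(object) {
  if (object@stride_px < 1L || object@stride_px > object@patch_px)
    return("0 < stride_px <= patch_px required")
  need <- c("row", "col", "x0", "y0", "tissue_fraction", "retained")
  if (!all(need %in% names(object@coords)))
    return(paste("coords must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' Per-case Gleason pattern tally
#'
#' Counts of patches positive for each Gleason pattern across all slides of
#' one case, with the tumor and tissue patch totals used as denominators by
#' grading and tumor-volume estimation.
#'
#' @slot counts named integer vector over `c("gp3","gp4","gp5")`.
#' @slot tumor_patch_total number of tumor patches in the case.
#' @slot tissue_patch_total number of tissue patches in the case.
#' @slot mode `"exclusive_highest"` or `"independent"` counting mode.
#' @slot per_slide optional data.frame breakdown by slide.
#' @export
setClass("CaseTally",
  representation(counts = "integer", tumor_patch_total = "integer",
                 tissue_patch_total = "integer", mode = "character",
                 per_slide = "data.frame"))

setValidity("CaseTally", function(object) {
  if (!identical(sort(names(object@counts)), c("gp3", "gp4", "gp5")))
    return("counts must be named gp3, gp4, gp5")
  if (any(object@counts < 0L)) return("counts must be nonnegative")
  if (object@tumor_patch_total < max(object@counts))
    return("tumor_patch_total must be >= every pattern count")
  if (object@mode == "exclusive_highest" &&
      object@tumor_patch_total > 0L &&
      sum(object@counts) != object@tumor_patch_total)
    return("exclusive mode requires counts to sum to tumor_patch_total")
  TRUE
})

#' Gleason pattern assignment for one case
#'
#' Primary/secondary/tertiary Gleason patterns with tumor-relative
#' proportions and the secondary-pattern threshold that produced them.
#'
#' @slot primary integer pattern in 3:5.
#' @slot secondary integer pattern in 3:5.
#' @slot tertiary integer pattern or `NA`.
#' @slot proportions named numeric: fraction of tumor patches per pattern.
#' @slot specimen `"biopsy"` or `"prostatectomy"`.
#' @slot threshold_used secondary-pattern minimum fraction applied.
#' @export
setClass("GleasonAssignment",
  representation(primary = "integer", secondary = "integer",
                 tertiary = "integer", proportions = "numeric",
                 specimen = "character", threshold_used = "numeric"))

setValidity("GleasonAssignment", function(object) {
  if (!object@primary %in% 3:5 || !object@secondary %in% 3:5)
    return("primary and secondary patterns must be in 3:5")
  if (length(object@proportions)) {
    prim <- object@proportions[paste0("gp", object@primary)]
    if (any(object@proportions > prim + 1e-12))
      return("primary pattern must carry the largest proportion")
  }
  TRUE
})

setMethod("show", "ArchitectureSpec", function(object) {
  tr <- if (object@transformer[1] > 0)
    sprintf("transformer(%d blocks, %d heads)", object@transformer[1],
            object@transformer[2]) else "no transformer"
  cat(sprintf(
    "ArchitectureSpec '%s': %s, depth %d, width %d, %d junction(s), %d short path(s)\n",
    object@label, object@block_type, object@depth, object@width,
    object@n_junctions, object@n_short_paths))
  cat(sprintf(
    "  stem %dx%d stride %d -> %d ch | factor %g, gamma %g, %s norm, %s pool, FC %d, %s(%d), %s, seed %d\n",
    object@k1, object@k1, object@s1, object@c1, object@initial_filter_factor,
    object@gamma, object@normalization, object@global_pooling,
    object@fc_channels, object@output, object@n_classes, tr, object@seed))
})

setMethod("show", "ModelGraph", function(object) {
  cat(sprintf("ModelGraph (%s '%s'): %d nodes, %s trainable parameters\n",
              object@spec@block_type, object@spec@label,
              length(object@nodes),
              format(countParameters(object), big.mark = ",")))
  if (length(object@meta$junctions))
    cat(sprintf("  junctions at (level, from, to): %s\n",
        paste(vapply(object@meta$junctions, function(j)
          sprintf("(%d,%d,%d)", j$level, j$from, j$to), ""), collapse = " ")))
  if (length(object@meta$short_paths))
    cat(sprintf("  short paths (insert level, depth): %s\n",
        paste(vapply(object@meta$short_paths, function(s)
          sprintf("(%d,%d)", s$level, s$depth), ""), collapse = " ")))
})

setMethod("show", "TileGrid", function(object) {
  cat(sprintf(
    "TileGrid '%s': %d x %d px patches, stride %d, %d boxes (%d retained) at %.2f um/px\n",
    object@slide_id, object@patch_px, object@patch_px, object@stride_px,
    nrow(object@coords), sum(object@coords$retained),
    object@microns_per_pixel))
})

setMethod("show", "CaseTally", function(object) {
  cat(sprintf("CaseTally (%s): gp3=%d gp4=%d gp5=%d | tumor %d / tissue %d patches\n",
              object@mode, object@counts["gp3"], object@counts["gp4"],
              object@counts["gp5"], object@tumor_patch_total,
              object@tissue_patch_total))
})

setMethod("show", "GleasonAssignment", function(object) {
  tert <- if (is.na(object@tertiary)) "none" else object@tertiary
  cat(sprintf(
    "Gleason %d + %d (tertiary %s), %s, secondary threshold %.0f%%\n",
    object@primary, object@secondary, tert, object@specimen,
    100 * object@threshold_used))
  cat("  proportions:",
      paste(sprintf("%s=%.1f%%", names(object@proportions),
                    100 * object@proportions), collapse = " "), "\n")
})

#' @describeIn TileGrid-class number of grid boxes.
#' @param x a `TileGrid`.
#' @export
setMethod("length", "TileGrid", function(x) nrow(x@coords))

#' Coordinate table of a tile grid
#'
#' @param x a [TileGrid-class].
#' @param ... ignored.
#' @return the `coords` data.frame (row, col, x0, y0, tissue_fraction,
#'   retained).
#' @export
setMethod("as.data.frame", "TileGrid", function(x, ...) x@coords)

#' Accessors for grading containers
#'
#' `patternCounts()` returns the per-pattern patch counts of a
#' [CaseTally-class]; `tumorPatchTotal()` and `tissuePatchTotal()` its
#' denominators; `gleasonPatterns()` the `c(primary, secondary, tertiary)`
#' patterns of a [GleasonAssignment-class].
#'
#' @param x a `CaseTally` or `GleasonAssignment`.
#' @return named integer vector or totals.
#' @export
patternCounts <- function(x) { stopifnot(is(x, "CaseTally")); x@counts }

#' @rdname patternCounts
#' @export
tumorPatchTotal <- function(x) {
  stopifnot(is(x, "CaseTally")); x@tumor_patch_total
}

#' @rdname patternCounts
#' @export
tissuePatchTotal <- function(x) {
  stopifnot(is(x, "CaseTally")); x@tissue_patch_total
}

#' @rdname patternCounts
#' @export
gleasonPatterns <- function(x) {
  stopifnot(is(x, "GleasonAssignment"))
  c(primary = x@primary, secondary = x@secondary, tertiary = x@tertiary)
}
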