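## Grid-method tumor volume, slide sorting and capsule-proximity zoning.

#' Grid-method tumor volume percentage
#'
#' Planimetric tumor volume estimate: each patch is one grid cell ("a
#' pixel" of the planimetry grid), and TuVol% is 100 times the number of
#' prostate-cancer-positive patches divided by the number of tissue
#' patches, pooled over all slides of the case.
#'
#' @param positive_patches integer vector: PCa-positive patch count per
#'   slide.
#' @param tissue_patches integer vector: tissue patch count per slide.
#' @return TuVol% in `[0, 100]`.
#' @examples
#' tumorVolumePercent(c(10, 15), c(50, 50))   # 25
#' @export
tumorVolumePercent <- function(positive_patches, tissue_patches) {
  stopifnot(length(positive_patches) == length(tissue_patches))
  tot <- sum(tissue_patches)
  if (tot == 0) stop("tumorVolumePercent: case has no tissue patches")
  100 * sum(positive_patches) / tot
}

#' Sort one slide by cancer presence
#'
#' A slide is marked positive when at least `min_positive_patches` patches
#' reach the tumor-probability threshold (the published rule: two patches
#' at a 49%-or-above confidence score suffice).
#'
#' @param patch_scores per-patch tumor scores in `[0, 1]`.
#' @param score_threshold decision threshold (default 0.49; rule is
#'   `score >= threshold`).
#' @param min_positive_patches minimum positive patches (default 2).
#' @return logical.
#' @export
classifySlide <- function(patch_scores, score_threshold = 0.49,
                          min_positive_patches = 2) {
  if (!length(patch_scores)) {
    warning("classifySlide: empty slide treated as negative")
    return(FALSE)
  }
  sum(patch_scores >= score_threshold) >= min_positive_patches
}

#' Case-level slide-sorting error metrics
#'
#' Compares predicted and true per-slide cancer flags: slide-level
#' confusion counts, the per-case error rate (misclassified slides over
#' slides in the case) for cases with at least one error, and the fraction
#' of cases with at least one falsely sorted slide -- the clinically
#' relevant "erroneous patients per 100 examined".
#'
#' @param predicted,truth logical per-slide vectors.
#' @param case_ids per-slide case identifiers.
#' @return list with `confusion` (tp/fp/tn/fn), `per_case` (data.frame of
#'   case, n_slides, n_errors, error_rate), and
#'   `fraction_cases_with_error`.
#' @export
caseSortingMetrics <- function(predicted, truth, case_ids) {
  if (length(predicted) != length(truth) ||
      length(truth) != length(case_ids))
    stop("caseSortingMetrics: input vectors must be aligned")
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  confusion <- c(tp = sum(predicted & truth),
                 fp = sum(predicted & !truth),
                 tn = sum(!predicted & !truth),
                 fn = sum(!predicted & truth))
  err <- predicted != truth
  perCase <- do.call(rbind, lapply(split(seq_along(err), case_ids),
    function(ii) data.frame(case = case_ids[ii[1]],
                            n_slides = length(ii),
                            n_errors = sum(err[ii]),
                            error_rate = mean(err[ii]),
                            stringsAsFactors = FALSE)))
  rownames(perCase) <- NULL
  list(confusion = confusion, per_case = perCase,
       fraction_cases_with_error = mean(perCase$n_errors > 0))
}

#' Capsule border zone of a tissue mask
#'
#' Extracts the boundary-adjacent band (zone 1) comprising
#' `area_fraction` of the tissue area: the mask is eroded iteratively
#' (3x3 diamond structuring element) and the erosion count whose interior
#' area is closest to `(1 - area_fraction)` of the tissue area is taken;
#' the zone is the tissue minus that interior. Fragmented masks are
#' processed per connected component, so each tissue fragment contributes
#' its own 10% band.
#'
#' @param tissue_mask logical matrix, `TRUE` = tissue.
#' @param area_fraction band area as a fraction of tissue area
#'   (default 0.10).
#' @return logical matrix of the zone.
#' @export
borderZone <- function(tissue_mask, area_fraction = 0.10) {
  stopifnot(area_fraction >= 0, area_fraction <= 1)
  if (area_fraction == 0) return(tissue_mask & FALSE)
  if (area_fraction == 1) return(tissue_mask)
  lab <- EBImage::bwlabel(EBImage::Image(t(tissue_mask) * 1))
  labm <- t(EBImage::imageData(lab))
  zone <- matrix(FALSE, nrow(tissue_mask), ncol(tissue_mask))
  brush <- EBImage::makeBrush(3, shape = "diamond")
  for (comp in setdiff(unique(as.vector(labm)), 0)) {
    m <- labm == comp
    target <- (1 - area_fraction) * sum(m)
    cur <- EBImage::Image(t(m) * 1)
    best <- m; bestDiff <- abs(sum(m) - target)
    interior <- m
    repeat {
      cur <- EBImage::erode(cur, brush)
      interior <- t(EBImage::imageData(cur)) > 0.5
      a <- sum(interior)
      if (abs(a - target) < bestDiff) {
        best <- interior; bestDiff <- abs(a - target)
      }
      if (a <= target || a == 0) break
    }
    zone <- zone | (m & !best)
  }
  zone
}

#' Cancer presence in the capsule border zone
#'
#' TRUE when any cancer pixel lies inside zone 1 (the capsule-adjacent
#' band), the definition used for the capsule-proximity flag.
#'
#' @param cancer_mask,zone_mask aligned logical matrices.
#' @return logical.
#' @export
capsuleProximity <- function(cancer_mask, zone_mask) {
  stopifnot(identical(dim(cancer_mask), dim(zone_mask)))
  any(cancer_mask & zone_mask)
}
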