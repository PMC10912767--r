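## Gleason pattern tallies and the ISUP grading algorithms.

#' Tally Gleason-pattern patch counts for a case
#'
#' Counts patches positive for each Gleason pattern across the slides of a
#' case. In `exclusive_highest` mode (the default) each tumor patch is
#' counted once, for the highest pattern whose threshold it passes, so the
#' pattern proportions sum to one; in `independent` mode a patch counts for
#' every pattern it passes. Input is either a boolean label matrix or a
#' score matrix plus per-pattern thresholds; columns `gp3`, `gp4`, `gp5`
#' are required. A case without tumor patches yields a zero tally (benign
#' case), which is valid input for volume estimation but not for grading.
#'
#' @param m patches-by-patterns matrix (logical labels or numeric scores)
#'   with columns `gp3`, `gp4`, `gp5`; rows from every slide of the case.
#' @param thresholds named per-pattern decision thresholds applied when `m`
#'   is numeric (defaults to the published operating points).
#' @param mode `"exclusive_highest"` or `"independent"`.
#' @param tissue_patch_total number of tissue patches in the case (defaults
#'   to `nrow(m)`, appropriate when `m` covers all tissue patches).
#' @param slide_ids optional per-row slide identifiers for the per-slide
#'   breakdown.
#' @return a [CaseTally-class].
#' @export
tallyCase <- function(m, thresholds = NULL,
                      mode = c("exclusive_highest", "independent"),
                      tissue_patch_total = nrow(m), slide_ids = NULL) {
  mode <- match.arg(mode)
  pats <- c("gp3", "gp4", "gp5")
  if (!all(pats %in% colnames(m)))
    stop("tallyCase: columns gp3, gp4, gp5 are required")
  if (is.numeric(m) && !is.logical(m)) {
    if (is.null(thresholds))
      thresholds <- unlist(defaultConfig()$decision_thresholds[pats])
    lab <- vapply(pats, function(p) m[, p] >= thresholds[[p]],
                  logical(nrow(m)))
    if (is.null(dim(lab))) lab <- matrix(lab, nrow = 1L,
                                         dimnames = list(NULL, pats))
  } else {
    lab <- m[, pats, drop = FALSE]
  }
  anyPos <- rowSums(lab) > 0
  if (mode == "exclusive_highest") {
    counts <- c(gp3 = 0L, gp4 = 0L, gp5 = 0L)
    highest <- apply(lab, 1L, function(r) {
      w <- which(r)
      if (length(w)) max(w) else 0L
    })
    for (k in 1:3) counts[k] <- sum(highest == k)
  } else {
    counts <- c(gp3 = sum(lab[, "gp3"]), gp4 = sum(lab[, "gp4"]),
                gp5 = sum(lab[, "gp5"]))
  }
  perSlide <- if (!is.null(slide_ids)) {
    stopifnot(length(slide_ids) == nrow(lab))
    agg <- stats::aggregate(lab, by = list(slide = slide_ids), FUN = sum)
    agg
  } else data.frame()
  new("CaseTally", counts = as.integer(counts) |>
        stats::setNames(pats),
      tumor_patch_total = as.integer(sum(anyPos)),
      tissue_patch_total = as.integer(tissue_patch_total),
      mode = mode, per_slide = perSlide)
}

#' Assign primary/secondary/tertiary Gleason patterns
#'
#' Implements the ISUP pattern-assignment rules. The primary pattern is
#' the most frequent one. For prostatectomy specimens the second most
#' common pattern becomes the secondary pattern only if its tumor-relative
#' fraction is at least `secondary_min_fraction` (5% in the reporting
#' guideline; 10% after correcting for the human underestimation bias);
#' otherwise the secondary pattern repeats the primary and the second most
#' common pattern is recorded as tertiary. For biopsy cores the secondary
#' pattern is simply the second most common pattern, with no minimum.
#' Frequency ties break toward the higher (clinically worse) pattern.
#' Proportions are fractions of the tumor patch total.
#'
#' @param tally a [CaseTally-class] with a nonzero tumor patch count.
#' @param specimen `"biopsy"` or `"prostatectomy"`.
#' @param secondary_min_fraction minimum tumor fraction for the secondary
#'   pattern (prostatectomy only; default 0.05).
#' @return a [GleasonAssignment-class].
#' @examples
#' t1 <- new("CaseTally", counts = c(gp3 = 920L, gp4 = 70L, gp5 = 10L),
#'           tumor_patch_total = 1000L, tissue_patch_total = 2000L,
#'           mode = "exclusive_highest", per_slide = data.frame())
#' assignPatterns(t1, "prostatectomy", 0.05)  # 3 + 4, tertiary 5
#' assignPatterns(t1, "prostatectomy", 0.10)  # 3 + 3, tertiary 4
#' @export
assignPatterns <- function(tally, specimen = c("prostatectomy", "biopsy"),
                           secondary_min_fraction = 0.05) {
  specimen <- match.arg(specimen)
  stopifnot(is(tally, "CaseTally"))
  counts <- tally@counts
  total <- sum(counts)
  if (total == 0L || tally@tumor_patch_total == 0L)
    stop("assignPatterns: benign case (zero tally) has no grade")
  denom <- tally@tumor_patch_total
  pats <- c(3L, 4L, 5L)
  ## order by count descending, ties toward the higher pattern
  ord <- order(counts, pats, decreasing = TRUE)
  present <- counts[ord] > 0L
  ranked <- pats[ord][present]
  fracs <- (counts[ord][present]) / denom
  primary <- ranked[1]
  tertiary <- NA_integer_
  if (length(ranked) == 1L) {
    secondary <- primary
  } else if (specimen == "biopsy") {
    secondary <- ranked[2]
    if (length(ranked) >= 3L) tertiary <- ranked[3]
  } else {
    if (fracs[2] >= secondary_min_fraction) {
      secondary <- ranked[2]
      if (length(ranked) >= 3L) tertiary <- ranked[3]
    } else {
      secondary <- primary
      tertiary <- ranked[2]
    }
  }
  props <- counts / denom
  new("GleasonAssignment", primary = primary,
      secondary = as.integer(secondary), tertiary = as.integer(tertiary),
      proportions = props, specimen = specimen,
      threshold_used = if (specimen == "prostatectomy")
        secondary_min_fraction else 0)
}

#' ISUP grade group from primary and secondary patterns
#'
#' `3+3 -> 1`, `3+4 -> 2`, `4+3 -> 3`, sum 8 (`4+4`, `3+5`, `5+3`) `-> 4`,
#' sums 9-10 `-> 5`.
#'
#' @param primary,secondary Gleason patterns in 3:5, or a
#'   [GleasonAssignment-class] as first argument.
#' @return integer grade group in 1:5.
#' @export
gradeGroup <- function(primary, secondary = NULL) {
  if (is(primary, "GleasonAssignment")) {
    secondary <- primary@secondary
    primary <- primary@primary
  }
  if (!primary %in% 3:5 || !secondary %in% 3:5)
    stop("gradeGroup: patterns must be in 3:5")
  s <- primary + secondary
  if (s == 6L) 1L
  else if (primary == 3L && secondary == 4L) 2L
  else if (primary == 4L && secondary == 3L) 3L
  else if (s == 8L) 4L
  else 5L
}

#' Binarise an ISUP grade group
#'
#' Grade groups 1-2 form the low-grade stratum `"GG1-2"`, groups 3-5 the
#' high-grade stratum `"GG3-5"`.
#'
#' @param grade_group integer in 1:5.
#' @return `"GG1-2"` or `"GG3-5"`.
#' @export
binarizeGrade <- function(grade_group) {
  stopifnot(all(grade_group %in% 1:5))
  ifelse(grade_group <= 2L, "GG1-2", "GG3-5")
}
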