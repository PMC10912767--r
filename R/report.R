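## Machine-readable per-case pathology summary.

#' Assemble a per-case pathology report
#'
#' Aggregates per-slide patch labels (or thresholded scores) into a
#' machine-readable case summary: ISUP grade under both the 5% and the
#' corrected 10% secondary-pattern thresholds, the pattern proportions,
#' grid-method TuVol%, the list of cancer-positive slides (two-positive-
#' patch rule), the capsule-proximity flag, and boolean flags for the
#' complementary findings (cribriform, ductal, HGPIN, nerve, vessel,
#' inflammation). A benign case carries no grade fields, TuVol 0 and
#' all-false flags. The report is a pure function of its inputs, and
#' serialises losslessly through JSON.
#'
#' @param case_id case identifier.
#' @param labels list of per-slide logical label matrices (columns `pca`,
#'   `gp3`, `gp4`, `gp5`, optionally the complementary findings), as
#'   produced by [labelGrid()].
#' @param tissue_masks optional list of per-slide logical tissue masks for
#'   the capsule-proximity flag.
#' @param cancer_masks optional list of per-slide logical cancer masks
#'   aligned with `tissue_masks`.
#' @param config configuration list (defaults to [defaultConfig()]).
#' @param qc_records optional data.frame of QC records to summarise.
#' @return a `CaseReport` list (class `"CaseReport"`).
#' @export
assembleCaseReport <- function(case_id, labels, tissue_masks = NULL,
                               cancer_masks = NULL, config = defaultConfig(),
                               qc_records = NULL) {
  stopifnot(is.list(labels), length(labels) >= 1)
  slideIds <- if (!is.null(names(labels)) && all(nzchar(names(labels))))
    names(labels) else sprintf("s%02d", seq_along(labels))
  lab <- do.call(rbind, labels)
  gpCols <- c("gp3", "gp4", "gp5")
  stopifnot(all(c("pca", gpCols) %in% colnames(lab)))

  tally <- tallyCase(lab[, gpCols, drop = FALSE],
                     tissue_patch_total = nrow(lab))
  tuvol <- tumorVolumePercent(
    vapply(labels, function(l) sum(l[, "pca"]), 0),
    vapply(labels, nrow, 0L))

  sorting <- config$slide_sorting
  positive <- vapply(labels, function(l)
    classifySlide(as.numeric(l[, "pca"]),
                  score_threshold = sorting$score_threshold,
                  min_positive_patches = sorting$min_positive_patches),
    logical(1))

  capsule <- FALSE
  if (!is.null(tissue_masks) && !is.null(cancer_masks)) {
    capsule <- any(mapply(function(tm, cm)
      capsuleProximity(cm, borderZone(tm, 0.10)),
      tissue_masks, cancer_masks))
  }

  flagNames <- c("cribriform", "ductal", "hgpin", "nerve", "vessel",
                 "inflammation")
  flags <- vapply(flagNames, function(f)
    f %in% colnames(lab) && any(lab[, f]), logical(1))

  graded <- sum(tally@counts) > 0L
  report <- list(
    case_id = case_id,
    n_slides = length(labels),
    tumor_patch_total = tally@tumor_patch_total,
    tissue_patch_total = tally@tissue_patch_total,
    tuvol_percent = tuvol,
    positive_slide_list = slideIds[positive],
    capsule_proximity = capsule,
    finding_flags = as.list(flags),
    qc_summary = if (is.null(qc_records)) NULL else
      as.list(table(qc_records$action)))
  if (graded) {
    a5 <- assignPatterns(tally, "prostatectomy",
                         config$grading$secondary_min_fraction_reported)
    a10 <- assignPatterns(tally, "prostatectomy",
                          config$grading$secondary_min_fraction_corrected)
    report <- c(report, list(
      pattern_counts = as.list(tally@counts),
      pattern_proportions = as.list(round(a5@proportions, 6)),
      primary_pattern = a5@primary,
      secondary_pattern_5pct = a5@secondary,
      tertiary_pattern_5pct = if (is.na(a5@tertiary)) NULL else a5@tertiary,
      isup_grade_5pct = gradeGroup(a5),
      secondary_pattern_10pct = a10@secondary,
      tertiary_pattern_10pct = if (is.na(a10@tertiary)) NULL
                               else a10@tertiary,
      isup_grade_10pct = gradeGroup(a10),
      binary_group_10pct = binarizeGrade(gradeGroup(a10))))
  }
  structure(report, class = "CaseReport")
}

#' Serialise / read back a case report
#'
#' @param report a `CaseReport`.
#' @param path JSON file path.
#' @return `readCaseReport` returns the parsed `CaseReport`.
#' @export
writeCaseReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeCaseReport
#' @export
readCaseReport <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE),
            class = "CaseReport")
}

#' @export
print.CaseReport <- function(x, ...) {
  cat(sprintf("CaseReport %s: %d slides, TuVol %.2f%%\n", x$case_id,
              x$n_slides, x$tuvol_percent))
  if (!is.null(x$isup_grade_10pct))
    cat(sprintf("  ISUP %d (5%% rule) / %d (10%% rule), patterns %d+%d\n",
                x$isup_grade_5pct, x$isup_grade_10pct, x$primary_pattern,
                x$secondary_pattern_10pct))
  else cat("  benign case (no grade)\n")
  invisible(x)
}
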