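## Synthetic slides, masks, scores and patch datasets with exact ground
## truth. The generators emulate tissue-on-white H&E slides: a textured
## tissue ellipse on a white scanner background, lesions painted as
## compact disks with class-specific band-limited textures, and the mask
## carrying one integer code per finding. Every artifact ships its own
## truth table; downstream oracle tests consume only these truths.

bandNoise <- function(h, w, sigma) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (sigma > 0) {
    img <- EBImage::gblur(EBImage::Image(t(z)), sigma = sigma)
    z <- t(EBImage::imageData(img))
  }
  (z - mean(z)) / stats::sd(z)
}

## base RGB colors (0-255) per mask code; tissue/stroma is code 0
codeColor <- function(code) {
  switch(as.character(code),
    "0" = c(225, 175, 205),          # benign stroma, eosin pink
    "3" = c(170, 120, 175),          # gp3
    "4" = c(150, 100, 160),          # gp4
    "5" = c(130, 85, 150),           # gp5
    "1" = c(160, 110, 170),          # generic pca
    c(175, 130, 180))                # other findings
}

## texture frequency (blur sigma of the band noise) per texture class
textureSigma <- function(texture_class) {
  c(0.5, 1.5, 2.5, 3.5, 4.5)[((texture_class - 1) %% 5) + 1]
}

#' Generate one synthetic slide with annotation mask and truth table
#'
#' Paints a white-background slide with a textured tissue ellipse and
#' compact disk lesions whose pixel areas are tuned by bisection to the
#' requested fractions of the tissue area. Each lesion carries the mask
#' code of its finding and a class-specific band-limited texture
#' (distinct dominant frequency, near-identical mean intensity). The
#' returned truth table records the exact painted pixel areas.
#'
#' @param size_px slide edge length in pixels (square slide).
#' @param microns_per_pixel resolution metadata (default 1).
#' @param tissue_axes ellipse semi-axes as fractions of the slide edge.
#' @param lesions list of `list(finding=, target_area_fraction=,
#'   texture_class=)`; fractions are of the tissue area and must sum to
#'   at most 0.9.
#' @param slide_id identifier.
#' @param seed RNG seed; equal seeds give identical rasters.
#' @return list with `slide` (a [SlideImage-class]), `mask` (integer
#'   matrix), `tissue_mask` (logical), and `truth` (data.frame with
#'   finding, code, pixel_area, area_fraction, tissue_pixels).
#' @export
generateSlide <- function(size_px = 768, microns_per_pixel = 1,
                          tissue_axes = c(0.42, 0.45), lesions = list(),
                          slide_id = "synthetic", seed = 1) {
  fr <- vapply(lesions, `[[`, 0, "target_area_fraction")
  if (length(fr) && (any(fr <= 0) || sum(fr) > 0.9))
    stop("generateSlide: lesion fractions must be positive and sum to <= 0.9")
  withr::with_seed(seed, {
    h <- size_px; w <- size_px
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    ay <- tissue_axes[1] * h; ax <- tissue_axes[2] * w
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    tissue <- ((rr - cy) / ay)^2 + ((cc - cx) / ax)^2 <= 1
    tissuePx <- sum(tissue)
    mask <- matrix(0L, h, w)
    avail <- tissue

    nles <- length(lesions)
    angles <- if (nles) 2 * pi * (seq_len(nles) - 1) / nles +
      stats::runif(1, 0, 2 * pi / max(1, nles)) else numeric()
    rad0 <- 0.5 * min(ax, ay)
    truth <- data.frame()
    for (i in seq_along(lesions)) {
      les <- lesions[[i]]
      code <- findingCode(les$finding)
      ly <- cy + rad0 * sin(angles[i]) * 0.8
      lx <- cx + rad0 * cos(angles[i]) * 0.8
      target <- les$target_area_fraction * tissuePx
      d2 <- (rr - ly)^2 + (cc - lx)^2
      lo <- 0; hi <- max(h, w)
      for (it in 1:45) {
        mid <- (lo + hi) / 2
        a <- sum(avail & d2 <= mid^2)
        if (a < target) lo <- mid else hi <- mid
      }
      sel <- avail & d2 <= hi^2
      got <- sum(sel)
      if (abs(got - target) > 0.05 * target + 4)
        stop("generateSlide: cannot reach target area for lesion '",
             les$finding, "' (wanted ", round(target), ", got ", got, ")")
      mask[sel] <- code
      avail <- avail & !sel
      truth <- rbind(truth, data.frame(
        finding = les$finding, code = code, pixel_area = got,
        area_fraction = got / tissuePx, tissue_pixels = tissuePx,
        texture_class = les$texture_class, stringsAsFactors = FALSE))
    }

    ## paint: white background, textured tissue, textured lesions
    ## (noise is generated over the selection's bounding box only)
    px <- array(255, c(h, w, 3))
    paint <- function(sel, base, sigma) {
      if (!any(sel)) return()
      ri <- range(which(rowSums(sel) > 0))
      ci <- range(which(colSums(sel) > 0))
      z <- matrix(0, h, w)
      z[ri[1]:ri[2], ci[1]:ci[2]] <-
        bandNoise(ri[2] - ri[1] + 1L, ci[2] - ci[1] + 1L, sigma)
      for (ch in 1:3) {
        plane <- px[, , ch]
        plane[sel] <- pmin(pmax(base[ch] + 22 * z[sel], 0), 255)
        px[, , ch] <<- plane
      }
    }
    paint(tissue & mask == 0L, codeColor(0), 1.0)
    for (i in seq_along(lesions)) {
      les <- lesions[[i]]
      paint(mask == findingCode(les$finding),
            codeColor(findingCode(les$finding)),
            textureSigma(les$texture_class))
    }
    list(slide = slideImage(px, microns_per_pixel, slide_id),
         mask = mask, tissue_mask = tissue, truth = truth)
  })
}

#' Generate a multi-slide synthetic case with grading ground truth
#'
#' Builds `n_slides` slides whose Gleason-pattern lesion areas follow the
#' requested tumor composition, then derives the case-level truth by
#' running the labeling and grading machinery on the generated masks:
#' per-pattern patch counts, TuVol%, and the expected ISUP grade under
#' both the 5% and the corrected 10% secondary-pattern thresholds. The
#' truth is therefore exactly consistent with [labelGrid()] output on the
#' generated masks (patch-quantization effects included).
#'
#' @param n_slides number of whole-mount slides (default 4).
#' @param size_px slide edge length (default 1024).
#' @param patch_px grid patch size for the truth labeling (default 32;
#'   fine enough that patch-count fractions track lesion area fractions).
#' @param gp_fractions named tumor composition, e.g.
#'   `c(gp3 = .92, gp4 = .07, gp5 = .01)`; zero entries are dropped.
#' @param tumor_fraction total tumor area as a fraction of tissue area
#'   per slide (default 0.35).
#' @param seed RNG seed.
#' @return list with `slides` (per-slide [generateSlide()] bundles),
#'   `grids`, `labels` (per-slide label matrices), `slide_ids`, and
#'   `truth` (tally, tuvol_percent, grades at both thresholds, flags).
#' @export
generateCase <- function(n_slides = 4, size_px = 1024, patch_px = 32,
                         gp_fractions = c(gp3 = 0.92, gp4 = 0.07,
                                          gp5 = 0.01),
                         tumor_fraction = 0.35, seed = 1) {
  stopifnot(n_slides >= 1)
  gp_fractions <- gp_fractions[gp_fractions > 0]
  if (length(gp_fractions) &&
      abs(sum(gp_fractions) - 1) > 1e-6)
    stop("generateCase: gp_fractions must sum to 1")
  lesions <- if (length(gp_fractions))
    lapply(names(gp_fractions), function(p) list(
      finding = p,
      target_area_fraction = tumor_fraction * gp_fractions[[p]],
      texture_class = findingCode(p) - 1L))
  else list()
  slides <- lapply(seq_len(n_slides), function(s)
    generateSlide(size_px = size_px, lesions = lesions,
                  slide_id = sprintf("s%02d", s), seed = seed * 1000 + s))
  tiled <- lapply(slides, function(sl)
    tileSlide(sl$slide, mask = sl$tissue_mask, patch_px = patch_px))
  labels <- lapply(seq_len(n_slides), function(s)
    labelGrid(slides[[s]]$mask, tiled[[s]]$grid,
              findings = c("pca", "gp3", "gp4", "gp5")))
  slideIds <- rep(sprintf("s%02d", seq_len(n_slides)),
                  vapply(labels, nrow, 0L))
  lab <- do.call(rbind, labels)
  tally <- tallyCase(lab[, c("gp3", "gp4", "gp5"), drop = FALSE],
                     tissue_patch_total = nrow(lab),
                     slide_ids = slideIds)
  tuvol <- tumorVolumePercent(
    vapply(labels, function(l) sum(l[, "pca"]), 0),
    vapply(labels, nrow, 0L))
  grades <- if (sum(tally@counts) > 0) {
    a5 <- assignPatterns(tally, "prostatectomy", 0.05)
    a10 <- assignPatterns(tally, "prostatectomy", 0.10)
    list(assignment_5pct = a5, assignment_10pct = a10,
         isup_5pct = gradeGroup(a5), isup_10pct = gradeGroup(a10))
  } else list(assignment_5pct = NULL, assignment_10pct = NULL,
              isup_5pct = NA_integer_, isup_10pct = NA_integer_)
  positiveSlides <- vapply(labels, function(l) sum(l[, "pca"]) >= 2,
                           logical(1))
  capsule <- any(vapply(slides, function(s)
    capsuleProximity(s$mask > 0, borderZone(s$tissue_mask, 0.10)),
    logical(1)))
  list(slides = slides, grids = lapply(tiled, `[[`, "grid"),
       labels = labels, slide_ids = slideIds,
       truth = c(list(tally = tally, tuvol_percent = tuvol,
                      positive_slides = positiveSlides,
                      capsule_proximity = capsule), grades))
}

#' Simulate score/label pairs at a target AUROC
#'
#' Binormal score model: positives draw from `N(mu, 1)` and negatives from
#' `N(0, 1)` with `mu = sqrt(2) * qnorm(target_auroc)`, so the expected
#' AUROC is exactly the target; scores are squashed to `(0, 1)` by the
#' logistic function (rank-preserving, hence AUROC-preserving). A target
#' of 1 produces separated supports.
#'
#' @param n number of samples.
#' @param prevalence positive fraction (positives count =
#'   `round(n * prevalence)`).
#' @param target_auroc expected AUROC in `[0.5, 1]`.
#' @param seed RNG seed.
#' @return list with `labels` (0/1) and `scores` in `[0, 1]`.
#' @export
simulateScores <- function(n, prevalence = 0.5, target_auroc = 0.8,
                           seed = 1) {
  if (target_auroc < 0.5 || target_auroc > 1)
    stop("simulateScores: target_auroc must be in [0.5, 1]")
  nPos <- round(n * prevalence)
  withr::with_seed(seed, {
    labels <- sample(c(rep(1L, nPos), rep(0L, n - nPos)))
    if (target_auroc >= 1) {
      scores <- ifelse(labels == 1L, stats::runif(n, 0.6, 1),
                       stats::runif(n, 0, 0.4))
    } else {
      mu <- sqrt(2) * stats::qnorm(target_auroc)
      raw <- stats::rnorm(n, mean = mu * labels)
      scores <- stats::plogis(raw - mu / 2)
    }
    list(labels = labels, scores = scores)
  })
}

#' Generate a labeled texture-patch dataset
#'
#' Balanced patch set whose classes share the same mean intensity exactly
#' (linearly inseparable in the raw pixel mean) but differ in the dominant
#' spatial frequency of their band-limited noise texture -- learnable by a
#' small CNN and by local texture statistics such as the variance of the
#' Laplacian.
#'
#' @param classes number of texture classes (>= 2).
#' @param n_per_class patches per class.
#' @param patch_px patch edge length.
#' @param seed RNG seed.
#' @return list with `x` (`(n, patch_px, patch_px, 3)` array in `[0, 1]`)
#'   and `y` (integer labels `0..classes-1`).
#' @export
generatePatchDataset <- function(classes = 2, n_per_class = 60,
                                 patch_px = 32, seed = 1) {
  stopifnot(classes >= 2)
  n <- classes * n_per_class
  withr::with_seed(seed, {
    x <- array(0, c(n, patch_px, patch_px, 3))
    y <- integer(n)
    i <- 0L
    for (k in seq_len(classes)) {
      sig <- c(0.5, 2.2, 3.5, 4.5)[((k - 1) %% 4) + 1]
      for (j in seq_len(n_per_class)) {
        i <- i + 1L
        z <- bandNoise(patch_px, patch_px, sig)
        plane <- pmin(pmax(0.5 + 0.16 * z, 0), 1)
        for (ch in 1:3) x[i, , , ch] <- plane
        y[i] <- k - 1L
      }
    }
    ord <- sample.int(n)
    list(x = x[ord, , , , drop = FALSE], y = y[ord])
  })
}
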