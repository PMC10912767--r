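## Mask-based patch labeling with per-finding area-fraction rules.

#' Default per-finding labeling rules
#'
#' The published area-fraction rules converting an annotation mask into
#' per-patch boolean labels: prostate cancer is positive when strictly more
#' than 1% of the patch is positive; Gleason patterns 3-5 and HGPIN at
#' 10%; ductal morphology at 40% with a white-background ceiling of 60%
#' (lumen-rich glands); cribriform at 50%; nerves and vessels at 5% (small
#' structures); inflammation at 3%; any unlisted finding defaults to 5%.
#'
#' @param finding optional finding name; when given, the single rule is
#'   returned (falling back to the 5% default).
#' @return data.frame with columns `finding`, `min_positive_fraction`,
#'   `strict` (strict inequality) and `max_white_fraction` (`NA` = none).
#' @export
findingRules <- function(finding = NULL) {
  cfg <- defaultConfig()
  rules <- do.call(rbind, lapply(names(cfg$labeling_rules), function(f) {
    r <- cfg$labeling_rules[[f]]
    data.frame(finding = f,
               min_positive_fraction = r$min_positive_fraction,
               strict = isTRUE(r$strict),
               max_white_fraction = if (is.null(r$max_white_fraction))
                 NA_real_ else r$max_white_fraction,
               stringsAsFactors = FALSE)
  }))
  if (is.null(finding)) return(rules)
  hit <- rules[rules$finding == finding, ]
  if (nrow(hit) == 1L) return(hit)
  data.frame(finding = finding,
             min_positive_fraction = cfg$default_rule$min_positive_fraction,
             strict = FALSE, max_white_fraction = NA_real_,
             stringsAsFactors = FALSE)
}

#' Fraction of mask pixels carrying a label code
#'
#' @param mask_patch integer-label matrix.
#' @param label_code the code counted as positive.
#' @return fraction in `[0, 1]`.
#' @export
fractionPositive <- function(mask_patch, label_code) {
  if (length(mask_patch) == 0L) stop("fractionPositive: empty patch")
  mean(mask_patch == label_code)
}

whiteFraction <- function(rgb_patch, white_level = 220) {
  mean(rgb_patch[, , 1] >= white_level & rgb_patch[, , 2] >= white_level &
       rgb_patch[, , 3] >= white_level)
}

#' Label one patch for one finding
#'
#' A patch is positive when its positive-area fraction reaches the rule's
#' threshold (strictly exceeds it for rules flagged `strict`, as for
#' prostate cancer's "more than one percent") and, where the rule carries a
#' white-area ceiling (ductal morphology), the white-background fraction of
#' the RGB patch does not exceed it. White pixels are those with all RGB
#' channels at 220 or above (configurable).
#'
#' @param mask_patch integer-label matrix.
#' @param rgb_patch `(h, w, 3)` RGB patch on the 0-255 scale; only needed
#'   for rules with a white ceiling.
#' @param rule one-row data.frame as returned by [findingRules()].
#' @param label_code mask code of the finding; defaults to
#'   `findingCode(rule$finding)`.
#' @param white_level channel floor defining a white pixel (default 220).
#' @return logical.
#' @export
labelPatch <- function(mask_patch, rgb_patch = NULL, rule,
                       label_code = findingCode(rule$finding),
                       white_level = 220) {
  if (!is.null(rgb_patch) &&
      !identical(dim(mask_patch), dim(rgb_patch)[1:2]))
    stop("labelPatch: mask and RGB patches are misaligned")
  frac <- fractionPositive(mask_patch, label_code)
  pos <- if (isTRUE(rule$strict)) frac > rule$min_positive_fraction
         else frac >= rule$min_positive_fraction
  if (pos && !is.na(rule$max_white_fraction)) {
    if (is.null(rgb_patch))
      stop("labelPatch: rule has a white ceiling but no RGB patch given")
    pos <- whiteFraction(rgb_patch, white_level) <= rule$max_white_fraction
  }
  pos
}

#' Mask codes of the findings
#'
#' Fixed integer codes used in single-raster annotation masks (0 =
#' unannotated background/benign tissue).
#'
#' @param finding optional finding name(s); returns all codes when `NULL`.
#' @return named integer vector (or scalar).
#' @export
findingCode <- function(finding = NULL) {
  codes <- c(pca = 1L, gp3 = 3L, gp4 = 4L, gp5 = 5L, hgpin = 6L,
             ductal = 7L, cribriform = 8L, nerve = 9L, vessel = 10L,
             inflammation = 11L)
  if (is.null(finding)) codes else codes[finding]
}

#' Label all retained patches of a grid
#'
#' Tiles the annotation mask with the slide's grid (image and mask share
#' the grid) and applies [labelPatch()] for every requested finding,
#' producing the patch-by-finding boolean label matrix. Gleason-pattern
#' codes also count as prostate cancer for the `pca` column, mirroring
#' masks where PCa area is annotated by its pattern.
#'
#' @param mask integer-label matrix with the slide's (resampled)
#'   dimensions.
#' @param grid a [TileGrid-class].
#' @param findings character vector of findings to label.
#' @param pixels optional RGB raster (needed for white-ceiling rules).
#' @param rules rules table, defaults to [findingRules()].
#' @return logical matrix (retained patches x findings) with the retained
#'   patch indices as rownames.
#' @export
labelGrid <- function(mask, grid, findings = c("pca", "gp3", "gp4", "gp5"),
                      pixels = NULL, rules = NULL) {
  co <- grid@coords
  p <- grid@patch_px
  if (nrow(co) && (max(co$y0) + p > nrow(mask) ||
                   max(co$x0) + p > ncol(mask)))
    stop("labelGrid: mask dimensions do not match the grid")
  keep <- which(co$retained)
  out <- matrix(FALSE, length(keep), length(findings),
                dimnames = list(keep, findings))
  gpCodes <- findingCode(c("gp3", "gp4", "gp5"))
  if (is.null(rules)) rules <- findingRules()
  getRule <- function(f) {
    rule <- rules[rules$finding == f, ]
    if (nrow(rule) != 1L) findingRules(f) else rule
  }
  ## fast path: non-overlapping grid -> block-sum reduction per code
  fast <- grid@stride_px == p && all(co$x0 %% p == 0) &&
    all(co$y0 %% p == 0)
  if (fast && length(keep)) {
    blockSum <- function(bin) {
      nr <- max(co$row); nc <- max(co$col)
      cr <- bin[seq_len(nr * p), seq_len(nc * p), drop = FALSE]
      m1 <- rowsum(cr, rep(seq_len(nr), each = p))
      t(rowsum(t(m1), rep(seq_len(nc), each = p)))   # nr x nc sums
    }
    cellIdx <- cbind(co$row[keep], co$col[keep])
    fracOf <- function(bin) blockSum(bin * 1)[cellIdx] / p^2
    whiteFrac <- NULL
    for (f in findings) {
      rule <- getRule(f)
      frac <- if (f == "pca")
        fracOf(mask == findingCode("pca") | mask %in% gpCodes)
      else fracOf(mask == findingCode(f))
      pos <- if (isTRUE(rule$strict)) frac > rule$min_positive_fraction
             else frac >= rule$min_positive_fraction
      if (!is.na(rule$max_white_fraction)) {
        if (is.null(pixels))
          stop("labelGrid: rule for '", f,
               "' has a white ceiling but no RGB raster given")
        if (is.null(whiteFrac))
          whiteFrac <- fracOf(pixels[, , 1] >= 220 &
                              pixels[, , 2] >= 220 &
                              pixels[, , 3] >= 220)
        pos <- pos & (whiteFrac <= rule$max_white_fraction)
      }
      out[, f] <- pos
    }
    return(out)
  }
  for (k in seq_along(keep)) {
    i <- keep[k]
    mp <- getPatch(mask, grid, i)
    rp <- if (!is.null(pixels)) getPatch(pixels, grid, i)
    for (f in findings) {
      rule <- getRule(f)
      if (f == "pca") {
        frac <- mean(mp == findingCode("pca") | mp %in% gpCodes)
        out[k, f] <- if (isTRUE(rule$strict))
          frac > rule$min_positive_fraction
        else frac >= rule$min_positive_fraction
      } else {
        out[k, f] <- labelPatch(mp, rp, rule)
      }
    }
  }
  out
}
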