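## Foreground detection, tiling and patch-level quality control.
##
## Raster convention: slides and patches are numeric arrays (height, width,
## 3) on the 0-255 scale, masks are logical (height, width) matrices with
## the origin at the top-left corner. EBImage stores images as (x, y[, c]),
## so spatial EBImage calls transpose on the way in and out.

#' Slide raster with resolution metadata
#'
#' @slot pixels `(height, width, 3)` numeric array, 0-255 scale.
#' @slot microns_per_pixel scan resolution (> 0); 1 um/px corresponds to
#'   the 10x working magnification, 0.5 um/px to 20x.
#' @slot slide_id slide identifier.
#' @export
setClass("SlideImage",
  representation(pixels = "array", microns_per_pixel = "numeric",
                 slide_id = "character"))

setValidity("SlideImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be a (height, width, 3) array")
  if (object@microns_per_pixel <= 0)
    return("microns_per_pixel must be > 0")
  TRUE
})

#' @describeIn SlideImage-class constructor.
#' @param pixels `(height, width, 3)` array on the 0-255 scale.
#' @param microns_per_pixel scan resolution in microns per pixel.
#' @param slide_id identifier.
#' @export
slideImage <- function(pixels, microns_per_pixel = 1, slide_id = "slide") {
  new("SlideImage", pixels = pixels,
      microns_per_pixel = as.numeric(microns_per_pixel),
      slide_id = slide_id)
}

setMethod("show", "SlideImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SlideImage '%s': %d x %d px at %.2f um/px\n",
              object@slide_id, d[1], d[2], object@microns_per_pixel))
})

rgbToGray <- function(pixels) {
  0.2126 * pixels[, , 1] + 0.7152 * pixels[, , 2] + 0.0722 * pixels[, , 3]
}

#' Otsu foreground (tissue) detection
#'
#' Computes Otsu's threshold on the 256-bin grayscale histogram of the
#' slide and returns the tissue mask (pixels darker than the threshold;
#' H&E tissue is darker than the white scanner background). A blank slide
#' yields an empty mask. The chosen threshold maximises the between-class
#' variance and is attached as attribute `"threshold"` (0-255 scale).
#'
#' @param slide a [SlideImage-class] or a `(height, width, 3)` array on the
#'   0-255 scale.
#' @return logical `(height, width)` matrix, `TRUE` = tissue.
#' @export
otsuForeground <- function(slide) {
  pixels <- if (is(slide, "SlideImage")) slide@pixels else slide
  gray <- rgbToGray(pixels)
  g <- pmin(pmax(gray, 0), 255)
  if (max(g) - min(g) < .Machine$double.eps * 255) {
    mask <- matrix(FALSE, nrow(g), ncol(g))
    attr(mask, "threshold") <- NA_real_
    return(mask)
  }
  th <- EBImage::otsu(EBImage::Image(t(g) / 255), range = c(0, 1),
                      levels = 256) * 255
  mask <- gray < th
  attr(mask, "threshold") <- th
  mask
}

#' Tile a slide into patches at a target resolution
#'
#' Resamples the slide to `target_mpp` microns per pixel (bilinear
#' interpolation), lays a row-major grid of `patch_px` x `patch_px`
#' half-open boxes with stride `patch_px * (1 - overlap_fraction)` starting
#' at the top-left corner, and marks as retained the boxes whose tissue
#' fraction against the foreground mask reaches `min_tissue_fraction`.
#' Only fully interior boxes are generated.
#'
#' @param slide a [SlideImage-class].
#' @param mask optional logical tissue mask at the target resolution;
#'   computed with [otsuForeground()] when missing.
#' @param patch_px patch edge length in pixels (default 512).
#' @param target_mpp working resolution (1.0 um/px ~ 10x; 0.5 ~ 20x).
#' @param overlap_fraction fractional overlap between neighbouring patches
#'   (0.5 halves the stride).
#' @param min_tissue_fraction minimum tissue fraction for retaining a patch
#'   (default 0.05).
#' @return list with `grid` (a [TileGrid-class]), `pixels` (the resampled
#'   raster) and `mask`.
#' @examples
#' sl <- slideImage(array(255, c(1024, 1024, 3)), 1, "blank")
#' tileSlide(sl, patch_px = 512)$grid
#' @export
tileSlide <- function(slide, mask = NULL, patch_px = 512, target_mpp = 1.0,
                      overlap_fraction = 0, min_tissue_fraction = 0.05) {
  stopifnot(is(slide, "SlideImage"))
  pixels <- slide@pixels
  scale <- slide@microns_per_pixel / target_mpp
  if (abs(scale - 1) > 1e-9) {
    d <- dim(pixels)
    newH <- max(1L, round(d[1] * scale)); newW <- max(1L, round(d[2] * scale))
    img <- EBImage::Image(aperm(pixels, c(2, 1, 3)) / 255,
                          colormode = "Color")
    img <- EBImage::resize(img, w = newW, h = newH, filter = "bilinear")
    pixels <- aperm(EBImage::imageData(img), c(2, 1, 3)) * 255
  }
  d <- dim(pixels)
  patch_px <- as.integer(patch_px)
  if (patch_px > d[1] || patch_px > d[2])
    stop("patch_px larger than the slide at the target resolution")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  if (is.null(mask)) mask <- otsuForeground(pixels)
  stopifnot(identical(dim(mask), d[1:2]))
  stride <- max(1L, as.integer(round(patch_px * (1 - overlap_fraction))))
  y0s <- seq.int(0L, d[1] - patch_px, by = stride)
  x0s <- seq.int(0L, d[2] - patch_px, by = stride)
  coords <- expand.grid(col = seq_along(x0s), row = seq_along(y0s))[, 2:1]
  coords$x0 <- x0s[coords$col]
  coords$y0 <- y0s[coords$row]
  coords$tissue_fraction <- mapply(function(y0, x0) {
    mean(mask[(y0 + 1L):(y0 + patch_px), (x0 + 1L):(x0 + patch_px)])
  }, coords$y0, coords$x0)
  coords$retained <- coords$tissue_fraction >= min_tissue_fraction
  rownames(coords) <- NULL
  grid <- new("TileGrid", slide_id = slide@slide_id, patch_px = patch_px,
              stride_px = stride, microns_per_pixel = target_mpp,
              coords = coords)
  list(grid = grid, pixels = pixels, mask = mask)
}

#' Extract one patch from a tiled slide
#'
#' @param pixels raster returned by [tileSlide()] (or any array/matrix with
#'   the grid's resolution).
#' @param grid a [TileGrid-class].
#' @param i patch index into `as.data.frame(grid)`.
#' @return the `(patch_px, patch_px[, channels])` sub-array.
#' @export
getPatch <- function(pixels, grid, i) {
  co <- grid@coords[i, ]
  p <- grid@patch_px
  if (length(dim(pixels)) == 3L)
    pixels[(co$y0 + 1L):(co$y0 + p), (co$x0 + 1L):(co$x0 + p), ,
           drop = FALSE]
  else
    pixels[(co$y0 + 1L):(co$y0 + p), (co$x0 + 1L):(co$x0 + p),
           drop = FALSE]
}

#' Variance-of-Laplacian blur score
#'
#' Convolves the grayscale patch (0-255 scale) with the 3x3 Laplacian
#' kernel `[[0,1,0],[1,-4,1],[0,1,0]]` and returns the sample variance of
#' the response over interior pixels (the one-pixel border is excluded so
#' no padding convention enters the score). Low variance indicates blur.
#'
#' @param patch `(h, w, 3)` array or `(h, w)` matrix, 0-255 scale.
#' @return nonnegative scalar.
#' @export
laplacianVariance <- function(patch) {
  g <- if (length(dim(patch)) == 3L) rgbToGray(patch) else patch
  h <- nrow(g); w <- ncol(g)
  if (h < 3L || w < 3L) return(0)
  ci <- 2:(h - 1); cj <- 2:(w - 1)
  resp <- g[ci - 1, cj] + g[ci + 1, cj] + g[ci, cj - 1] + g[ci, cj + 1] -
    4 * g[ci, cj]
  if (length(resp) < 2L) return(0)
  stats::var(as.vector(resp))
}

#' Mean relative luminance of a patch
#'
#' Mean over pixels of the Rec. 709 relative luminance
#' `0.2126 R + 0.7152 G + 0.0722 B` on the 0-255 scale; the published
#' reference range for well-stained patches is 144.4-165.3.
#'
#' @param patch `(h, w, 3)` array, 0-255 scale.
#' @return scalar in `[0, 255]`.
#' @export
meanRelativeLuminance <- function(patch) {
  mean(rgbToGray(patch))
}

#' One unsharp-mask sharpening pass
#'
#' `sharp = patch + amount * (patch - gaussian_blur(patch, sigma))` with
#' amount 1 and sigma 1, clipped to `[0, 255]`. A constant patch is
#' returned unchanged.
#'
#' @param patch `(h, w, 3)` array, 0-255 scale.
#' @param amount unsharp amount (default 1).
#' @param sigma Gaussian blur standard deviation in pixels (default 1).
#' @return sharpened patch, same shape, values in `[0, 255]`.
#' @export
sharpenOnce <- function(patch, amount = 1, sigma = 1) {
  img <- EBImage::Image(aperm(patch, c(2, 1, 3)) / 255, colormode = "Color")
  blur <- EBImage::gblur(img, sigma = sigma)
  blurArr <- aperm(EBImage::imageData(blur), c(2, 1, 3)) * 255
  pmin(pmax(patch + amount * (patch - blurArr), 0), 255)
}

#' Blur and illuminance quality control for one patch
#'
#' Applies the published patch QC rule: if the variance-of-Laplacian blur
#' score falls outside `blur_range`, one sharpening pass is applied and the
#' score re-tested -- a patch still outside the range is excluded from
#' detection. If the mean relative luminance falls outside `illum_range`,
#' stain enhancement ([enhanceStain()]) is applied. Action precedence when
#' several steps fire: `excluded` > `corrected` > `sharpened` > `pass`.
#' A passing patch is returned unmodified.
#'
#' @param patch `(h, w, 3)` array, 0-255 scale.
#' @param blur_range blur reference range (default `c(112, 124)`).
#' @param illum_range luminance reference range (default `c(144.4, 165.3)`).
#' @param patch_id identifier recorded in the QC record.
#' @return list with `patch` (possibly modified) and `record`, a one-row
#'   data.frame `(patch_id, blur_score, illuminance, action)` where the
#'   scores are the ones the decision was based on.
#' @export
qcPatch <- function(patch, blur_range = c(112, 124),
                    illum_range = c(144.4, 165.3), patch_id = "patch") {
  outside <- function(x, r) x < r[1] || x > r[2]
  blur <- laplacianVariance(patch)
  action <- "pass"
  out <- patch
  if (outside(blur, blur_range)) {
    out <- sharpenOnce(out)
    blur <- laplacianVariance(out)
    if (outside(blur, blur_range)) {
      rec <- data.frame(patch_id = patch_id, blur_score = blur,
                        illuminance = meanRelativeLuminance(out),
                        action = "excluded", stringsAsFactors = FALSE)
      return(list(patch = patch, record = rec))
    }
    action <- "sharpened"
  }
  illum <- meanRelativeLuminance(out)
  if (outside(illum, illum_range)) {
    out <- enhanceStain(out)
    action <- "corrected"
  }
  if (action == "pass") out <- patch
  list(patch = out,
       record = data.frame(patch_id = patch_id, blur_score = blur,
                           illuminance = illum, action = action,
                           stringsAsFactors = FALSE))
}
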