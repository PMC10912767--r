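#' CLAHE + reference-free Macenko stain enhancement
#'
#' Two-stage color/contrast correction for H&E patches. First, contrast
#' limited adaptive histogram equalization (CLAHE) is applied to the
#' lightness channel in CIELAB space. Second, a reference-free Macenko
#' normalization: pixel optical densities `OD = -log((I + 1)/256)` are
#' computed per channel, pixels with all OD components above `beta` define
#' the stained set, the two stain vectors are estimated from the extreme
#' percentile angles in the plane of the top two eigenvectors of the OD
#' covariance, stain concentrations are solved by least squares, rescaled
#' so their `conc_percentile`-th percentile matches fixed canonical H&E
#' targets, and the patch is reconstructed from canonical stain vectors.
#' "Reference-free" means the target stain matrix is the canonical H&E
#' basis rather than a reference image. The procedure is deterministic.
#'
#' A near-white patch with fewer than 1% stained pixels is returned
#' unchanged with attribute `"flag" = "no_stain"`.
#'
#' @param patch `(h, w, 3)` array, 0-255 scale.
#' @param clahe_clip CLAHE clip limit (default 2).
#' @param clahe_tiles CLAHE tile grid edge count (default 8).
#' @param beta optical-density floor defining stained pixels (default 0.15).
#' @param angle_percentiles extreme-angle percentiles (default `c(1, 99)`).
#' @param conc_percentile concentration scaling percentile (default 99).
#' @return corrected patch, same shape, values in `[0, 255]`.
#' @export
enhanceStain <- function(patch, clahe_clip = 2, clahe_tiles = 8,
                         beta = 0.15, angle_percentiles = c(1, 99),
                         conc_percentile = 99) {
  d <- dim(patch)
  ## --- stage 1: CLAHE on the CIELAB lightness channel
  ## (clahe_clip = 0 skips the stage, leaving pure Macenko)
  if (clahe_clip > 0) {
    rgb01 <- pmin(pmax(patch, 0), 255) / 255
    flat <- cbind(as.vector(rgb01[, , 1]), as.vector(rgb01[, , 2]),
                  as.vector(rgb01[, , 3]))
    lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
    lmat <- matrix(lab[, 1] / 100, d[1], d[2])
    leq <- EBImage::clahe(EBImage::Image(t(lmat)),
                          nx = clahe_tiles, ny = clahe_tiles,
                          limit = clahe_clip)
    lab[, 1] <- pmin(pmax(as.vector(t(EBImage::imageData(leq))), 0), 1) * 100
    back <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
    back <- pmin(pmax(back, 0), 1) * 255
    px <- array(0, d)
    px[, , 1] <- back[, 1]; px[, , 2] <- back[, 2]; px[, , 3] <- back[, 3]
  } else {
    px <- pmin(pmax(patch, 0), 255)
  }

  ## --- stage 2: reference-free Macenko
  heRef <- matrix(c(0.5626, 0.7201, 0.4062,
                    0.2159, 0.8012, 0.5581), nrow = 3)   # H, E columns
  maxCRef <- c(1.9705, 1.0308)
  odFlat <- -log((cbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                        as.vector(px[, , 3])) + 1) / 256)
  stained <- rowSums(odFlat > beta) == 3L
  if (mean(stained) < 0.01) {
    attr(patch, "flag") <- "no_stain"
    return(patch)
  }
  odS <- odFlat[stained, , drop = FALSE]
  ## plane of the top two eigenvectors of the uncentered OD second moment
  ev <- eigen(crossprod(odS) / nrow(odS), symmetric = TRUE)$vectors[, 1:2]
  ## deterministic sign: make each eigenvector point into the positive octant
  for (k in 1:2) if (sum(ev[, k]) < 0) ev[, k] <- -ev[, k]
  proj <- odS %*% ev
  phi <- atan2(proj[, 2], proj[, 1])
  aq <- stats::quantile(phi, angle_percentiles / 100, names = FALSE)
  v1 <- ev %*% c(cos(aq[1]), sin(aq[1]))
  v2 <- ev %*% c(cos(aq[2]), sin(aq[2]))
  ## hematoxylin absorbs red light most strongly: larger red-channel OD
  he <- if (v1[1] >= v2[1]) cbind(v1, v2) else cbind(v2, v1)
  gram <- crossprod(he)
  if (abs(det(gram)) < 1e-6) {
    ## near-collinear stain vectors (e.g. a gray patch has no separable
    ## stains): return the CLAHE-corrected patch untouched by Macenko
    attr(px, "flag") <- "collinear_stains"
    return(px)
  }
  conc <- solve(gram, crossprod(he, t(odFlat)))   # 2 x N
  maxC <- apply(conc, 1L, stats::quantile, probs = conc_percentile / 100,
                names = FALSE)
  maxC[maxC < 1e-8] <- 1e-8
  conc <- conc * (maxCRef / maxC)
  recon <- 256 * exp(-(heRef %*% conc)) - 1
  out <- array(0, d)
  out[, , 1] <- matrix(recon[1, ], d[1], d[2])
  out[, , 2] <- matrix(recon[2, ], d[1], d[2])
  out[, , 3] <- matrix(recon[3, ], d[1], d[2])
  pmin(pmax(out, 0), 255)
}
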