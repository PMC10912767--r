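diskImage <- function(n = 200, r = 50, fg = 40, bg = 255) {
  px <- array(bg, c(n, n, 3))
  d <- (row(matrix(0, n, n)) - n / 2)^2 + (col(matrix(0, n, n)) - n / 2)^2
  disk <- d <= r^2
  for (ch in 1:3) { p <- px[, , ch]; p[disk] <- fg; px[, , ch] <- p }
  list(px = px, disk = disk)
}

test_that("Otsu foreground separates a bimodal image and handles blanks", {
  di <- diskImage()
  mask <- otsuForeground(di$px)
  expect_true(all(mask == di$disk))
  expect_identical(dim(mask), dim(di$disk))
  blank <- otsuForeground(array(255, c(50, 50, 3)))
  expect_false(any(blank))
})

test_that("Otsu threshold maximises between-class variance (exhaustive oracle)", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      g <- matrix(sample(c(rnorm(600, 60, 15), rnorm(400, 200, 20))),
                  40, 25)
    })
    g <- pmin(pmax(g, 0), 255)
    px <- array(rep(g, 3), c(40, 25, 3))
    mask <- otsuForeground(px)
    th <- attr(mask, "threshold")
    oracle <- bruteForceOtsu(rgbToGrayTest(px))
    gi <- floor(rgbToGrayTest(px))
    bcv <- function(t) {
      lo <- gi[gi < t]; hi <- gi[gi >= t]
      if (!length(lo) || !length(hi)) return(-Inf)
      w0 <- length(lo) / length(gi)
      w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    }
    ## the chosen cut attains the exhaustive-search maximum of the
    ## between-class variance and induces the same foreground split
    expect_equal(bcv(th), bcv(oracle))
    expect_true(all((gi < th) == (gi < oracle)))
    expect_true(all(mask == (rgbToGrayTest(px) < th)))
  }
})

test_that("tiling yields the expected grid and stride", {
  sl <- slideImage(array(120, c(5120, 5120, 3)), 1, "t")
  m <- matrix(TRUE, 5120, 5120)
  g0 <- tileSlide(sl, m, patch_px = 512)$grid
  expect_identical(length(g0), 100L)
  g5 <- tileSlide(sl, m, patch_px = 512, overlap_fraction = 0.5)$grid
  expect_identical(g5@stride_px, 256L)
  expect_identical(length(g5), 361L)
  expect_error(tileSlide(slideImage(array(0, c(100, 100, 3)), 1, "s"),
                         patch_px = 512), "larger")
})

test_that("grid boxes partition the interior and coordinates round-trip", {
  sl <- slideImage(array(100, c(1100, 900, 3)), 1, "t")
  g <- tileSlide(sl, matrix(TRUE, 1100, 900), patch_px = 256)$grid
  co <- as.data.frame(g)
  expect_identical(nrow(co), (1100L %/% 256L) * (900L %/% 256L))
  ## bijection between (row, col) and (x0, y0)
  expect_identical(co$x0, (co$col - 1L) * g@stride_px)
  expect_identical(co$y0, (co$row - 1L) * g@stride_px)
  expect_false(any(duplicated(co[, c("x0", "y0")])))
  ## no two boxes intersect at zero overlap
  expect_true(all(diff(sort(unique(co$x0))) >= g@patch_px))
})

test_that("background exclusion matches the per-patch mask-sum oracle", {
  withr::with_seed(4, {
    m <- matrix(runif(640 * 640) < 0.3, 640, 640)
  })
  sl <- slideImage(array(90, c(640, 640, 3)), 1, "t")
  res <- tileSlide(sl, m, patch_px = 128, min_tissue_fraction = 0.25)
  co <- as.data.frame(res$grid)
  for (i in seq_len(nrow(co))) {
    frac <- mean(m[co$y0[i] + 1:128, co$x0[i] + 1:128])
    expect_equal(co$tissue_fraction[i], frac)
    expect_identical(co$retained[i], frac >= 0.25)
  }
})

test_that("variance of Laplacian behaves as a blur score", {
  expect_equal(laplacianVariance(array(128, c(20, 20, 3))), 0)
  ## single bright pixel (gray 200) at the centre of a 5x5 black patch:
  ## interior responses are (0,200,0,200,-800,200,0,200,0), variance 1e5
  g <- matrix(0, 5, 5); g[3, 3] <- 200
  expect_equal(laplacianVariance(g), 1e5)
  sharp <- noisePatch(64, 64, 128, 40, seed = 8)
  blurred <- gaussianBlurTest(sharp, 1.5)
  expect_lt(laplacianVariance(blurred), laplacianVariance(sharp))
})

test_that("relative luminance uses Rec. 709 coefficients", {
  expect_equal(meanRelativeLuminance(array(255, c(4, 4, 3))), 255)
  expect_equal(meanRelativeLuminance(array(0, c(4, 4, 3))), 0)
  green <- array(0, c(4, 4, 3)); green[, , 2] <- 255
  expect_equal(meanRelativeLuminance(green), 0.7152 * 255)
})

test_that("unsharp masking sharpens and stays in range", {
  const <- array(99, c(16, 16, 3))
  expect_equal(sharpenOnce(const), const)
  ## blurred edge gets strictly sharper
  edge <- array(0, c(32, 32, 3)); edge[, 17:32, ] <- 255
  blurred <- gaussianBlurTest(edge, 2)
  sharpened <- sharpenOnce(blurred)
  expect_gt(laplacianVariance(sharpened), laplacianVariance(blurred))
  expect_true(all(sharpened >= 0 & sharpened <= 255))
})

test_that("QC applies the sharpen/enhance/exclude decision rule", {
  ## flat gray can never reach the blur range: excluded
  flat <- array(150, c(32, 32, 3))
  r <- qcPatch(flat)
  expect_identical(r$record$action, "excluded")
  expect_identical(r$patch, flat)
  expect_identical(r$record$blur_score, 0)

  ## patch built inside both reference ranges: passes untouched
  ## (iid noise: Laplacian response variance = 20 sigma^2, so sigma ~ 2.4
  ## puts the blur score near 118)
  good <- noisePatch(64, 64, 155, 2.43, seed = 21)
  r2 <- qcPatch(good)
  expect_identical(r2$record$action, "pass")
  expect_identical(r2$patch, good)
  expect_true(r2$record$blur_score >= 112 && r2$record$blur_score <= 124)
  expect_true(r2$record$illuminance >= 144.4 &&
                r2$record$illuminance <= 165.3)

  ## over-bright patch with acceptable blur: corrected, both scores kept
  bright <- noisePatch(64, 64, 205, 2.43, seed = 22)
  r3 <- qcPatch(bright)
  expect_identical(r3$record$action, "corrected")
  expect_gt(r3$record$illuminance, 165.3)
  expect_false(identical(r3$patch, bright))
})
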