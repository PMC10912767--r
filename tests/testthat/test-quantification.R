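test_that("TuVol% is the pooled positive-over-tissue patch ratio", {
  expect_equal(tumorVolumePercent(0, 400), 0)
  expect_equal(tumorVolumePercent(25, 100), 25)
  expect_error(tumorVolumePercent(0, 0), "tissue")
  ## invariant to slide ordering, additive over slides
  pos <- c(3, 10, 0, 7); tis <- c(40, 60, 25, 80)
  expect_equal(tumorVolumePercent(pos, tis),
               tumorVolumePercent(rev(pos), rev(tis)))
  expect_equal(tumorVolumePercent(pos, tis), 100 * sum(pos) / sum(tis))
})

test_that("grid-aligned synthetic masks match pixel planimetry within a patch quantum", {
  p <- 32
  for (seed in 1:10) {
    withr::with_seed(seed, {
      nr <- sample(6:10, 1); nc <- sample(6:10, 1)
      tumorCells <- matrix(runif(nr * nc) < 0.3, nr, nc)
    })
    mask <- matrix(0L, nr * p, nc * p)
    for (r in seq_len(nr)) for (c in seq_len(nc))
      if (tumorCells[r, c])
        mask[(r - 1) * p + 1:p, (c - 1) * p + 1:p] <- 1L
    sl <- slideImage(array(100, c(nr * p, nc * p, 3)), 1, "t")
    tl <- tileSlide(sl, matrix(TRUE, nr * p, nc * p), patch_px = p)
    lab <- labelGrid(mask, tl$grid, findings = "pca")
    tuvol <- tumorVolumePercent(sum(lab[, "pca"]), nrow(lab))
    pixel <- 100 * sum(mask == 1L) / length(mask)
    expect_lt(abs(tuvol - pixel), 100 / nrow(lab) + 1e-9)
  }
})

test_that("the two-positive-patch rule sorts slides", {
  expect_true(classifySlide(c(0.5, 0.6, 0.1)))
  expect_false(classifySlide(c(0.9, 0.1, 0.1)))
  expect_false(classifySlide(c(0.2, 0.3, 0.48)))
  ## the threshold is inclusive: 0.49 itself counts
  expect_true(classifySlide(c(0.49, 0.49)))
  expect_warning(v <- classifySlide(numeric(0)), "empty")
  expect_false(v)
})

test_that("classifySlide is monotone in added positive patches", {
  withr::with_seed(5, {
    for (i in 1:25) {
      sc <- runif(sample(3:12, 1))
      before <- classifySlide(sc)
      after <- classifySlide(c(sc, 0.99))
      expect_true(!before || after)
    }
  })
})

test_that("case-level sorting metrics report per-case error rates", {
  ## one 9-slide case with one error, one 7-slide case with two errors,
  ## one clean 4-slide case
  truth <- c(rep(TRUE, 9), rep(FALSE, 7), rep(TRUE, 4))
  pred <- truth
  pred[3] <- FALSE          # case A: 1/9
  pred[10:11] <- TRUE       # case B: 2/7
  cases <- rep(c("A", "B", "C"), c(9, 7, 4))
  m <- caseSortingMetrics(pred, truth, cases)
  expect_equal(m$per_case$error_rate[m$per_case$case == "A"], 1 / 9)
  expect_equal(m$per_case$error_rate[m$per_case$case == "B"], 2 / 7)
  expect_equal(m$per_case$error_rate[m$per_case$case == "C"], 0)
  expect_equal(m$fraction_cases_with_error, 2 / 3)
  expect_identical(unname(m$confusion["fn"]), 1L)
  expect_identical(unname(m$confusion["fp"]), 2L)
  clean <- caseSortingMetrics(truth, truth, cases)
  expect_equal(clean$fraction_cases_with_error, 0)
  expect_error(caseSortingMetrics(pred[-1], truth, cases), "aligned")
})

diskMask <- function(n, r) {
  (row(matrix(0, n, n)) - n / 2)^2 + (col(matrix(0, n, n)) - n / 2)^2 <= r^2
}

test_that("the border zone captures the requested area fraction on a disk", {
  disk <- diskMask(256, 100)
  zone <- borderZone(disk, 0.10)
  frac <- sum(zone) / sum(disk)
  expect_lt(abs(frac - 0.10), 0.01)
  ## the zone hugs the boundary: inner radius near 100 * sqrt(0.9)
  inner <- disk & !zone
  rmin <- sqrt(min((which(zone, arr.ind = TRUE)[, 1] - 128)^2 +
                   (which(zone, arr.ind = TRUE)[, 2] - 128)^2))
  expect_equal(rmin, 100 * sqrt(0.9), tolerance = 0.05)
  expect_identical(borderZone(disk, 1), disk)
  expect_false(any(borderZone(disk, 0)))
})

test_that("the border-zone area converges with resolution", {
  errs <- vapply(c(64, 128, 256), function(n) {
    disk <- diskMask(n, 0.4 * n)
    abs(sum(borderZone(disk, 0.10)) / sum(disk) - 0.10)
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  expect_true(errs[3] <= errs[1] + 1e-9)
})

test_that("fragmented masks get a zone per connected component", {
  m <- matrix(FALSE, 128, 256)
  m[32:96, 32:96] <- TRUE
  m[32:96, 160:224] <- TRUE
  zone <- borderZone(m, 0.10)
  expect_true(any(zone[, 32:96]) && any(zone[, 160:224]))
  frac <- sum(zone) / sum(m)
  expect_lt(abs(frac - 0.10), 0.02)
})

test_that("capsule proximity flags cancer inside zone 1", {
  disk <- diskMask(256, 100)
  zone <- borderZone(disk, 0.10)
  central <- diskMask(256, 30)
  expect_false(capsuleProximity(central, zone))
  touching <- disk & !diskMask(256, 97)   # thin outer rim
  expect_true(capsuleProximity(touching, zone))
  ## analytic annulus fixture equals the pixel-intersection oracle
  annulus <- disk & !diskMask(256, 96)
  expect_identical(capsuleProximity(annulus, zone),
                   any(annulus & zone))
})
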