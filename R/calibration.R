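## Brute-force decision-threshold calibration by bootstrap-median kappa.

#' Bootstrap median of Cohen kappa at a fixed threshold
#'
#' Draws `n_boot` resamples (with replacement, size n) of the label/score
#' pairs, computes Cohen kappa between the true labels and the thresholded
#' scores (`score >= threshold`) in each resample, and returns the median.
#' The median of the bootstrapped scores mitigates the effect of outlier
#' resamples. Resamples in which kappa is undefined (single-class truth or
#' chance agreement 1) are skipped. Deterministic given `seed`.
#'
#' @param y_true 0/1 labels.
#' @param y_score scores in `[0, 1]`.
#' @param threshold decision threshold in (0, 1).
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param seed RNG seed.
#' @param .resamples optional precomputed `n x n_boot` index matrix (used
#'   by [findBestThreshold()] to share resamples across the grid).
#' @return median bootstrap kappa (NA when every resample is degenerate).
#' @export
bootstrapMedianKappa <- function(y_true, y_score, threshold, n_boot = 10000,
                                 seed = 1, .resamples = NULL) {
  stopifnot(length(y_true) == length(y_score))
  n <- length(y_true)
  idx <- if (is.null(.resamples))
    withr::with_seed(seed, matrix(sample.int(n, n * n_boot, replace = TRUE),
                                  n, n_boot))
  else .resamples
  pred <- as.integer(y_score >= threshold)
  y_true <- as.integer(y_true)
  ks <- vapply(seq_len(ncol(idx)), function(b) {
    ii <- idx[, b]
    cohenKappa(y_true[ii], pred[ii], na_undefined = TRUE)
  }, numeric(1))
  ks <- ks[!is.na(ks)]
  if (!length(ks)) return(NA_real_)
  stats::median(ks)
}

#' Brute-force threshold search maximising bootstrap-median kappa
#'
#' Evaluates every threshold on the grid (default 0.10 to 0.99 in steps of
#' 0.01), scoring each with [bootstrapMedianKappa()], and returns the
#' threshold attaining the maximum. One bootstrap resample-index set is
#' drawn from `seed` and shared across the grid so the trace is comparable
#' point to point and the search is deterministic. Ties are broken toward
#' the lowest threshold (favouring sensitivity). A flat all-zero trace
#' (e.g. constant scores) returns the lowest grid point with a warning.
#'
#' @param y_true 0/1 labels (both classes required).
#' @param y_score scores in `[0, 1]`.
#' @param grid threshold grid (default `seq(0.10, 0.99, by = 0.01)`).
#' @param n_boot bootstrap resamples per grid point (default 10000).
#' @param seed RNG seed.
#' @return list with `best_threshold`, `trace` (data.frame of threshold and
#'   median bootstrap kappa), `n_boot`, `seed`.
#' @examples
#' r <- findBestThreshold(c(0, 0, 1, 1), c(0.2, 0.3, 0.8, 0.9),
#'                        n_boot = 200, seed = 1)
#' r$best_threshold   # 0.31: lowest grid point reaching kappa 1
#' @export
findBestThreshold <- function(y_true, y_score,
                              grid = seq(0.10, 0.99, by = 0.01),
                              n_boot = 10000, seed = 1) {
  grid <- round(grid, 10)   # guard the >= rule against seq() float drift
  y_true <- as.integer(y_true)
  if (length(unique(y_true)) < 2L)
    stop("findBestThreshold: y_true must contain both classes")
  n <- length(y_true)
  idx <- withr::with_seed(seed,
    matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot))
  kappas <- vapply(grid, function(th)
    bootstrapMedianKappa(y_true, y_score, th, .resamples = idx),
    numeric(1))
  kappas[is.na(kappas)] <- -Inf
  if (max(kappas) <= 0)
    warning("findBestThreshold: no threshold achieves positive median ",
            "kappa; a flat trace resolves to the lowest grid point")
  best <- which.max(kappas)   # which.max takes the first (lowest) maximum
  list(best_threshold = grid[best],
       trace = data.frame(threshold = grid,
                          median_bootstrap_kappa = ifelse(
                            is.finite(kappas), kappas, NA_real_)),
       n_boot = n_boot, seed = seed)
}
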