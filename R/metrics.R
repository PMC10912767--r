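## Agreement and accuracy statistics.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with tie correction via average ranks:
#' the probability that a random positive outscores a random negative,
#' counting ties as one half.
#'
#' @param y_true 0/1 labels (both classes required).
#' @param y_score numeric scores.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(y_true, y_score) {
  stopifnot(length(y_true) == length(y_score))
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1L); n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("auroc: both classes must be present")
  r <- rank(y_score)
  (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rates derived from a confusion matrix
#'
#' Sensitivity (TPR), specificity (TNR), positive and negative predictive
#' values, and the positive/negative likelihood ratios
#' `LR+ = sens / (1 - spec)`, `LR- = (1 - sens) / spec`. Rates with a zero
#' denominator are returned as `NA` and listed in the `undefined`
#' attribute.
#'
#' @param tp,fp,tn,fn nonnegative counts.
#' @return named numeric vector `(sensitivity, specificity, ppv, npv,
#'   lr_pos, lr_neg)`.
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  out <- c(sensitivity = sens, specificity = spec,
           ppv = div(tp, tp + fp), npv = div(tn, tn + fn),
           lr_pos = if (is.na(sens) || is.na(spec)) NA_real_
                    else div(sens, 1 - spec),
           lr_neg = if (is.na(sens) || is.na(spec)) NA_real_
                    else div(1 - sens, spec))
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Predictive values at a given prevalence
#'
#' Bayes-rule positive and negative predictive values for a test of known
#' sensitivity and specificity applied at prevalence `p`:
#' `PPV = sens p / (sens p + (1 - spec)(1 - p))`,
#' `NPV = spec (1 - p) / (spec (1 - p) + (1 - sens) p)`.
#' Boundary prevalences return the boundary value with the undefined side
#' flagged `NA`.
#'
#' @param sensitivity,specificity,prevalence values in `[0, 1]`.
#' @return named numeric `c(ppv, npv)`.
#' @export
predictiveValuesAtPrevalence <- function(sensitivity, specificity,
                                         prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, specificity >= 0,
            specificity <= 1, prevalence >= 0, prevalence <= 1)
  if (prevalence == 0) return(c(ppv = NA_real_, npv = 1))
  if (prevalence == 1) return(c(ppv = 1, npv = NA_real_))
  pd <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  nd <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  c(ppv = if (pd == 0) NA_real_ else sensitivity * prevalence / pd,
    npv = if (nd == 0) NA_real_ else
      specificity * (1 - prevalence) / nd)
}

#' Cohen kappa
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` between two
#' categorical vectors.
#'
#' @param a,b equal-length categorical vectors.
#' @param na_undefined return `NA` instead of erroring when the expected
#'   agreement is 1 (e.g. both raters constant).
#' @return kappa in `[-1, 1]`.
#' @export
cohenKappa <- function(a, b, na_undefined = FALSE) {
  stopifnot(length(a) == length(b))
  lev <- sort(unique(c(a, b)))
  ta <- factor(a, levels = lev); tb <- factor(b, levels = lev)
  tab <- table(ta, tb)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) {
    if (na_undefined) return(NA_real_)
    stop("cohenKappa: expected agreement is 1; kappa undefined")
  }
  (po - pe) / (1 - pe)
}

#' Quadratic weighted kappa
#'
#' Weighted kappa with quadratic agreement weights
#' `w_ij = 1 - (i - j)^2 / (k - 1)^2` over `k` ordinal categories; used
#' for ordinal endpoints such as ISUP grade groups. For two categories it
#' equals Cohen kappa exactly.
#'
#' @param a,b equal-length ordinal vectors.
#' @param categories ordered category values (defaults to the sorted union
#'   of observed values).
#' @param na_undefined as in [cohenKappa()].
#' @return weighted kappa.
#' @export
quadraticWeightedKappa <- function(a, b, categories = NULL,
                                   na_undefined = FALSE) {
  stopifnot(length(a) == length(b))
  if (is.null(categories)) categories <- sort(unique(c(a, b)))
  k <- length(categories)
  if (k < 2L) {
    if (na_undefined) return(NA_real_)
    stop("quadraticWeightedKappa: need at least two categories")
  }
  ta <- factor(a, levels = categories)
  tb <- factor(b, levels = categories)
  obs <- table(ta, tb) / length(a)
  exp0 <- outer(rowSums(obs), colSums(obs))
  w <- 1 - (outer(seq_len(k), seq_len(k), "-")^2) / (k - 1)^2
  den <- sum((1 - w) * exp0)
  if (den < 1e-12) {
    if (na_undefined) return(NA_real_)
    stop("quadraticWeightedKappa: expected disagreement is 0; undefined")
  }
  1 - sum((1 - w) * obs) / den
}

#' Verbal agreement level for a kappa value
#'
#' The published agreement bands: below 0 less-than-chance, 0.01-0.20
#' slight, 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 substantial,
#' 0.81-0.99 almost perfect. Exactly 0 is assigned to the slight-band
#' floor and values above 0.99 (including 1) to almost perfect, the two
#' points the published table leaves unassigned.
#'
#' @param kappa numeric kappa value(s), each at most 1.
#' @return character vector of agreement labels.
#' @export
agreementLevel <- function(kappa) {
  stopifnot(all(kappa <= 1 + 1e-12))
  vapply(kappa, function(k) {
    if (k < 0) "Less than chance agreement"
    else if (k <= 0.20) "Slight agreement"
    else if (k <= 0.40) "Fair agreement"
    else if (k <= 0.60) "Moderate agreement"
    else if (k <= 0.80) "Substantial agreement"
    else "Almost perfect agreement"
  }, character(1))
}

#' Exact Clopper-Pearson confidence interval
#'
#' Exact binomial interval for a proportion from the beta quantiles:
#' lower `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`), upper
#' `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param successes,n counts with `0 <= successes <= n`, `n > 0`.
#' @param confidence confidence level (default 0.95).
#' @return named numeric `c(lower, upper)`.
#' @export
clopperPearson <- function(successes, n, confidence = 0.95) {
  if (n <= 0) stop("clopperPearson: n must be positive")
  stopifnot(successes >= 0, successes <= n)
  alpha <- 1 - confidence
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

#' Per-slide aggregation of patch-level performance
#'
#' Groups patch-level truth/score pairs by slide and reports the mean
#' per-slide AUROC and the median and range of the per-slide Cohen kappa
#' at the given threshold. Slides with a single truth class cannot be
#' scored and are skipped, with their count reported.
#'
#' @param y_true 0/1 patch labels.
#' @param y_score patch scores.
#' @param slide_ids per-patch slide identifiers.
#' @param threshold decision threshold for the kappa computation
#'   (default 0.49).
#' @return list with `mean_auroc`, `median_kappa`, `kappa_range`,
#'   `n_slides`, `n_skipped`, and the `per_slide` data.frame.
#' @export
perSlideAggregate <- function(y_true, y_score, slide_ids,
                              threshold = 0.49) {
  stopifnot(length(y_true) == length(y_score),
            length(y_score) == length(slide_ids))
  groups <- split(seq_along(y_true), slide_ids)
  rows <- lapply(names(groups), function(s) {
    ii <- groups[[s]]
    if (length(unique(y_true[ii])) < 2L) return(NULL)
    data.frame(slide = s,
               auroc = auroc(y_true[ii], y_score[ii]),
               kappa = cohenKappa(y_true[ii],
                                  as.integer(y_score[ii] >= threshold),
                                  na_undefined = TRUE),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  per <- do.call(rbind, rows)
  if (is.null(per) || !nrow(per))
    stop("perSlideAggregate: no slide has both classes")
  list(mean_auroc = mean(per$auroc),
       median_kappa = stats::median(per$kappa, na.rm = TRUE),
       kappa_range = range(per$kappa, na.rm = TRUE),
       n_slides = nrow(per), n_skipped = skipped, per_slide = per)
}

#' Chance concordance between two independent raters
#'
#' Probability that two independent raters, each choosing uniformly among
#' `k` groups, both select one designated group: `(1/k)^2` -- 4% for five
#' groups and 25% for two, the chance component behind collapsing grade
#' groups. `simulate` mode estimates the probability empirically.
#'
#' @param k_groups number of groups (>= 1).
#' @param mode `"analytic"` or `"simulate"`.
#' @param n draws in simulate mode (default 1e6).
#' @param seed RNG seed for simulate mode.
#' @return probability in `[0, 1]`.
#' @export
chanceConcordance <- function(k_groups, mode = c("analytic", "simulate"),
                              n = 1e6, seed = 1) {
  mode <- match.arg(mode)
  if (k_groups < 1) stop("chanceConcordance: k_groups must be >= 1")
  if (mode == "analytic") return((1 / k_groups)^2)
  withr::with_seed(seed, {
    a <- sample.int(k_groups, n, replace = TRUE)
    b <- sample.int(k_groups, n, replace = TRUE)
    mean(a == 1L & b == 1L)
  })
}

#' Percentile bootstrap confidence interval
#'
#' Percentile interval of a statistic over `n_resamples` bootstrap
#' resamples; deterministic given `seed`. Degenerate (constant) data yield
#' a zero-width interval flagged via attribute `"degenerate"`.
#'
#' @param statistic function of a data vector (or of resampled rows if
#'   `data` is a matrix/data.frame).
#' @param data vector or matrix/data.frame resampled by rows.
#' @param n_resamples bootstrap replications (the published evaluations
#'   use 100,000; scale down for quick runs).
#' @param seed RNG seed.
#' @param confidence confidence level (default 0.95).
#' @return named numeric `c(lower, upper)`.
#' @export
bootstrapCI <- function(statistic, data, n_resamples = 1e5, seed = 1,
                        confidence = 0.95) {
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  stopifnot(n > 0)
  pick <- if (is.null(dim(data))) function(ii) data[ii]
          else function(ii) data[ii, , drop = FALSE]
  stats <- withr::with_seed(seed, vapply(seq_len(n_resamples), function(b)
    statistic(pick(sample.int(n, n, replace = TRUE))), numeric(1)))
  alpha <- 1 - confidence
  out <- stats::quantile(stats, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  out <- c(lower = out[1], upper = out[2])
  if (out[1] == out[2]) attr(out, "degenerate") <- TRUE
  out
}
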