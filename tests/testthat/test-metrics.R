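test_that("AUROC handles separation, inversion and ties like the pairwise oracle", {
  y <- rep(c(0, 1), each = 10)
  s <- c(runif(10, 0, 0.4), runif(10, 0.6, 1))
  expect_equal(auroc(y, s), 1)
  expect_equal(auroc(1 - y, s), 0)
  expect_error(auroc(rep(1, 5), runif(5)), "both classes")
  withr::with_seed(3, {
    yy <- rbinom(200, 1, 0.4)
    ss <- round(runif(200), 1)   # heavy ties
  })
  expect_equal(auroc(yy, ss), pairwiseAUROC(yy, ss))
  ## complement identity with tie-free scores
  withr::with_seed(4, { s2 <- runif(200) })
  expect_equal(auroc(yy, s2) + auroc(yy, -s2), 1)
  ## agreement with the field-standard implementation
  skip_if_not_installed("pROC")
  expect_equal(auroc(yy, ss),
               as.numeric(pROC::auc(pROC::roc(yy, ss, quiet = TRUE,
                                              direction = "<"))))
})

test_that("confusion-matrix rates match hand arithmetic", {
  perfect <- confusionMetrics(50, 0, 50, 0)
  expect_equal(unname(perfect[1:4]), rep(1, 4))
  always <- confusionMetrics(50, 50, 0, 0)
  expect_equal(unname(always["sensitivity"]), 1)
  expect_equal(unname(always["specificity"]), 0)
  m <- confusionMetrics(90, 10, 80, 20)
  expect_equal(unname(m["sensitivity"]), 90 / 110)
  expect_equal(unname(m["specificity"]), 80 / 90)
  expect_equal(unname(m["ppv"]), 0.9)
  expect_equal(unname(m["lr_pos"]), (90 / 110) / (1 - 80 / 90))
  z <- confusionMetrics(0, 0, 5, 0)
  expect_true("sensitivity" %in% attr(z, "undefined"))
})

test_that("predictive values follow Bayes' rule at a given prevalence", {
  expect_equal(unname(predictiveValuesAtPrevalence(1, 1, 0.3)), c(1, 1))
  pv <- predictiveValuesAtPrevalence(0.999, 0.90, 0.92)
  expect_equal(unname(pv["ppv"]), 0.9914, tolerance = 1e-4)
  expect_equal(unname(pv["npv"]), 0.9874, tolerance = 1e-4)
  p0 <- predictiveValuesAtPrevalence(0.9, 0.9, 0)
  expect_true(is.na(p0["ppv"]))
  expect_equal(unname(p0["npv"]), 1)
})

test_that("Cohen kappa matches hand computation and is symmetric", {
  expect_equal(cohenKappa(1:10, 1:10), 1)
  ## 2x2 table [[45,15],[25,15]]: po=.60, pe=.54, kappa=.06/.46
  a <- rep(c(0, 0, 1, 1), c(45, 15, 25, 15))
  b <- rep(c(0, 1, 0, 1), c(45, 15, 25, 15))
  expect_equal(cohenKappa(a, b), 0.06 / 0.46)
  expect_equal(cohenKappa(a, b), cohenKappa(b, a))
  withr::with_seed(6, {
    x <- rbinom(5000, 1, 0.5); y <- rbinom(5000, 1, 0.5)
  })
  expect_lt(abs(cohenKappa(x, y)), 0.05)
  expect_error(cohenKappa(rep(1, 4), rep(1, 4)), "undefined")
  skip_if_not_installed("e1071")
  expect_equal(cohenKappa(a, b),
               e1071::classAgreement(table(a, b))$kappa)
})

test_that("quadratic weighted kappa handles ordinal tables", {
  expect_equal(quadraticWeightedKappa(c(1, 2, 3), c(1, 2, 3)), 1)
  ## binary case equals Cohen kappa exactly
  withr::with_seed(7, {
    a <- rbinom(300, 1, 0.6); b <- rbinom(300, 1, 0.4)
  })
  expect_equal(quadraticWeightedKappa(a, b), cohenKappa(a, b))
  ## 3-class hand computation
  a3 <- rep(c(1, 1, 2, 2, 3, 3), c(20, 5, 4, 15, 3, 10))
  b3 <- rep(c(1, 2, 1, 2, 2, 3), c(20, 5, 4, 15, 3, 10))
  obs <- table(factor(a3, 1:3), factor(b3, 1:3)) / length(a3)
  ex <- outer(rowSums(obs), colSums(obs))
  w <- 1 - (outer(1:3, 1:3, "-")^2) / 4
  manual <- 1 - sum((1 - w) * obs) / sum((1 - w) * ex)
  expect_equal(quadraticWeightedKappa(a3, b3), manual)
})

test_that("agreement bands map exactly at the published boundaries", {
  expect_identical(agreementLevel(0.70), "Substantial agreement")
  expect_identical(agreementLevel(0.44), "Moderate agreement")
  expect_identical(agreementLevel(-0.1), "Less than chance agreement")
  expect_identical(
    agreementLevel(c(0.20, 0.21, 0.40, 0.41, 0.60, 0.61, 0.80, 0.81)),
    c("Slight agreement", "Fair agreement", "Fair agreement",
      "Moderate agreement", "Moderate agreement", "Substantial agreement",
      "Substantial agreement", "Almost perfect agreement"))
  ## the two gaps of the published table
  expect_identical(agreementLevel(0), "Slight agreement")
  expect_identical(agreementLevel(0.995), "Almost perfect agreement")
  expect_identical(agreementLevel(1), "Almost perfect agreement")
})

test_that("Clopper-Pearson equals the exact binomial interval", {
  expect_equal(unname(clopperPearson(0, 10)["lower"]), 0)
  expect_equal(unname(clopperPearson(10, 10)["upper"]), 1)
  ci <- clopperPearson(8, 10)
  oracle <- stats::binom.test(8, 10)$conf.int
  expect_equal(unname(ci), as.numeric(oracle), tolerance = 1e-6)
  expect_error(clopperPearson(0, 0), "positive")
})

test_that("per-slide aggregation equals regrouped recomputation", {
  sim <- simulateScores(300, target_auroc = 0.9, seed = 9)
  slides <- rep(sprintf("s%d", 1:6), each = 50)
  agg <- perSlideAggregate(sim$labels, sim$scores, slides)
  manual <- vapply(unique(slides), function(s) {
    ii <- slides == s
    auroc(sim$labels[ii], sim$scores[ii])
  }, numeric(1))
  expect_equal(agg$mean_auroc, mean(manual))
  expect_identical(agg$n_slides + agg$n_skipped, 6L)
  ## identical slides reduce to the single-slide values
  one <- perSlideAggregate(rep(sim$labels[1:50], 2),
                           rep(sim$scores[1:50], 2),
                           rep(c("a", "b"), each = 50))
  expect_equal(one$mean_auroc, auroc(sim$labels[1:50], sim$scores[1:50]))
  expect_equal(one$kappa_range[1], one$kappa_range[2])
})

test_that("chance concordance is (1/k)^2 and the simulation converges", {
  expect_equal(chanceConcordance(5), 0.04)
  expect_equal(chanceConcordance(2), 0.25)
  expect_equal(chanceConcordance(1), 1)
  expect_error(chanceConcordance(0), ">= 1")
  sim5 <- chanceConcordance(5, "simulate", n = 1e6, seed = 2)
  expect_lt(abs(sim5 - 0.04), 0.002)
})

test_that("bootstrap CIs are reproducible and cover the mean", {
  dat <- withr::with_seed(17, rnorm(30))
  expect_identical(bootstrapCI(mean, dat, 200, seed = 4),
                   bootstrapCI(mean, dat, 200, seed = 4))
  const <- bootstrapCI(mean, rep(3, 20), 100, seed = 1)
  expect_equal(as.numeric(const), c(3, 3))
  expect_true(isTRUE(attr(const, "degenerate")))
  ## coverage near the nominal level
  hits <- vapply(1:200, function(i) {
    x <- withr::with_seed(1000 + i, rnorm(80, mean = 2))
    ci <- bootstrapCI(mean, x, n_resamples = 300, seed = i)
    ci["lower"] <= 2 && 2 <= ci["upper"]
  }, logical(1))
  expect_gt(mean(hits), 0.85)
  expect_lt(mean(hits), 1)
})
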