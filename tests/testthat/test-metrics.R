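test_that("confusion_counts counts the four cells", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(cc), c(n_pos = 2, n_neg = 2, false_neg = 0,
                             false_pos = 0))
  cc <- confusion_counts(c(1, 1, 0, 0), c(0, 1, 1, 0))
  expect_equal(cc$false_neg, 1)
  expect_equal(cc$false_pos, 1)
  cc <- confusion_counts(c(1, 0), c(0, 0))
  expect_equal(unlist(cc), c(n_pos = 1, n_neg = 1, false_neg = 1,
                             false_pos = 0))
  expect_error(confusion_counts(c(1, 0), c(1)), "length")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "0/1")
})

test_that("Sn/Sp/Acc/MCC match their definitions", {
  m <- compute_metrics(list(n_pos = 2, n_neg = 2, false_neg = 0,
                            false_pos = 0))
  expect_equal(unlist(m), c(sn = 1, sp = 1, acc = 1, mcc = 1))
  m <- compute_metrics(list(n_pos = 100, n_neg = 100, false_neg = 10,
                            false_pos = 20))
  expect_equal(m$sn, 0.90)
  expect_equal(m$sp, 0.80)
  expect_equal(m$acc, 0.85)
  expect_warning(
    m0 <- compute_metrics(list(n_pos = 5, n_neg = 5, false_neg = 5,
                               false_pos = 0)),
    "denominator")
  expect_equal(m0$mcc, 0)
})

test_that("MCC equals the Pearson correlation of the binary vectors", {
  set.seed(21)
  for (i in 1:50) {
    P <- sample(2:60, 1); N <- sample(2:60, 1)
    FN <- sample(0:(P - 1), 1); FP <- sample(0:(N - 1), 1)
    labels <- rep(c(1, 0), c(P, N))
    preds <- c(rep(c(0, 1), c(FN, P - FN)), rep(c(1, 0), c(FP, N - FP)))
    m <- compute_metrics(list(n_pos = P, n_neg = N, false_neg = FN,
                              false_pos = FP))
    expect_equal(m$mcc, suppressWarnings(cor(labels, preds)),
                 tolerance = 1e-12)
  }
})

test_that("metric identities are integer-exact on integer counts", {
  set.seed(22)
  for (i in 1:100) {
    P <- sample(1:500, 1); N <- sample(1:500, 1)
    FN <- sample(0:P, 1); FP <- sample(0:N, 1)
    m <- suppressWarnings(
      compute_metrics(list(n_pos = P, n_neg = N, false_neg = FN,
                           false_pos = FP)))
    expect_equal(m$sn * P + FN, P, tolerance = 1e-9)
    expect_equal(m$acc * (P + N) + FN + FP, P + N, tolerance = 1e-9)
  }
})

test_that("roc_auc matches hand-worked and degenerate cases", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(roc_auc(c(1, 1, 0, 0), rep(0.5, 4)), 0.5)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75)
  expect_error(roc_auc(c(1, 1), c(0.5, 0.4)), "both classes")
})

test_that("roc_auc equals pair counting; negation flips it", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    scores <- round(runif(n), 1)   # coarse grid forces ties
    auc <- roc_auc(labels, scores)
    expect_equal(auc, oracle_auc_pairs(labels, scores), tolerance = 1e-12)
    expect_equal(roc_auc(labels, -scores), 1 - auc, tolerance = 1e-12)
  }
})

test_that("ROC points are monotone, span the unit square, integrate to AUC", {
  pts <- roc_curve_points(c(1, 0), c(0.9, 0.1))
  expect_equal(pts, data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1)))

  set.seed(24)
  for (i in 1:20) {
    n <- sample(5:80, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.3))
    scores <- round(runif(n), 1)
    pts <- roc_curve_points(labels, scores)
    expect_equal(pts$fpr[1], 0)
    expect_equal(pts$tpr[1], 0)
    expect_equal(pts$fpr[nrow(pts)], 1)
    expect_equal(pts$tpr[nrow(pts)], 1)
    expect_true(all(diff(pts$fpr) >= 0))
    expect_true(all(diff(pts$tpr) >= 0))
    area <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
    expect_equal(area, roc_auc(labels, scores), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(25)
  labels <- c(1, 0, rbinom(98, 1, 0.3))
  scores <- runif(100)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(labels, scores), ref, tolerance = 1e-12)
})
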