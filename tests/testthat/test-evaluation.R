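test_that("confusion metrics follow the four closed forms", {
  perfect <- metrics_from_counts(list(tp = 1, fp = 0, tn = 1, fn = 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  m <- metrics_from_counts(list(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_false(any(m$undefined))
})

test_that("zero denominators are flagged, never silently zero", {
  m <- metrics_from_counts(list(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_true(is.nan(m$precision))
  expect_true(m$undefined[["precision"]])
  expect_equal(m$accuracy, 0.5)
  m2 <- metrics_from_counts(list(tp = 0, fp = 5, tn = 5, fn = 0))
  expect_true(is.nan(m2$recall))
  expect_error(metrics_from_counts(list(tp = 0, fp = 0, tn = 0, fn = 0)),
               "no evaluated samples")
})

test_that("metrics recompute exactly from stored confusion counts", {
  set.seed(50)
  for (i in 1:20) {
    pred <- sample(0:1, 30, replace = TRUE)
    truth <- sample(0:1, 30, replace = TRUE)
    cc <- confusion_counts(pred, truth)
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 30)
    m <- metrics_from_counts(cc)
    expect_equal(m$accuracy, mean(pred == truth))
    if (!m$undefined[["precision"]]) {
      expect_equal(m$precision, sum(pred & truth) / sum(pred))
    }
  }
})

test_that("AUC equals exhaustive pair counting and handles ties", {
  labels <- c(1, 0, 1, 0, 1, 0)
  expect_equal(roc_auc(labels, labels), 1)
  expect_equal(roc_auc(rep(0.3, 6), labels), 0.5)
  hand <- list(scores = c(0.9, 0.8, 0.8, 0.4, 0.3, 0.2),
               labels = c(1, 1, 0, 1, 0, 0))
  expect_equal(roc_auc(hand$scores, hand$labels),
               oracle_auc(hand$scores, hand$labels))
  set.seed(51)
  for (i in 1:15) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 2)  # induce ties
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
  expect_error(roc_auc(runif(4), rep(1, 4)), "both classes")
})

test_that("AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(52)
  labels <- sample(0:1, 60, replace = TRUE, prob = c(0.7, 0.3))
  labels[1:2] <- 0:1
  scores <- runif(60)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("threshold-0.5 accuracy is consistent with thresholded counts", {
  set.seed(53)
  probs <- cbind(runif(40))
  probs <- cbind(1 - probs, probs)
  truth <- sample(0:1, 40, replace = TRUE)
  pred <- predict_classes(probs)
  expect_equal(pred, as.integer(probs[, 2] > 0.5))
  m <- metrics_from_counts(confusion_counts(pred, truth))
  expect_equal(m$accuracy, mean(pred == truth))
})

test_that("report tables have the canonical columns and round-trip", {
  cols <- c("model", "accuracy", "loss", "sensitivity", "precision", "f1",
            "auc", "intra_class_0", "intra_class_1",
            "inter_class_center_distance")
  empty <- report_table(list())
  expect_named(empty, cols)
  expect_equal(nrow(empty), 0)

  set.seed(54)
  reports <- lapply(1:12, function(i) {
    r <- list(accuracy = runif(1), loss = runif(1), recall = runif(1),
              precision = runif(1), f1 = runif(1), auc = runif(1),
              separability = c(intra_class_0 = runif(1) * 30,
                               intra_class_1 = runif(1) * 30,
                               inter_class_center_distance = runif(1) * 70))
    class(r) <- "eval_report"
    r
  })
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- report_table(reports, 1:12, path = path)
  expect_equal(nrow(tab), 12)
  expect_named(tab, cols)
  back <- read.csv(path)
  expect_equal(as.matrix(back), as.matrix(tab), tolerance = 1e-12)
})
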