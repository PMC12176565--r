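#' Class decision from softmax probabilities
#'
#' Argmax with ties broken toward the normal class (class 0) — the
#' conservative direction for a screening tool.
#'
#' @param probs matrix `n x n_classes` of class probabilities
#' @return integer vector of predicted labels (0-based)
#' @export
predict_classes <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  apply(probs, 1, which.max) - 1L   # first maximum: ties fall to class 0
}

#' Confusion counts with abnormal as the positive class
#'
#' @param pred,truth integer vectors (0 = normal, 1 = abnormal)
#' @return an object of class `confusion_counts` (fields tp, fp, tn, fn)
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(length(pred) == length(truth),
            all(pred %in% 0:1), all(truth %in% 0:1))
  structure(list(tp = sum(pred == 1 & truth == 1),
                 fp = sum(pred == 1 & truth == 0),
                 tn = sum(pred == 0 & truth == 0),
                 fn = sum(pred == 0 & truth == 1)),
            class = "confusion_counts")
}

#' Confusion-matrix metrics
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' (sensitivity) `TP/(TP+FN)` and F1 `2PR/(P+R)`. A zero denominator yields
#' `NaN` together with the corresponding entry of `undefined` set to `TRUE`
#' — never a silent 0.
#'
#' @param counts a [confusion_counts()] or list with tp, fp, tn, fn
#' @return list with `accuracy`, `precision`, `recall`, `f1`, and
#'   `undefined` (named logical vector)
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  total <- tp + fp + tn + fn
  if (total == 0) stop("no evaluated samples")
  prec <- if (tp + fp == 0) NaN else tp / (tp + fp)
  rec <- if (tp + fn == 0) NaN else tp / (tp + fn)
  f1 <- if (is.nan(prec) || is.nan(rec) || prec + rec == 0) NaN else
    2 * prec * rec / (prec + rec)
  list(accuracy = (tp + tn) / total, precision = prec, recall = rec, f1 = f1,
       undefined = c(precision = is.nan(prec), recall = is.nan(rec),
                     f1 = is.nan(f1)))
}

#' Area under the ROC curve
#'
#' Mann–Whitney formulation: the probability that a random positive sample
#' outranks a random negative one, ties counting one half. Computed from
#' midranks, equivalent to exhaustive pair counting.
#'
#' @param scores numeric scores (higher = more abnormal)
#' @param labels binary labels (0/1), both classes present
#' @return AUC in \[0, 1\]
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' False/true positive rates over every decision threshold (each unique
#' score), from the most permissive to the strictest.
#'
#' @param scores numeric scores (higher = more abnormal)
#' @param labels binary labels (0/1), both classes present
#' @return data frame with columns `threshold`, `fpr`, `tpr`
#' @export
roc_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  th <- c(-Inf, sort(unique(scores)), Inf)
  do.call(rbind, lapply(th, function(t) {
    pred <- scores > t
    data.frame(threshold = t, fpr = sum(pred & labels == 0) / n0,
               tpr = sum(pred & labels == 1) / n1)
  }))
}

#' Evaluate a fitted model on a labelled dataset
#'
#' @param model a `pcg_model`
#' @param data list with `x` (list of input matrices) and `y` (0/1 labels)
#' @return an `eval_report`: confusion counts, the four confusion metrics,
#'   AUC on the abnormal-class score, mean cross-entropy loss, and the
#'   per-sample `scores`
#' @export
evaluate_model <- function(model, data) {
  probs <- model_predict(model, data$x)
  scores <- probs[, 2]
  pred <- predict_classes(probs)
  counts <- confusion_counts(pred, data$y)
  m <- metrics_from_counts(counts)
  auc <- if (length(unique(data$y)) == 2) roc_auc(scores, data$y) else NA_real_
  loss <- -mean(log(pmax(probs[cbind(seq_along(data$y), data$y + 1L)], 1e-12)))
  structure(list(confusion = counts, accuracy = m$accuracy,
                 precision = m$precision, recall = m$recall, f1 = m$f1,
                 undefined = m$undefined, auc = auc, loss = loss,
                 scores = scores, labels = data$y),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report: acc %.4f, sens %.4f, prec %.4f, ",
                     "f1 %.4f, auc %s, loss %.4f>\n"),
              x$accuracy, x$recall, x$precision, x$f1,
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)), x$loss))
  invisible(x)
}

#' Tabulate evaluation reports across models
#'
#' One row per model with the accuracy/loss/sensitivity/precision/F1/AUC
#' columns plus the three t-SNE separability distances (NA when absent).
#'
#' @param reports list of `eval_report` (each optionally carrying a
#'   `separability` element with intra_class_0, intra_class_1,
#'   inter_class_center_distance)
#' @param model_ids vector of model identifiers, same length as `reports`
#' @param path optional CSV output path
#' @return data frame (written to `path` when given)
#' @export
report_table <- function(reports, model_ids = seq_along(reports),
                         path = NULL) {
  stopifnot(length(reports) == length(model_ids))
  grab <- function(r, field) {
    v <- r[[field]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  rows <- mapply(function(r, id) {
    sep <- r$separability
    data.frame(model = id,
               accuracy = grab(r, "accuracy"), loss = grab(r, "loss"),
               sensitivity = grab(r, "recall"), precision = grab(r, "precision"),
               f1 = grab(r, "f1"), auc = grab(r, "auc"),
               intra_class_0 = if (is.null(sep)) NA_real_ else sep[["intra_class_0"]],
               intra_class_1 = if (is.null(sep)) NA_real_ else sep[["intra_class_1"]],
               inter_class_center_distance =
                 if (is.null(sep)) NA_real_ else sep[["inter_class_center_distance"]])
  }, reports, model_ids, SIMPLIFY = FALSE)
  tab <- if (length(rows) == 0) {
    data.frame(model = integer(), accuracy = numeric(), loss = numeric(),
               sensitivity = numeric(), precision = numeric(), f1 = numeric(),
               auc = numeric(), intra_class_0 = numeric(),
               intra_class_1 = numeric(),
               inter_class_center_distance = numeric())
  } else {
    do.call(rbind, rows)
  }
  if (!is.null(path)) write.csv(tab, path, row.names = FALSE)
  tab
}
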