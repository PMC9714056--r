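# ---- confusion matrix and metric suite -------------------------------------

#' Confusion counts for binary amyloid classification
#'
#' Counts follow the positive = amyloid convention.
#'
#' @param y_true,y_pred vectors of class labels, equal length.
#' @return a `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  yt <- .label_factor(y_true)
  yp <- .label_factor(y_pred)
  if (anyNA(yt) || anyNA(yp)) {
    stop("labels outside the two classes (", paste(LABEL_LEVELS,
         collapse = ", "), ")")
  }
  confusion_counts(
    TP = sum(yt == LABEL_POSITIVE & yp == LABEL_POSITIVE),
    TN = sum(yt == LABEL_NEGATIVE & yp == LABEL_NEGATIVE),
    FP = sum(yt == LABEL_NEGATIVE & yp == LABEL_POSITIVE),
    FN = sum(yt == LABEL_POSITIVE & yp == LABEL_NEGATIVE))
}

#' @rdname confusion
#' @param TP,TN,FP,FN non-negative counts (direct construction, e.g. to feed
#'   published confusion tables through the metric suite).
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  stopifnot(all(counts >= 0))
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  # printed in TN, FP / FN, TP layout for direct comparison with published
  # validation/test tables
  cat("confusion counts (rows = truth, cols = predicted):\n")
  m <- matrix(c(x$TN, x$FP, x$FN, x$TP), 2, 2, byrow = TRUE,
              dimnames = list(c("non-amyloid", "amyloid"),
                              c("pred non-amyloid", "pred amyloid")))
  print(m)
  invisible(x)
}

#' The confusion-matrix metric suite
#'
#' Computes accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, the balanced summary `Q = (SN+SP)/2`, the Matthews
#' correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` and the error rate
#' `(FP+FN)/total`. Zero-denominator conventions: an undefined SN or SP is
#' reported as 0, and an MCC with any zero factor under the root is 0 —
#' reports are always total, never NaN.
#'
#' @param cm a `confusion_counts` object.
#' @param auc optional AUC to carry in the report.
#' @return a `metrics_report` list: `ACC`, `SN`, `SP`, `Q`, `MCC`,
#'   `error_rate`, `AUC` (possibly NA), `counts`.
#' @examples
#' metrics(confusion_counts(TP = 33, TN = 21, FP = 12, FN = 0))
#' @export
metrics <- function(cm, auc = NA_real_) {
  stopifnot(inherits(cm, "confusion_counts"))
  total <- cm$TP + cm$TN + cm$FP + cm$FN
  if (total <= 0) stop("empty confusion matrix")
  tp <- as.numeric(cm$TP); tn <- as.numeric(cm$TN)
  fp <- as.numeric(cm$FP); fn <- as.numeric(cm$FN)
  sn <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  # product computed in double: the four marginals overflow integer range
  denom_sq <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom_sq > 0) (tp * tn - fp * fn) / sqrt(denom_sq) else 0
  structure(list(ACC = (cm$TP + cm$TN) / total,
                 SN = sn, SP = sp, Q = (sn + sp) / 2, MCC = mcc,
                 error_rate = (cm$FP + cm$FN) / total,
                 AUC = auc, counts = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "ACC %.4f  SN %.4f  SP %.4f  Q %.4f  MCC %.4f  error %.4f  AUC %s\n",
    x$ACC, x$SN, x$SP, x$Q, x$MCC, x$error_rate,
    if (is.na(x$AUC)) "NA" else sprintf("%.4f", x$AUC)))
  invisible(x)
}

#' Serialize a metrics report to a structured file
#'
#' @param report a `metrics_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  out <- list(ACC = report$ACC, SN = report$SN, SP = report$SP,
              Q = report$Q, MCC = report$MCC, error_rate = report$error_rate,
              AUC = report$AUC,
              counts = list(TP = report$counts$TP, TN = report$counts$TN,
                            FP = report$counts$FP, FN = report$counts$FN))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

# ---- ROC / AUC --------------------------------------------------------------

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the distinct scores (plus infinite sentinels) as thresholds
#' (predict positive when score >= threshold) and integrates the curve by the
#' trapezoid rule, which equals the probability that a random positive
#' outscores a random negative with ties counted one half.
#'
#' @param scores real-valued classifier scores (higher = more amyloid-like).
#' @param y_true true class labels; both classes must be present.
#' @return list with `roc` (data frame: `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, y_true) {
  yt <- .label_factor(y_true)
  if (anyNA(yt)) stop("labels outside the two classes")
  if (length(scores) != length(yt)) stop("scores/labels length mismatch")
  n_pos <- sum(yt == LABEL_POSITIVE)
  n_neg <- sum(yt == LABEL_NEGATIVE)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC is undefined: only one class present in the truth")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- t(vapply(thr, function(th) {
    pred_pos <- scores >= th
    c(fpr = sum(pred_pos & yt == LABEL_NEGATIVE) / n_neg,
      tpr = sum(pred_pos & yt == LABEL_POSITIVE) / n_pos)
  }, numeric(2)))
  roc <- data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                              utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Write ROC points as a two-column CSV (FPR, TPR)
#'
#' @param roc the `roc` data frame from [roc_auc()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roc_points <- function(roc, path) {
  utils::write.table(roc[, c("fpr", "tpr")], path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- cross-validation -------------------------------------------------------

#' Stratified k-fold cross-validation
#'
#' Shuffles each class separately (seeded) and deals records round-robin into
#' k folds, so per-fold class ratios stay within one record of the global
#' ratio. Each fold is validated once against a model trained on the
#' remaining k-1 folds; the pooled report is computed from the summed
#' confusion counts of all folds and labelled as pooled.
#'
#' @param X labelled `feature_matrix` (or matrix + `labels`).
#' @param labels labels when `X` is a plain matrix.
#' @param config a [train_config()] (its `k` is used unless `k` is given).
#' @param k fold count (>= 2); every class must have at least k records.
#' @param seed integer seed for the fold shuffle.
#' @return a `cv_result`: `k`, `fold_reports` (list of `metrics_report`),
#'   `pooled` (metrics from summed counts), `assignment` (fold id per row),
#'   `scores` (out-of-fold scores).
#' @export
kfold_cv <- function(X, labels = NULL, config = train_config(),
                     k = config$k, seed = config$seed) {
  d <- .as_xy(X, labels)
  if (is.null(d$y)) stop("labels are required for cross-validation")
  stopifnot(k >= 2)
  cc <- table(d$y)
  if (any(cc < k)) {
    stop("every class needs at least k = ", k, " records; counts: ",
         paste(sprintf("%s=%d", names(cc), cc), collapse = ", "))
  }
  fold <- integer(nrow(d$x))
  withr::with_seed(seed, {
    for (cl in LABEL_LEVELS) {
      idx <- sample(which(d$y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold_reports <- vector("list", k)
  scores <- numeric(nrow(d$x))
  preds <- character(nrow(d$x))
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- fit_classifier(d$x[tr, , drop = FALSE], d$y[tr], config)
    p <- predict_classifier(model, d$x[!tr, , drop = FALSE])
    scores[!tr] <- p$score
    preds[!tr] <- as.character(p$labels)
    fold_reports[[f]] <- metrics(confusion(d$y[!tr], p$labels))
  }
  pooled_cm <- confusion(d$y, preds)
  pooled_auc <- roc_auc(scores, d$y)$auc
  structure(list(k = as.integer(k),
                 fold_reports = fold_reports,
                 pooled = metrics(pooled_cm, auc = pooled_auc),
                 assignment = fold,
                 scores = scores),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (pooled counts):\n", x$k))
  print(x$pooled)
  invisible(x)
}

# ---- robustness protocol ----------------------------------------------------

#' Repeated random-rebuild robustness protocol
#'
#' For each train/test pair: recompute all descriptors, train the configured
#' classifier on the training set, and evaluate it both on the training set
#' itself (the validation phase of the protocol) and on the disjoint test
#' set; then average ACC, SN and SP over the pairs for both phases.
#'
#' @param pairs list of pairs from [make_robustness_pairs()].
#' @param descriptors a [descriptor_config()].
#' @param train a [train_config()].
#' @param tables a [property_tables()] bundle.
#' @param verbose print one progress line per pair.
#' @return a `robustness_result`: `per_pair` (data frame of ACC/SN/SP per
#'   phase) and `averages` (named vector of the six means, in percent).
#' @export
robustness_run <- function(pairs, descriptors = descriptor_config(),
                           train = train_config(),
                           tables = property_tables(), verbose = FALSE) {
  stopifnot(length(pairs) >= 1)
  rows <- lapply(pairs, function(pair) {
    res <- tryCatch({
      fm_train <- extract_all(pair$train, descriptors, tables)
      fm_test <- extract_all(pair$test, descriptors, tables)
      model <- fit_classifier(fm_train, config = train)
      val <- metrics(confusion(fm_train$labels,
                               predict_classifier(model, fm_train)$labels))
      tst <- metrics(confusion(fm_test$labels,
                               predict_classifier(model, fm_test)$labels))
      data.frame(pair = pair$index,
                 val_ACC = val$ACC, val_SN = val$SN, val_SP = val$SP,
                 test_ACC = tst$ACC, test_SN = tst$SN, test_SP = tst$SP)
    }, error = function(e) {
      stop("robustness pair ", pair$index, ": ", conditionMessage(e),
           call. = FALSE)
    })
    if (verbose) {
      message(sprintf("pair %d: val ACC %.3f, test ACC %.3f",
                      pair$index, res$val_ACC, res$test_ACC))
    }
    res
  })
  per_pair <- do.call(rbind, rows)
  averages <- 100 * colMeans(per_pair[, -1, drop = FALSE])
  structure(list(per_pair = per_pair, averages = averages),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("robustness over %d pairs (averages, %%):\n",
              nrow(x$per_pair)))
  # Table layout: metric x phase
  m <- matrix(c(x$averages["val_ACC"], x$averages["test_ACC"],
                x$averages["val_SN"], x$averages["test_SN"],
                x$averages["val_SP"], x$averages["test_SP"]),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("Average of ACC", "Average of SN",
                                "Average of SP"),
                              c("Validation", "Test")))
  print(round(m, 2))
  invisible(x)
}
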