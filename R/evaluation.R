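# Confusion-matrix metrics, ROC/AUC and cross-validated reports.

#' Confusion matrix from binary truth and prediction
#'
#' @param y_true,y_pred Equal-length binary vectors.
#' @return Object of class `confusion_matrix`: list with `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop_invalid("y_true and y_pred lengths differ")
  if (anyNA(y_true) || anyNA(y_pred) ||
      !all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L))) {
    stop_invalid("labels must be binary (0/1) with no missing values")
  }
  structure(list(
    tp = sum(y_true == 1L & y_pred == 1L),
    tn = sum(y_true == 0L & y_pred == 0L),
    fp = sum(y_true == 0L & y_pred == 1L),
    fn = sum(y_true == 1L & y_pred == 0L)
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix: TP=%d TN=%d FP=%d FN=%d\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' Accuracy = (TP + TN) / (TP + FP + TN + FN), sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP). A rate whose denominator is zero is
#' reported as `NA` (missing), not as 0.
#'
#' @param cm A [confusion()] result.
#' @return List with `accuracy`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0L) stop_invalid("empty confusion matrix")
  list(
    accuracy = (cm$tp + cm$tn) / total,
    sensitivity = if (cm$tp + cm$fn > 0L) cm$tp / (cm$tp + cm$fn) else NA_real_,
    specificity = if (cm$tn + cm$fp > 0L) cm$tn / (cm$tn + cm$fp) else NA_real_
  )
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores in descending order
#' (one ROC vertex per unique score, so tied scores are grouped), plots true
#' positive rate against false positive rate from (0, 0) to (1, 1), and
#' integrates by the trapezoidal rule.
#'
#' @param y_true Binary truth vector containing both classes.
#' @param probabilities Numeric scores (higher = more likely positive).
#' @return List of class `roc_curve` with `points` (data frame `fpr`, `tpr`,
#'   `threshold`) and `auc`.
#' @export
roc_auc <- function(y_true, probabilities) {
  y_true <- as.integer(y_true)
  s <- as.numeric(probabilities)
  if (length(y_true) != length(s)) stop_invalid("lengths differ")
  if (anyNA(y_true) || anyNA(s)) stop_invalid("missing values are not supported")
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    bow_stop("AUC is undefined when only one class is present", "bow_undefined_auc")
  }
  ord <- order(s, decreasing = TRUE)
  su <- s[ord]
  yu <- y_true[ord]
  grp <- cumsum(!duplicated(su))
  tp_by <- tapply(yu == 1L, grp, sum)
  fp_by <- tapply(yu == 0L, grp, sum)
  tpr <- c(0, cumsum(tp_by) / n_pos)
  fpr <- c(0, cumsum(fp_by) / n_neg)
  thr <- c(Inf, su[!duplicated(su)])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
                 auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve with %d vertices, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Plot method for ROC curves
#' @param x A `roc_curve`.
#' @param ... Passed to [plot()].
#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Cross-validated evaluation of a classifier on a fixed feature matrix
#'
#' Trains the specified classifier on each training fold and scores the held
#' out fold. Per-fold confusion metrics use the strict 0.5 threshold rule;
#' the overall ROC/AUC pools the out-of-fold scores (each pair is scored
#' exactly once).
#'
#' @param spec A [classifier_spec()].
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param folds Integer fold ids from [kfold()].
#' @return Object of class `metrics_report`: per-fold metrics, pooled
#'   metrics, ROC points and AUC, out-of-fold scores.
#' @export
crossval_report <- function(spec, X, y, folds) {
  X <- as.matrix(X)
  y <- as.integer(y)
  folds <- as.integer(folds)
  if (length(folds) != length(y) || nrow(X) != length(y)) {
    stop_invalid("folds must assign one fold id per row of X / element of y")
  }
  ids <- sort(unique(folds))
  scores <- rep(NA_real_, length(y))
  fold_metrics <- vector("list", length(ids))
  for (fi in seq_along(ids)) {
    test <- folds == ids[fi]
    model <- train_classifier(spec, X[!test, , drop = FALSE], y[!test])
    p <- as.numeric(predict_proba(model, X[test, , drop = FALSE]))
    scores[test] <- p
    mm <- classification_metrics(confusion(y[test], classify(p)))
    fold_metrics[[fi]] <- c(fold = ids[fi], n = sum(test), unlist(mm))
  }
  roc <- roc_auc(y, scores)
  pooled <- classification_metrics(confusion(y, classify(scores)))
  structure(list(
    classifier = spec$name, seed = spec$seed, k = length(ids),
    fold_metrics = as.data.frame(do.call(rbind, fold_metrics)),
    accuracy = pooled$accuracy, sensitivity = pooled$sensitivity,
    specificity = pooled$specificity,
    roc = roc$points, auc = roc$auc, scores = scores, y = y
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated report for '%s'\n", x$k, x$classifier))
  cat(sprintf("  pooled AUC %.4f | accuracy %.4f | sensitivity %.4f | specificity %.4f\n",
              x$auc, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Serialize a metrics report as JSON
#' @param report A `metrics_report`.
#' @param path Output path.
#' @param extra Named list merged into the output (e.g. run manifest data).
#' @export
write_metrics_report <- function(report, path, extra = list()) {
  obj <- list(classifier = report$classifier, seed = report$seed, k = report$k,
              auc = report$auc, accuracy = report$accuracy,
              sensitivity = report$sensitivity, specificity = report$specificity,
              fold_metrics = report$fold_metrics, roc = report$roc)
  jsonlite::write_json(c(obj, extra), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}
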