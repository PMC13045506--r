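# Evaluation battery: confusion matrix, Top-1 accuracy, per-class precision /
# one-vs-rest accuracy / recall / F1, and one-vs-rest ROC-AUC with micro,
# macro and class-proportion-weighted averaging.

STAGE_NAMES <- c("Tillering", "Mid Vegetative", "Booting", "Heading", "Milking")

check_labels <- function(y, k, what) {
  bad <- which(!(y %in% 0:(k - 1L)))
  if (length(bad)) {
    stop(what, " contains label ", y[bad[1]], " out of range [0, ", k,
         ") at index ", bad[1])
  }
  invisible(y)
}

#' Confusion matrix
#'
#' Tallies `counts[t, p] = #\{j : y_true_j = t, y_pred_j = p\}` with rows as
#' the true class and columns as the predicted class.
#'
#' @param y_true,y_pred integer vectors of 0-based class labels.
#' @param k number of classes.
#' @return a `wheat_confusion` integer matrix `[k, k]` with per-class
#'   `tp/fp/fn/tn` attached as an attribute.
#' @export
confusion_matrix <- function(y_true, y_pred, k) {
  stopifnot(length(y_true) == length(y_pred))
  check_labels(y_true, k, "y_true")
  check_labels(y_pred, k, "y_pred")
  cm <- matrix(0L, k, k, dimnames = list(true = 0:(k - 1L),
                                         pred = 0:(k - 1L)))
  for (j in seq_along(y_true)) {
    cm[y_true[j] + 1L, y_pred[j] + 1L] <- cm[y_true[j] + 1L, y_pred[j] + 1L] + 1L
  }
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- sum(cm) - tp - fp - fn
  structure(cm, counts = data.frame(class = 0:(k - 1L), tp = tp, fp = fp,
                                    fn = fn, tn = tn, row.names = NULL),
            class = c("wheat_confusion", "matrix", "array"))
}

#' Top-1 accuracy
#'
#' Fraction of samples whose predicted class equals the true class
#' (equivalently `trace(CM) / M`).
#'
#' @param y_true,y_pred integer label vectors.
#' @return scalar in `[0, 1]`.
#' @export
top1_accuracy <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) == 0L) stop("cannot compute accuracy on empty input")
  mean(y_true == y_pred)
}

#' Per-class precision, one-vs-rest accuracy, recall and F1
#'
#' One-vs-rest decomposition of a confusion matrix:
#' precision `TP/(TP+FP)`, OvR accuracy `(TP+TN)/M`, recall `TP/(TP+FN)`,
#' F1 the harmonic mean of precision and recall. A zero denominator yields 0
#' with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @return data frame with one row per class.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "wheat_confusion"))
  ct <- attr(cm, "counts")
  m <- sum(cm)
  safe_div <- function(num, den, what) {
    out <- numeric(length(num))
    zero <- den == 0
    if (any(zero)) {
      warning("zero denominator for ", what, " in class(es) ",
              paste(ct$class[zero], collapse = ", "), "; reporting 0")
    }
    out[!zero] <- num[!zero] / den[!zero]
    out
  }
  precision <- safe_div(ct$tp, ct$tp + ct$fp, "precision")
  recall <- safe_div(ct$tp, ct$tp + ct$fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  data.frame(class = ct$class,
             precision = precision,
             ovr_accuracy = (ct$tp + ct$tn) / m,
             recall = recall,
             f1 = f1,
             row.names = NULL)
}

# Rank-based binary AUC (Mann-Whitney with mid-rank ties), equivalent to
# trapezoidal integration of the ROC curve.
binary_auc <- function(labels, scores) {
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# ROC curve points (FPR, TPR) at every distinct threshold, descending.
roc_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]
  scores <- scores[ord]
  keep <- c(diff(scores) != 0, TRUE)
  tpr <- cumsum(labels)[keep] / max(1L, sum(labels))
  fpr <- cumsum(!labels)[keep] / max(1L, sum(!labels))
  data.frame(threshold = c(Inf, scores[keep]),
             fpr = c(0, fpr), tpr = c(0, tpr))
}

#' One-vs-rest ROC-AUC with micro, macro and weighted averaging
#'
#' Each class is scored one-vs-rest with a rank-based AUC (mid-rank tie
#' handling). The macro average is the unweighted mean over classes present
#' in `y_true`; the micro average pools all `M*K` binary indicator/score
#' pairs into one task; the weighted average is
#' `sum(auc_i * p(c_i))` with `p(c_i)` the class frequency in `y_true`.
#' Classes with no positives or no negatives have undefined AUC and are
#' excluded from the macro and weighted averages with a warning.
#'
#' @param y_true integer labels (0-based).
#' @param scores numeric matrix `[M, K]` of class scores per sample.
#' @return list with `auc` (per class), `auc_micro`, `auc_macro`,
#'   `auc_weighted_ovr`, `proportions` and per-class `curves`.
#' @export
roc_auc_ovr <- function(y_true, scores) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(y_true), all(is.finite(scores)))
  k <- ncol(scores)
  check_labels(y_true, k, "y_true")
  auc <- numeric(k)
  curves <- vector("list", k)
  for (i in seq_len(k)) {
    pos <- y_true == (i - 1L)
    auc[i] <- binary_auc(pos, scores[, i])
    curves[[i]] <- roc_points(pos, scores[, i])
  }
  undef <- is.na(auc)
  if (any(undef)) {
    warning("AUC undefined for class(es) ",
            paste(which(undef) - 1L, collapse = ", "),
            " (no positives or no negatives); excluded from averages")
  }
  prop <- tabulate(y_true + 1L, nbins = k) / length(y_true)
  present <- prop > 0 & !undef
  flat_labels <- as.vector(outer(y_true, 0:(k - 1L), "=="))
  auc_micro <- binary_auc(flat_labels, as.vector(scores))
  auc_macro <- mean(auc[present])
  wp <- prop[present] / sum(prop[present])
  auc_weighted <- sum(auc[present] * wp)
  names(auc) <- names(curves) <- paste0("class", 0:(k - 1L))
  list(auc = auc, auc_micro = auc_micro, auc_macro = auc_macro,
       auc_weighted_ovr = auc_weighted, proportions = prop, curves = curves)
}

#' Full metric report
#'
#' Combines the confusion matrix, Top-1 accuracy, the per-class battery and
#' the one-vs-rest AUC summary into a single report object.
#'
#' @param y_true integer labels (0-based).
#' @param scores numeric matrix `[M, K]` of class scores; predictions are the
#'   per-row argmax (lowest index on ties).
#' @param class_names optional display names, defaults to the five wheat
#'   stage names when `K = 5`.
#' @return a `wheat_metric_report` list.
#' @export
metric_report <- function(y_true, scores, class_names = NULL) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  if (is.null(class_names)) {
    class_names <- if (k == 5L) STAGE_NAMES else paste0("class", 0:(k - 1L))
  }
  y_pred <- max.col(scores, ties.method = "first") - 1L
  cm <- confusion_matrix(y_true, y_pred, k)
  per_class <- per_class_metrics(cm)
  per_class$name <- class_names
  auc <- roc_auc_ovr(y_true, scores)
  per_class$auc <- unname(auc$auc)
  structure(list(confusion = cm,
                 top1 = top1_accuracy(y_true, y_pred),
                 per_class = per_class,
                 macro_f1 = mean(per_class$f1),
                 proportions = auc$proportions,
                 auc_micro = auc$auc_micro,
                 auc_macro = auc$auc_macro,
                 auc_weighted_ovr = auc$auc_weighted_ovr,
                 curves = auc$curves,
                 class_names = class_names,
                 n = length(y_true)),
            class = "wheat_metric_report")
}

#' @export
print.wheat_metric_report <- function(x, ...) {
  cat("Growth-stage classification report (", x$n, " samples)\n", sep = "")
  cat(sprintf("  Top-1 accuracy : %.4f\n", x$top1))
  cat(sprintf("  Macro-F1       : %.4f\n", x$macro_f1))
  cat(sprintf("  AUC (micro/macro/weighted): %.4f / %.4f / %.4f\n",
              x$auc_micro, x$auc_macro, x$auc_weighted_ovr))
  pc <- x$per_class
  cat("  Per class:\n")
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("    %-14s P %.3f  R %.3f  F1 %.3f  OvR-acc %.3f  AUC %.3f\n",
                pc$name[i], pc$precision[i], pc$recall[i], pc$f1[i],
                pc$ovr_accuracy[i], pc$auc[i]))
  }
  invisible(x)
}

#' Write a metric report to disk
#'
#' Emits `report.json` (full report), `per_class.csv`, a confusion-matrix CSV
#' with stage-name header row/column, and optionally per-class ROC point
#' tables.
#'
#' @param report a [metric_report()].
#' @param dir output directory (created if missing).
#' @param roc_curves also write `roc_class<i>.csv` point tables.
#' @return `dir`, invisibly.
#' @export
write_metric_report <- function(report, dir, roc_curves = FALSE) {
  stopifnot(inherits(report, "wheat_metric_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cm <- matrix(as.integer(report$confusion), nrow(report$confusion))
  dimnames(cm) <- list(report$class_names, report$class_names)
  utils::write.csv(cm, file.path(dir, "confusion_matrix.csv"))
  utils::write.csv(report$per_class, file.path(dir, "per_class.csv"),
                   row.names = FALSE)
  payload <- list(top1 = report$top1,
                  macro_f1 = report$macro_f1,
                  auc_micro = report$auc_micro,
                  auc_macro = report$auc_macro,
                  auc_weighted_ovr = report$auc_weighted_ovr,
                  proportions = report$proportions,
                  per_class = report$per_class,
                  confusion = cm,
                  n = report$n)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  if (roc_curves) {
    for (i in seq_along(report$curves)) {
      utils::write.csv(report$curves[[i]],
                       file.path(dir, sprintf("roc_class%d.csv", i - 1L)),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}
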