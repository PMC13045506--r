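# Metric battery against hand-tallied examples, brute-force pair-counting
# oracles and (for AUC) an independent reference implementation.

# Exhaustive pairwise AUC oracle: concordant pairs + half ties over all
# positive-negative pairs.
pair_auc <- function(labels, scores) {
  pos <- scores[labels]
  neg <- scores[!labels]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

test_that("confusion matrix tallies the worked example and its equivariances", {
  y_true <- c(0L, 0L, 1L, 2L, 2L)
  y_pred <- c(0L, 1L, 1L, 2L, 0L)
  cm <- confusion_matrix(y_true, y_pred, 3L)
  expect_equal(unclass(cm)[, ], matrix(c(1, 0, 1, 1, 1, 0, 0, 0, 1), 3,
                                       dimnames = dimnames(cm)))
  counts <- attr(cm, "counts")
  expect_true(all(counts$tp + counts$fp + counts$fn + counts$tn == 5))

  perfect <- confusion_matrix(y_true, y_true, 3L)
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))

  # relabeling by a permutation permutes rows and columns the same way:
  # cm'(perm(t), perm(p)) = cm(t, p)
  perm <- c(2L, 0L, 1L)
  cmp <- confusion_matrix(perm[y_true + 1L], perm[y_pred + 1L], 3L)
  expect_equal(unclass(cmp)[perm + 1L, perm + 1L][, ],
               unclass(cm)[, ], ignore_attr = TRUE)

  expect_error(confusion_matrix(c(0L, 3L), c(0L, 0L), 3L),
               "label 3 out of range.*index 2")
})

test_that("top-1 accuracy equals the indicator mean and the confusion-matrix trace", {
  y_true <- c(0L, 0L, 1L, 2L, 2L)
  y_pred <- c(0L, 1L, 1L, 2L, 0L)
  expect_equal(top1_accuracy(y_true, y_pred), 0.6)
  expect_equal(top1_accuracy(y_true, y_true), 1.0)
  expect_equal(top1_accuracy(c(0L, 1L), c(1L, 0L)), 0.0)
  expect_error(top1_accuracy(integer(0), integer(0)), "empty")
  set.seed(51)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    yt <- sample(0:(k - 1L), 12, replace = TRUE)
    yp <- sample(0:(k - 1L), 12, replace = TRUE)
    cm <- confusion_matrix(yt, yp, k)
    expect_equal(top1_accuracy(yt, yp), sum(diag(cm)) / sum(cm))
  }
})

test_that("per-class metrics match hand counting and handle degenerate classes", {
  cm <- confusion_matrix(c(0L, 0L, 1L, 2L, 2L), c(0L, 1L, 1L, 2L, 0L), 3L)
  pc <- per_class_metrics(cm)
  expect_equal(pc$precision[1], 0.5)
  expect_equal(pc$recall[1], 0.5)
  expect_equal(pc$f1[1], 0.5)
  expect_equal(pc$ovr_accuracy[1], 0.6)

  diagonal <- confusion_matrix(c(0L, 1L, 2L), c(0L, 1L, 2L), 3L)
  pcd <- per_class_metrics(diagonal)
  expect_true(all(pcd$precision == 1 & pcd$recall == 1 & pcd$f1 == 1 &
                    pcd$ovr_accuracy == 1))

  # class 2 absent from truth and prediction: convention 0, OvR accuracy 1
  absent <- confusion_matrix(c(0L, 1L), c(0L, 1L), 3L)
  w <- capture_warnings(pca <- per_class_metrics(absent))
  expect_match(w, "zero denominator", all = FALSE)
  expect_equal(pca$precision[3], 0)
  expect_equal(pca$recall[3], 0)
  expect_equal(pca$f1[3], 0)
  expect_equal(pca$ovr_accuracy[3], 1)
})

test_that("rank-based AUC matches the hand-derived example and tie conventions", {
  # y = (0,0,1); class-1 scores (0.2, 0.8, 0.6): one concordant, one
  # discordant of the 2 positive-negative pairs
  res <- roc_auc_ovr(c(0L, 0L, 1L),
                     cbind(c(0.8, 0.2, 0.4), c(0.2, 0.8, 0.6)))
  expect_equal(unname(res$auc[2]), 0.5)
  # identical score rows: mid-rank ties give 0.5
  res2 <- roc_auc_ovr(c(0L, 1L), matrix(0.5, 2, 2))
  expect_equal(unname(res2$auc), c(0.5, 0.5))
  # perfectly separating scores give 1 everywhere
  y <- c(0L, 0L, 1L, 1L, 2L)
  s <- t(vapply(y, function(cl) {
    v <- c(0.1, 0.1, 0.1)
    v[cl + 1] <- 0.9
    v
  }, numeric(3)))
  res3 <- roc_auc_ovr(y, s)
  expect_equal(unname(res3$auc), c(1, 1, 1))
  expect_equal(res3$auc_micro, 1)
  expect_equal(res3$auc_macro, 1)
  expect_equal(res3$auc_weighted_ovr, 1)
})

test_that("metric battery agrees with brute-force oracles on 200 random small instances", {
  set.seed(52)
  for (i in 1:200) {
    k <- sample(2:3, 1)
    m <- sample(3:12, 1)
    y <- sample(0:(k - 1L), m, replace = TRUE)
    scores <- matrix(stats::runif(m * k), m, k)
    if (i %% 3 == 0) scores <- round(scores, 1)  # provoke ties
    pred <- max.col(scores, ties.method = "first") - 1L

    expect_equal(top1_accuracy(y, pred), mean(y == pred))
    cm <- confusion_matrix(y, pred, k)
    tally <- matrix(0L, k, k)
    for (j in seq_len(m)) tally[y[j] + 1, pred[j] + 1] <- tally[y[j] + 1, pred[j] + 1] + 1L
    expect_equal(unclass(cm)[, ], tally, ignore_attr = TRUE)

    suppressWarnings({
      res <- roc_auc_ovr(y, scores)
      for (cl in seq_len(k)) {
        expect_equal(unname(res$auc[cl]), pair_auc(y == (cl - 1L), scores[, cl]),
                     label = sprintf("instance %d class %d", i, cl))
      }
      flat <- pair_auc(as.vector(outer(y, 0:(k - 1L), "==")),
                       as.vector(scores))
      expect_equal(res$auc_micro, flat)
    })
  }
})

test_that("AUC agrees with an independent reference implementation and is invariant to monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(53)
  y <- sample(0:2, 60, replace = TRUE)
  scores <- matrix(runif(180), 60, 3)
  res <- roc_auc_ovr(y, scores)
  for (cl in 1:3) {
    ref <- pROC::auc(pROC::roc(response = as.integer(y == (cl - 1L)),
                               predictor = scores[, cl], quiet = TRUE,
                               direction = "<"))
    expect_equal(unname(res$auc[cl]), as.numeric(ref), tolerance = 1e-12)
  }
  trans <- roc_auc_ovr(y, exp(3 * scores))  # strictly increasing transform
  expect_equal(trans$auc, res$auc, tolerance = 1e-12)
})

test_that("weighted AUC is the class-proportion mix and collapses when all classes agree", {
  set.seed(54)
  y <- c(rep(0L, 6), rep(1L, 3), rep(2L, 1))
  scores <- matrix(runif(30), 10, 3)
  res <- roc_auc_ovr(y, scores)
  expect_equal(res$auc_weighted_ovr,
               sum(res$auc * res$proportions), tolerance = 1e-9)
  expect_equal(res$auc_macro, mean(res$auc))
  # all-equal per-class AUCs: weighted equals that common value regardless
  # of the proportions (tested via the formula on synthetic aucs)
  a <- 0.87
  p <- c(0.6, 0.3, 0.1)
  expect_equal(sum(rep(a, 3) * p), a)
})

test_that("a full report is internally consistent, prints, and writes its files", {
  set.seed(55)
  y <- sample(0:4, 80, replace = TRUE)
  scores <- matrix(runif(80 * 5), 80, 5)
  scores[cbind(seq_len(80), y + 1L)] <- scores[cbind(seq_len(80), y + 1L)] + 0.6
  rep <- metric_report(y, scores)
  expect_s3_class(rep, "wheat_metric_report")
  expect_equal(rep$macro_f1, mean(rep$per_class$f1))
  expect_equal(sum(rep$proportions), 1)
  expect_true(all(unlist(rep$per_class[, c("precision", "recall", "f1",
                                           "ovr_accuracy", "auc")]) >= 0))
  expect_output(print(rep), "Top-1 accuracy")
  dir <- withr::local_tempdir()
  write_metric_report(rep, dir, roc_curves = TRUE)
  expect_true(file.exists(file.path(dir, "confusion_matrix.csv")))
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "roc_class4.csv")))
  cm <- utils::read.csv(file.path(dir, "confusion_matrix.csv"), row.names = 1)
  expect_equal(rownames(cm)[1], "Tillering")
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$top1, rep$top1)
})
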