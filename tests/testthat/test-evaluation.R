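test_that("confusion matrix counts true/predicted pairs in fixed order", {
  true <- c("BCC", "BCC", "SCC", "melanoma")
  pred <- c("BCC", "SCC", "SCC", "melanoma")
  cm <- confusion_matrix(true, pred)
  expect_equal(sum(cm), 4L)
  expect_equal(cm["BCC", "BCC"], 1L)
  expect_equal(cm["BCC", "SCC"], 1L)
  expect_identical(rownames(cm), tissue_classes())
  # perfect predictions give a diagonal matrix
  cmd <- confusion_matrix(true, true)
  expect_true(all(cmd[upper.tri(cmd) | lower.tri(cmd)] == 0L))
  expect_error(confusion_matrix(c("BCC", "weird"), c("BCC", "BCC")),
               "unknown")
  expect_error(confusion_matrix("BCC", c("BCC", "BCC")), "equal length")
})

test_that("label pairs reproducing the published matrix recover it", {
  cm0 <- published_confusion()
  true <- rep(rownames(cm0), rowSums(cm0))
  pred <- unlist(lapply(seq_len(nrow(cm0)), function(i) {
    rep(colnames(cm0), cm0[i, ])
  }))
  expect_equal(confusion_matrix(true, pred), cm0)
})

test_that("per-class metrics agree with a brute-force recount", {
  set.seed(21)
  true <- sample(tissue_classes(), 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.7, true,
                 sample(tissue_classes(), 200, replace = TRUE))
  cm <- confusion_matrix(true, pred)
  m <- precision_recall_f1(cm)
  for (cl in tissue_classes()) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    row <- m$per_class[m$per_class$class == cl, ]
    expect_equal(row$precision, tp / (tp + fp))
    expect_equal(row$recall, tp / (tp + fn))
    expect_equal(row$f1, 2 * tp / (2 * tp + fp + fn))
    expect_gte(row$f1, min(row$precision, row$recall))
    expect_lte(row$f1, max(row$precision, row$recall))
  }
  expect_equal(m$accuracy, mean(true == pred))
})

test_that("rounding is two decimals, half away from zero", {
  expect_equal(round_half_away(0.925), 0.93)
  expect_equal(round_half_away(0.9375), 0.94)
  expect_equal(round_half_away(0.005), 0.01)
  expect_equal(round_half_away(-0.005), -0.01)
  expect_equal(round_half_away(111 / 120), 0.93)
  expect_equal(round_half_away(0.8235294), 0.82)
})

test_that("degenerate matrices hit the documented conventions", {
  cmd <- diag(c(5L, 5L, 5L, 5L))
  dimnames(cmd) <- dimnames(published_confusion())
  m <- precision_recall_f1(cmd)
  expect_true(all(m$per_class$precision == 1))
  expect_true(all(m$per_class$f1 == 1))
  expect_equal(accuracy(cmd), 1)
  off <- matrix(c(0L, 3L, 3L, 0L), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(accuracy(off), 0)
  # zero denominator: class never predicted -> precision 0 with warning
  cm0 <- matrix(c(2L, 0L, 1L, 0L), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(m0 <- precision_recall_f1(cm0), "zero denominator")
  expect_equal(m0$per_class$precision[2], 0)
  expect_error(accuracy(matrix(0L, 2, 2)), "empty")
})

test_that("one-vs-rest AUC equals the Mann-Whitney pairwise oracle", {
  mw_auc <- function(pos_scores, neg_scores) {
    cmp <- outer(pos_scores, neg_scores,
                 function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(31)
  for (i in 1:10) {
    true <- sample(c("a", "b"), 40, replace = TRUE)
    s <- round(runif(40), 1)  # coarse scores force ties
    scores <- cbind(a = s, b = 1 - s)
    got <- roc_auc_ovr(true, scores, classes = c("a", "b"))
    expect_equal(got$auc[["a"]], mw_auc(s[true == "a"], s[true != "a"]))
    expect_equal(got$auc[["b"]],
                 mw_auc(1 - s[true == "b"], 1 - s[true != "b"]))
  }
})

test_that("AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  true <- sample(c("a", "b"), 60, replace = TRUE)
  s <- runif(60)
  got <- roc_auc_ovr(true, cbind(a = s, b = 1 - s), classes = c("a", "b"))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(true, levels = c("b", "a")), predictor = s,
    quiet = TRUE, direction = "<")))
  expect_equal(got$auc[["a"]], ref)
})

test_that("AUC is invariant under monotone score transforms and edge cases", {
  set.seed(35)
  true <- sample(c("a", "b"), 50, replace = TRUE)
  s <- runif(50)
  a1 <- roc_auc_ovr(true, cbind(a = s, b = -s), classes = c("a", "b"))$auc
  a2 <- roc_auc_ovr(true, cbind(a = exp(3 * s), b = -exp(3 * s)),
                    classes = c("a", "b"))$auc
  expect_equal(a1, a2)
  # perfectly separating scores
  true2 <- rep(c("a", "b"), each = 10)
  s2 <- c(runif(10, 0.8, 1), runif(10, 0, 0.2))
  perfect <- roc_auc_ovr(true2, cbind(a = s2, b = 1 - s2),
                         classes = c("a", "b"))
  expect_equal(unname(perfect$auc), c(1, 1))
  # absent class is NA and excluded from the mean with a warning
  expect_warning(
    miss <- roc_auc_ovr(rep("a", 10),
                        cbind(a = runif(10), b = runif(10), c = runif(10)),
                        classes = c("a", "b", "c")),
    "absent")
  expect_true(is.na(miss$auc[["b"]]))
})

test_that("label-independent scores give chance-level AUC at large n", {
  set.seed(37)
  n <- 4000
  true <- sample(c("a", "b"), n, replace = TRUE)
  s <- runif(n)
  got <- roc_auc_ovr(true, cbind(a = s, b = runif(n)),
                     classes = c("a", "b"))
  expect_lt(abs(got$auc[["a"]] - 0.5), 0.05)
})

test_that("the report directory is complete and reproducible", {
  cm <- published_confusion()
  m <- precision_recall_f1(cm)
  imp <- stats::setNames(rep(1 / 15, 15), mm_feature_names())
  auc <- list(auc = stats::setNames(c(0.999, 1, 1, 0.996), tissue_classes()),
              mean_auc = 0.999)
  d1 <- withr::local_tempdir()
  render_report(d1, cm, m, auc, imp)
  files <- c("confusion.csv", "metrics.csv", "auc.csv", "importance.csv",
             "importance_matrix.csv", "summary.log")
  expect_true(all(file.exists(file.path(d1, files))))
  met <- utils::read.csv(file.path(d1, "metrics.csv"))
  bcc <- met[met$class == "BCC", ]
  expect_equal(c(bcc$precision.rounded, bcc$recall.rounded, bcc$f1.rounded),
               c(0.81, 1.00, 0.90))
  rank_ <- utils::read.csv(file.path(d1, "importance.csv"))
  expect_equal(nrow(rank_), 15L)
  expect_true(!is.unsorted(rev(rank_$importance)))
  # rerun gives identical bytes
  d2 <- withr::local_tempdir()
  render_report(d2, cm, m, auc, imp)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
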