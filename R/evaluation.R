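#' Round half away from zero
#'
#' Presentation rounding used in all reported metrics: exact halves round
#' away from zero, so 0.925 prints as 0.93 and 0.9375 as 0.94 (base R's
#' `round()` rounds half to even). Raw values are always kept alongside the
#' rounded ones in machine output.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Confusion matrix with a fixed class order
#'
#' @param true,predicted Equal-length label vectors over `classes`.
#' @param classes Class order for rows/columns (default [tissue_classes()]).
#' @return `k x k` integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(true, predicted, classes = tissue_classes()) {
  true <- as.character(true)
  predicted <- as.character(predicted)
  if (length(true) != length(predicted)) {
    stop("true and predicted labels must have equal length")
  }
  unknown <- setdiff(unique(c(true, predicted)), classes)
  if (length(unknown)) {
    stop("unknown class label(s): ", paste(unknown, collapse = ", "))
  }
  cm <- table(factor(true, levels = classes),
              factor(predicted, levels = classes))
  m <- matrix(as.integer(cm), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' One-vs-rest reading of the matrix: for class c, TP is the diagonal entry,
#' FP the rest of column c, FN the rest of row c; precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 their harmonic mean. A zero denominator gives a 0
#' metric with a warning. Overall accuracy is trace/total. Rounded columns
#' use two decimals, half away from zero.
#'
#' @param cm Confusion matrix as from [confusion_matrix()].
#' @return List: `per_class` data frame (`class`, raw and `.rounded`
#'   precision/recall/f1), `accuracy`, `accuracy_rounded`.
#' @export
precision_recall_f1 <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0))
  classes <- rownames(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) {
      warning("zero denominator in ", what, " for class(es) ",
              paste(classes[den == 0], collapse = ", "),
              "; reporting 0")
    }
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(
    class = classes,
    precision = precision, recall = recall, f1 = f1,
    precision.rounded = round_half_away(precision),
    recall.rounded = round_half_away(recall),
    f1.rounded = round_half_away(f1),
    stringsAsFactors = FALSE, row.names = NULL
  )
  acc <- accuracy(cm)
  list(per_class = per_class, accuracy = acc,
       accuracy_rounded = round_half_away(acc))
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm Confusion matrix.
#' @return `trace / total` as a raw fraction (round with
#'   [round_half_away()] for presentation).
#' @export
accuracy <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  if (total == 0) stop("accuracy undefined for an empty confusion matrix")
  sum(diag(cm)) / total
}

#' One-vs-rest ROC AUC from vote fractions
#'
#' For each class, the ROC curve is traced over thresholds at the distinct
#' observed scores (that class's vote fraction), and the AUC obtained by
#' trapezoidal integration — equivalent to the Mann-Whitney probability that
#' a random positive outscores a random negative (ties counting 1/2). The
#' mean AUC is the unweighted average over classes; a class absent from the
#' true labels has undefined AUC, reported `NA` and dropped from the mean
#' with a warning.
#'
#' @param true True labels.
#' @param scores `n x k` matrix of per-class scores (vote fractions), with
#'   the class names as columns.
#' @param classes Class set (default the score columns).
#' @return List: `auc` named per-class vector, `mean_auc`.
#' @export
roc_auc_ovr <- function(true, scores, classes = colnames(scores)) {
  true <- as.character(true)
  scores <- as.matrix(scores)
  if (is.null(classes)) stop("scores must have class names as columns")
  stopifnot(length(true) == nrow(scores))
  auc <- vapply(classes, function(cl) {
    pos <- true == cl
    if (!any(pos) || all(pos)) return(NA_real_)
    s <- scores[, cl]
    # threshold sweep over distinct scores, descending
    thr <- sort(unique(s), decreasing = TRUE)
    tpr <- vapply(thr, function(t) mean(s[pos] >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(s[!pos] >= t), numeric(1))
    tpr <- c(0, tpr, 1)
    fpr <- c(0, fpr, 1)
    sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  }, numeric(1))
  names(auc) <- classes
  if (anyNA(auc)) {
    warning("AUC undefined for class(es) absent from the true labels: ",
            paste(classes[is.na(auc)], collapse = ", "),
            "; excluded from the mean")
  }
  list(auc = auc, mean_auc = mean(auc, na.rm = TRUE))
}

#' Write the full evaluation report to a directory
#'
#' Emits `confusion.csv`, `metrics.csv` (per-class precision/recall/F1 plus
#' accuracy), `auc.csv`, `importance.csv` (descending ranking), an
#' `importance_matrix.csv` in 4x4 Mueller layout (`m11` blank), and a
#' plain-text `summary.log`. Rerunning on the same inputs reproduces the
#' files byte for byte.
#'
#' @param dir Output directory (created if absent).
#' @param cm Confusion matrix.
#' @param metrics Result of [precision_recall_f1()] (computed from `cm` if
#'   omitted).
#' @param auc Optional result of [roc_auc_ovr()].
#' @param importance Optional named importance vector over
#'   [mm_feature_names()].
#' @return The directory path, invisibly.
#' @export
render_report <- function(dir, cm, metrics = precision_recall_f1(cm),
                          auc = NULL, importance = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- function(f) file.path(dir, f)
  utils::write.csv(as.data.frame(cm), path("confusion.csv"))
  met <- metrics$per_class
  utils::write.csv(met, path("metrics.csv"), row.names = FALSE)
  if (!is.null(auc)) {
    utils::write.csv(
      data.frame(class = c(names(auc$auc), "mean"),
                 auc = c(auc$auc, auc$mean_auc), row.names = NULL),
      path("auc.csv"), row.names = FALSE)
  }
  if (!is.null(importance)) {
    rank_df <- data.frame(element = names(sort(importance, decreasing = TRUE)),
                          importance = as.numeric(sort(importance,
                                                       decreasing = TRUE)))
    utils::write.csv(rank_df, path("importance.csv"), row.names = FALSE)
    m <- matrix(NA_real_, 4, 4,
                dimnames = list(paste0("row", 1:4), paste0("col", 1:4)))
    for (nm in names(importance)) {
      i <- as.integer(substr(nm, 2, 2))
      j <- as.integer(substr(nm, 3, 3))
      m[i, j] <- importance[[nm]]
    }
    utils::write.csv(as.data.frame(m), path("importance_matrix.csv"))
  }
  lines <- c(
    "muellerforest evaluation summary",
    sprintf("instances: %d", sum(cm)),
    sprintf("accuracy: %.4f (reported %.2f)", metrics$accuracy,
            metrics$accuracy_rounded),
    sprintf("%-10s precision %.2f recall %.2f F1 %.2f", met$class,
            met$precision.rounded, met$recall.rounded, met$f1.rounded)
  )
  if (!is.null(auc)) {
    lines <- c(lines, sprintf("mean AUC: %.3f", auc$mean_auc))
  }
  writeLines(lines, path("summary.log"))
  invisible(dir)
}
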