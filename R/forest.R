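#' Fit a Gini random forest to Mueller-matrix features
#'
#' Ensemble of CART classification trees, each grown on a bootstrap resample
#' (size n, with replacement) with a fresh random feature subset of size
#' `mtry` drawn at every node. Splitting maximizes the sample-proportion-
#' weighted Gini impurity decrease over thresholds at midpoints of
#' consecutive distinct sorted feature values; growth stops at purity,
#' `max_depth`, node size below `min_samples_split`, or when no split gives
#' a positive decrease. Prediction is by plurality vote of the trees, with
#' ties broken towards the first factor level (alphabetical for the default
#' tissue labels). Per-feature mean-decrease-in-impurity importances are
#' computed at fit time (see [feature_importance()]).
#'
#' @param x Numeric feature matrix or data frame (or a model formula).
#' @param y Class labels (factor or character); for the formula method taken
#'   from `data`.
#' @param ntree Number of trees (default 220).
#' @param max_depth Maximum tree depth; the root split counts as depth 1
#'   (default 14).
#' @param mtry Features sampled at each split; default
#'   `floor(sqrt(ncol(x)))`.
#' @param min_samples_split Minimum node size eligible for splitting
#'   (default 2).
#' @param bootstrap Grow each tree on a bootstrap resample (default `TRUE`);
#'   with `FALSE`, every tree sees the full data.
#' @param seed Optional integer seed; when given, fitting (and hence
#'   prediction and importance) is fully reproducible.
#' @param ... Passed between methods.
#' @return An object of class `mueller_forest` with components `trees`,
#'   `classes`, `importance`, and the hyperparameters.
#' @export
#' @examples
#' d <- generate_dataset(dataset_config(seed = 7))
#' fit <- mueller_forest(label ~ ., data = d$train[, c(4:19)],
#'                       ntree = 25, seed = 1)
#' fit
mueller_forest <- function(x, ...) UseMethod("mueller_forest")

#' @rdname mueller_forest
#' @param formula Model formula such as `label ~ .`.
#' @param data Data frame holding the response and features.
#' @export
mueller_forest.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- mf[, -1L, drop = FALSE]
  fit <- mueller_forest.default(x, y, ...)
  fit$call <- match.call()
  fit
}

#' @rdname mueller_forest
#' @export
mueller_forest.default <- function(x, y, ntree = 220L, max_depth = 14L,
                                   mtry = NULL, min_samples_split = 2L,
                                   bootstrap = TRUE, seed = NULL, ...) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing values in the feature matrix are not supported")
  if (!is.factor(y)) {
    # case-insensitive, locale-independent level order so that plurality
    # ties always break the same way (BCC < melanoma < normal < SCC)
    lv <- unique(as.character(y))
    y <- factor(y, levels = lv[order(tolower(lv), lv, method = "radix")])
  }
  y <- droplevels(y)
  if (length(y) != nrow(X)) stop("x and y must have matching row counts")
  if (nrow(X) == 0L) stop("cannot fit a forest on empty data")
  if (anyNA(y)) stop("missing class labels are not supported")
  ntree <- as.integer(ntree)
  max_depth <- as.integer(max_depth)
  if (ntree < 1L) stop("ntree must be at least 1")
  if (max_depth < 0L) stop("max_depth must be non-negative")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  mtry <- as.integer(mtry)
  if (mtry < 1L || mtry > ncol(X)) stop("mtry must lie in [1, ncol(x)]")
  if (!is.null(seed)) set.seed(as.integer(seed))

  classes <- levels(y)
  yi <- as.integer(y)
  k <- length(classes)
  n <- nrow(X)
  trees <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    trees[[t]] <- grow_tree(X, yi, idx = idx, k = k, max_depth = max_depth,
                            min_samples_split = min_samples_split,
                            mtry = mtry, n_total = n)
  }
  imp <- rowMeans(matrix(vapply(trees, tree_importance, numeric(ncol(X)),
                                p = ncol(X)), nrow = ncol(X)))
  if (sum(imp) > 0) imp <- imp / sum(imp)
  names(imp) <- colnames(X)
  structure(list(
    trees = trees, classes = classes, importance = imp,
    feature_names = colnames(X), n_features = ncol(X),
    ntree = ntree, max_depth = max_depth, mtry = mtry,
    min_samples_split = as.integer(min_samples_split),
    bootstrap = bootstrap, seed = seed, n_train = n,
    call = match.call()
  ), class = "mueller_forest")
}

#' Predict classes or vote fractions from a fitted forest
#'
#' @param object A [mueller_forest()] fit.
#' @param newdata Feature matrix or data frame with the training feature
#'   count (and names, if the fit had them).
#' @param type `"class"` for plurality-vote labels, `"vote"` for the matrix
#'   of per-class vote fractions (each row a probability vector used as the
#'   ROC score).
#' @param ... Unused.
#' @return Factor of predicted labels, or an `n x k` matrix of vote
#'   fractions.
#' @export
predict.mueller_forest <- function(object, newdata,
                                   type = c("class", "vote"), ...) {
  type <- match.arg(type)
  X <- as.matrix(if (is.data.frame(newdata) && !is.null(object$feature_names) &&
                     all(object$feature_names %in% names(newdata))) {
    newdata[, object$feature_names, drop = FALSE]
  } else {
    newdata
  })
  storage.mode(X) <- "double"
  if (ncol(X) != object$n_features) {
    stop("newdata has ", ncol(X), " features; the model was trained on ",
         object$n_features)
  }
  k <- length(object$classes)
  votes <- matrix(0L, nrow(X), k)
  for (tr in object$trees) {
    p <- predict_tree(tr, X)
    votes[cbind(seq_len(nrow(X)), p)] <- votes[cbind(seq_len(nrow(X)), p)] + 1L
  }
  frac <- votes / object$ntree
  colnames(frac) <- object$classes
  if (type == "vote") return(frac)
  factor(object$classes[max.col(frac, ties.method = "first")],
         levels = object$classes)
}

#' Mean-decrease-in-impurity feature importance
#'
#' For every tree, each feature's importance is the sum of the
#' sample-proportion-weighted Gini impurity decreases at the nodes splitting
#' on it, divided by the total decrease over all internal nodes of that
#' tree; the forest importance is the per-feature mean over trees,
#' renormalized to sum to 1. A tree with no internal node (a lone leaf)
#' contributes zeros.
#'
#' @param model A fitted [mueller_forest()].
#' @return Named numeric vector of importances summing to 1.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "mueller_forest"))
  model$importance
}

#' @export
print.mueller_forest <- function(x, ...) {
  cat("Gini random forest (", x$ntree, " trees, max depth ", x$max_depth,
      ", mtry ", x$mtry, ")\n", sep = "")
  cat("Classes:", paste(x$classes, collapse = ", "), "\n")
  cat("Trained on", x$n_train, "instances with", x$n_features, "features\n")
  top <- sort(x$importance, decreasing = TRUE)[seq_len(min(5L, x$n_features))]
  cat("Top features:",
      paste(sprintf("%s (%.1f%%)", names(top), 100 * top), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.mueller_forest <- function(object, ...) {
  depths <- vapply(object$trees, tree_depth, integer(1))
  leaves <- vapply(object$trees, function(tr) {
    sum(vapply(tr, function(nd) is.na(nd$feature), logical(1)))
  }, integer(1))
  out <- list(
    ntree = object$ntree, classes = object$classes,
    depth = summary(depths), leaves = summary(leaves),
    importance = sort(object$importance, decreasing = TRUE)
  )
  class(out) <- "summary.mueller_forest"
  out
}

#' @export
print.summary.mueller_forest <- function(x, ...) {
  cat("Gini random forest with", x$ntree, "trees\n")
  cat("Tree depth:\n"); print(x$depth)
  cat("Leaves per tree:\n"); print(x$leaves)
  cat("Feature importance (descending):\n")
  print(round(x$importance, 4))
  invisible(x)
}

#' Plot forest feature importances
#'
#' Horizontal bar chart of the mean-decrease-in-impurity importances in
#' descending order, the standard reading of which Mueller elements drive
#' the classification.
#'
#' @param x A fitted [mueller_forest()].
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.mueller_forest <- function(x, ...) {
  imp <- sort(x$importance)
  graphics::barplot(imp, horiz = TRUE, las = 1,
                    xlab = "mean decrease in impurity (normalized)",
                    main = "Feature importance", ...)
  invisible(x)
}

#' Serialize a fitted forest to JSON
#'
#' Writes the full tree structure (node ids, split rules, class counts,
#' children, leaf labels), hyperparameters, class levels and importance
#' vector. [read_forest_json()] restores an object giving identical
#' predictions.
#'
#' @param model A fitted [mueller_forest()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_forest_json <- function(model, path) {
  stopifnot(inherits(model, "mueller_forest"))
  payload <- list(
    format = "muellerforest/1",
    classes = model$classes,
    feature_names = model$feature_names,
    n_features = model$n_features,
    ntree = model$ntree, max_depth = model$max_depth, mtry = model$mtry,
    min_samples_split = model$min_samples_split,
    bootstrap = model$bootstrap, seed = model$seed, n_train = model$n_train,
    importance = as.numeric(model$importance),
    trees = lapply(model$trees, function(tr) {
      lapply(tr, function(nd) {
        nd[c("id", "n", "counts", "gini", "weight", "feature", "threshold",
             "left", "right", "decrease", "pred")]
      })
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Load a forest serialized by [write_forest_json()]
#'
#' @param path JSON file path.
#' @return A `mueller_forest` object.
#' @export
read_forest_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "muellerforest/1")) {
    stop("not a muellerforest model file: ", path)
  }
  as_scalar <- function(x, mode) if (is.null(x)) NA else as.vector(x, mode)
  trees <- lapply(payload$trees, function(tr) {
    lapply(tr, function(nd) {
      list(
        id = as.integer(nd$id), n = as.integer(nd$n),
        counts = as.numeric(unlist(nd$counts)),
        gini = as.numeric(nd$gini), weight = as.numeric(nd$weight),
        feature = as_scalar(nd$feature, "integer"),
        threshold = as_scalar(nd$threshold, "double"),
        left = as_scalar(nd$left, "integer"),
        right = as_scalar(nd$right, "integer"),
        decrease = as_scalar(nd$decrease, "double"),
        pred = as.integer(nd$pred)
      )
    })
  })
  imp <- as.numeric(unlist(payload$importance))
  names(imp) <- unlist(payload$feature_names)
  structure(list(
    trees = trees, classes = unlist(payload$classes), importance = imp,
    feature_names = unlist(payload$feature_names),
    n_features = as.integer(payload$n_features),
    ntree = as.integer(payload$ntree),
    max_depth = as.integer(payload$max_depth),
    mtry = as.integer(payload$mtry),
    min_samples_split = as.integer(payload$min_samples_split),
    bootstrap = isTRUE(payload$bootstrap),
    seed = if (is.null(payload$seed)) NULL else as.integer(payload$seed),
    n_train = as.integer(payload$n_train),
    call = quote(read_forest_json())
  ), class = "mueller_forest")
}
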