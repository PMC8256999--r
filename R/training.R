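# derive a stage seed from a master seed, kept within 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

#' Balance a dataset by random minority-class oversampling
#'
#' Randomly duplicates instances of every minority class (sampling with
#' replacement within the class) until each class count equals the majority
#' count; majority-class rows are untouched and no row is ever deleted.
#' Duplicating rows before cross-validation lets copies of one instance land
#' in different folds, which inflates validation scores — the workflow keeps
#' this order because it reproduces the study design, but see the `oversample`
#' flags of [run_pipeline()] to opt out.
#'
#' @param data Data frame with a class-label column.
#' @param label Name of the label column (default `"label"`).
#' @param seed Optional integer seed for the duplication draws.
#' @return The balanced data frame (original rows first, duplicates
#'   appended).
#' @export
#' @examples
#' d <- data.frame(label = rep(c("a", "b"), c(5, 2)), x = 1:7)
#' table(oversample(d, seed = 1)$label)
oversample <- function(data, label = "label", seed = NULL) {
  stopifnot(is.data.frame(data), label %in% names(data))
  y <- as.character(data[[label]])
  counts <- table(data[[label]])  # factor levels keep empty classes visible
  if (any(counts == 0L)) stop("every class must have at least one instance")
  if (!is.null(seed)) set.seed(as.integer(seed))
  target <- max(counts)
  extra <- lapply(names(counts), function(cl) {
    need <- target - counts[[cl]]
    if (need == 0L) return(NULL)
    pool <- which(y == cl)
    data[sample(pool, need, replace = TRUE), , drop = FALSE]
  })
  out <- rbind(data, do.call(rbind, extra))
  rownames(out) <- NULL
  out
}

#' Stratified k-fold assignment
#'
#' Partitions `n` instances into `k` folds of near-equal size, keeping each
#' class's instances spread as evenly as possible across folds.
#'
#' @param labels Class label per instance.
#' @param k Number of folds (default 10).
#' @param seed Optional integer seed.
#' @return Integer vector of fold ids in `1..k`, one per instance.
#' @export
kfold_indices <- function(labels, k = 10L, seed = NULL) {
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (n < k) stop("need at least k instances for k folds")
  if (!is.null(seed)) set.seed(as.integer(seed))
  fold <- integer(n)
  offset <- 0L
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    # rotate the starting fold per class so small classes don't all pile
    # into fold 1
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Repeated stratified k-fold cross-validation of the forest
#'
#' For each repetition, draws a fresh stratified fold assignment, then for
#' each fold fits a forest on the remaining k-1 folds and scores accuracy on
#' the held-out fold (and on the training folds themselves).
#'
#' @param x Feature matrix or data frame.
#' @param y Class labels.
#' @param ntree,max_depth,mtry Forest hyperparameters (see
#'   [mueller_forest()]).
#' @param k Folds (default 10).
#' @param reps Repetitions with distinct derived seeds (default 3).
#' @param seed Master seed (default 1).
#' @return List with `validation` and `training` `reps x k` accuracy
#'   matrices and their means `mean_validation`, `mean_training`.
#' @export
cross_validate <- function(x, y, ntree = 220L, max_depth = 14L, mtry = NULL,
                           k = 10L, reps = 3L, seed = 1L) {
  X <- as.matrix(x)
  y <- factor(y)
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be at least 1")
  val <- tr <- matrix(NA_real_, reps, k,
                      dimnames = list(paste0("rep", seq_len(reps)),
                                      paste0("fold", seq_len(k))))
  for (r in seq_len(reps)) {
    fold <- kfold_indices(y, k = k, seed = derive_seed(seed, r))
    for (f in seq_len(k)) {
      hold <- fold == f
      fit <- mueller_forest(X[!hold, , drop = FALSE], y[!hold],
                            ntree = ntree, max_depth = max_depth, mtry = mtry,
                            seed = derive_seed(seed, 1000L * r + f))
      val[r, f] <- mean(predict(fit, X[hold, , drop = FALSE]) == y[hold])
      tr[r, f] <- mean(predict(fit, X[!hold, , drop = FALSE]) == y[!hold])
    }
  }
  list(validation = val, training = tr,
       mean_validation = mean(val), mean_training = mean(tr))
}

#' Grid search over forest size and depth
#'
#' Scores every `(ntree, max_depth)` grid point by its mean repeated-CV
#' validation accuracy and returns the argmax; ties resolve to fewer trees,
#' then smaller depth, so the result does not depend on grid ordering.
#'
#' @param x,y Training features and labels.
#' @param ntree_grid Candidate tree counts (default `seq(10, 1000, 10)`).
#' @param depth_grid Candidate depths (default `2:20`).
#' @param k,reps,seed,mtry Passed to [cross_validate()].
#' @return List with `best` (named vector `ntree`, `max_depth`), `score`
#'   (its mean validation accuracy), and the full score `table`.
#' @export
grid_search <- function(x, y, ntree_grid = seq(10L, 1000L, 10L),
                        depth_grid = 2:20, k = 10L, reps = 3L, seed = 1L,
                        mtry = NULL) {
  if (!length(ntree_grid) || !length(depth_grid)) {
    stop("hyperparameter grids must be nonempty")
  }
  grid <- expand.grid(ntree = sort(unique(as.integer(ntree_grid))),
                      max_depth = sort(unique(as.integer(depth_grid))))
  grid$score <- vapply(seq_len(nrow(grid)), function(i) {
    cross_validate(x, y, ntree = grid$ntree[i], max_depth = grid$max_depth[i],
                   mtry = mtry, k = k, reps = reps,
                   seed = seed)$mean_validation
  }, numeric(1))
  ord <- order(-grid$score, grid$ntree, grid$max_depth)
  best <- grid[ord[1L], ]
  list(best = c(ntree = best$ntree, max_depth = best$max_depth),
       score = best$score, table = grid)
}

#' Oversample and fit the final classifier
#'
#' The deployment fit: balances the training set by [oversample()], then
#' fits a [mueller_forest()] at the chosen hyperparameters (defaults: 220
#' trees, depth 14).
#'
#' @param train Training feature data frame with a `label` column and the
#'   [mm_feature_names()] feature columns (extra provenance columns are
#'   ignored).
#' @param ntree,max_depth,mtry Forest hyperparameters.
#' @param seed Master seed driving both the oversampling and the fit.
#' @param balance Apply oversampling first (default `TRUE`).
#' @return The fitted `mueller_forest`.
#' @export
train_final <- function(train, ntree = 220L, max_depth = 14L, mtry = NULL,
                        seed = 1L, balance = TRUE) {
  stopifnot("label" %in% names(train))
  feats <- intersect(mm_feature_names(), names(train))
  if (!length(feats)) feats <- setdiff(names(train), "label")
  if (balance) train <- oversample(train, seed = derive_seed(seed, 17L))
  mueller_forest(train[, feats, drop = FALSE], train$label,
                 ntree = ntree, max_depth = max_depth, mtry = mtry,
                 seed = derive_seed(seed, 29L))
}
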