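test_that("a degenerate forest equals a single deterministic tree", {
  d <- toy_gaussian(n_per_class = 15, k = 3, seed = 2)
  f1 <- mueller_forest(d$x, d$y, ntree = 1, mtry = ncol(d$x),
                       bootstrap = FALSE, max_depth = 8)
  t1 <- muellerforest:::grow_tree(d$x, as.integer(d$y), k = 3L,
                                  max_depth = 8L)
  expect_equal(as.integer(predict(f1, d$x)),
               muellerforest:::predict_tree(t1, d$x))
  expect_equal(mean(predict(f1, d$x) == d$y), 1)
})

test_that("fitting and prediction are deterministic under a fixed seed", {
  d <- generate_dataset(small_config(seed = 11))
  x <- d$train[, mm_feature_names()]; y <- d$train$label
  xt <- d$test[, mm_feature_names()]
  a <- mueller_forest(x, y, ntree = 30, max_depth = 8, seed = 5)
  b <- mueller_forest(x, y, ntree = 30, max_depth = 8, seed = 5)
  expect_identical(predict(a, xt), predict(b, xt))
  expect_identical(a$importance, b$importance)
  c_ <- mueller_forest(x, y, ntree = 30, max_depth = 8, seed = 6)
  expect_false(identical(a$importance, c_$importance))
})

test_that("vote fractions are a probability vector per instance", {
  d <- generate_dataset(small_config(seed = 11))
  fit <- mueller_forest(d$train[, mm_feature_names()], d$train$label,
                        ntree = 40, max_depth = 8, seed = 1)
  v <- predict(fit, d$test[, mm_feature_names()], type = "vote")
  expect_equal(dim(v), c(nrow(d$test), 4L))
  expect_identical(colnames(v), tissue_classes())
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(unname(rowSums(v)), rep(1, nrow(v)))
  # the voted class is the plurality argmax of the fractions
  expect_identical(as.character(predict(fit, d$test[, mm_feature_names()])),
                   colnames(v)[max.col(v, ties.method = "first")])
})

test_that("unanimous trees give a vote fraction of one", {
  d <- toy_gaussian(n_per_class = 20, k = 2, sep = 6, sd = 0.3, seed = 4)
  fit <- mueller_forest(d$x, d$y, ntree = 15, max_depth = 6, seed = 1)
  v <- predict(fit, d$x, type = "vote")
  expect_true(all(apply(v, 1, max) == 1))
})

test_that("importance is normalized and one-hot for single-split trees", {
  # only feature 2 is informative; depth-1 trees must put all importance on it
  set.seed(9)
  x <- cbind(f1 = rep(0, 40), f2 = c(rnorm(20, 0), rnorm(20, 8)),
             f3 = rep(1, 40))
  y <- factor(rep(c("a", "b"), each = 20))
  fit <- mueller_forest(x, y, ntree = 10, max_depth = 1, mtry = 3, seed = 2)
  expect_equal(unname(fit$importance), c(0, 1, 0))
  expect_equal(sum(fit$importance), 1)
  # importance sums to one on real fits too
  d <- generate_dataset(small_config(seed = 11))
  f2 <- mueller_forest(d$train[, mm_feature_names()], d$train$label,
                       ntree = 25, max_depth = 10, seed = 3)
  expect_equal(sum(f2$importance), 1)
  expect_true(all(f2$importance >= 0))
  expect_identical(names(f2$importance), mm_feature_names())
})

test_that("importance is invariant to consistent positive feature scaling", {
  d <- generate_dataset(small_config(seed = 12))
  x <- as.matrix(d$train[, mm_feature_names()])
  y <- d$train$label
  sc <- 100
  a <- mueller_forest(x, y, ntree = 20, max_depth = 8, seed = 7)
  b <- mueller_forest(x * sc, y, ntree = 20, max_depth = 8, seed = 7)
  expect_equal(a$importance, b$importance)
  xt <- as.matrix(d$test[, mm_feature_names()])
  expect_identical(predict(a, xt), predict(b, xt * sc))
})

test_that("depth limit is respected everywhere", {
  d <- generate_dataset(small_config(seed = 11))
  fit <- mueller_forest(d$train[, mm_feature_names()], d$train$label,
                        ntree = 15, max_depth = 4, seed = 1)
  depths <- vapply(fit$trees, muellerforest:::tree_depth, integer(1))
  expect_true(all(depths <= 4L))
})

test_that("hyperparameter and input validation errors are raised", {
  d <- toy_gaussian(seed = 1)
  expect_error(mueller_forest(d$x, d$y, ntree = 0), "ntree")
  expect_error(mueller_forest(d$x, d$y, mtry = 99), "mtry")
  expect_error(mueller_forest(d$x, d$y[-1]), "matching")
  xna <- d$x; xna[1, 1] <- NA
  expect_error(mueller_forest(xna, d$y), "missing")
  fit <- mueller_forest(d$x, d$y, ntree = 5, seed = 1)
  expect_error(predict(fit, d$x[, 1, drop = FALSE]), "features")
})

test_that("JSON round trip preserves predictions and importance", {
  d <- generate_dataset(small_config(seed = 11))
  fit <- mueller_forest(d$train[, mm_feature_names()], d$train$label,
                        ntree = 12, max_depth = 6, seed = 4)
  path <- tempfile(fileext = ".json")
  write_forest_json(fit, path)
  back <- read_forest_json(path)
  xt <- d$test[, mm_feature_names()]
  expect_identical(predict(back, xt), predict(fit, xt))
  expect_equal(predict(back, xt, type = "vote"),
               predict(fit, xt, type = "vote"))
  expect_equal(back$importance, fit$importance)
  expect_identical(back$classes, fit$classes)
  suppressWarnings(expect_error(read_forest_json(tempfile())))
})

test_that("formula interface and methods work", {
  d <- generate_dataset(small_config(seed = 11))
  df <- d$train[, c("label", mm_feature_names())]
  fit <- mueller_forest(label ~ ., data = df, ntree = 10, max_depth = 6,
                        seed = 1)
  expect_s3_class(fit, "mueller_forest")
  expect_output(print(fit), "Gini random forest")
  expect_output(print(summary(fit)), "Feature importance")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("the bespoke forest matches a reference forest on held-out accuracy", {
  skip_if_not_installed("randomForest")
  d <- generate_dataset(small_config(seed = 11))
  x <- d$train[, mm_feature_names()]; y <- factor(d$train$label)
  xt <- d$test[, mm_feature_names()]; yt <- factor(d$test$label)
  ours <- mueller_forest(x, y, ntree = 100, max_depth = 14, mtry = 3,
                         seed = 1)
  acc_ours <- mean(predict(ours, xt) == yt)
  set.seed(1)
  ref <- randomForest::randomForest(x, y, ntree = 100, mtry = 3)
  acc_ref <- mean(predict(ref, xt) == yt)
  expect_lte(abs(acc_ours - acc_ref), 0.05)
})
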