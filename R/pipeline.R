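#' Read and write measurement and feature tables
#'
#' The package's single tabular interchange format is headered CSV.
#' Measurement tables have one row per (point, state): `sample_id`,
#' `slice_id`, `point_id`, `state` (one of the six input-state names),
#' `s0..s3`, plus optional `partition` and `label`. Feature tables have one
#' row per point: `sample_id`, `slice_id`, `point_id`, `label`, then the 15
#' [mm_feature_names()] columns.
#'
#' @param x Data frame to write.
#' @param path CSV file path.
#' @return Readers return the data frame; writers return `path` invisibly.
#' @export
write_measurement_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurement_csv
#' @export
read_measurement_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "slice_id", "point_id", "state",
            "s0", "s1", "s2", "s3")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("measurement CSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  x
}

#' @rdname write_measurement_csv
#' @export
write_feature_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurement_csv
#' @export
read_feature_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("label", mm_feature_names()), names(x))
  if (length(miss)) {
    stop("feature CSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  x
}

#' Reconstruct normalized feature vectors from a measurement table
#'
#' Groups a long measurement table by (sample, slice, point), reconstructs
#' the Mueller matrix of every point that has all six states exactly once,
#' and normalizes it into the 15-element feature vector. Points with an
#' incomplete state set are skipped with a warning naming how many were
#' dropped.
#'
#' @param meas Measurement data frame (see [read_measurement_csv()]).
#' @param quiet Suppress the skipped-point warning (used internally).
#' @return Feature data frame with provenance columns, `label` (if present
#'   in the input), and the 15 feature columns; the number of skipped points
#'   is attached as attribute `"skipped"`.
#' @export
reconstruct_from_measurements <- function(meas, quiet = FALSE) {
  need <- c("sample_id", "slice_id", "point_id", "state",
            "s0", "s1", "s2", "s3")
  stopifnot(all(need %in% names(meas)))
  states <- names(input_states())
  key <- paste(meas$sample_id, meas$slice_id, meas$point_id, sep = "\r")
  groups <- split(seq_len(nrow(meas)), key)
  # preserve first-appearance order of points
  groups <- groups[unique(key)]
  skipped <- 0L
  rows <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    ii <- groups[[g]]
    st <- meas$state[ii]
    if (!setequal(st, states) || anyDuplicated(st)) {
      skipped <- skipped + 1L
      next
    }
    ms <- lapply(states, function(s) {
      unlist(meas[ii[match(s, st)], c("s0", "s1", "s2", "s3")],
             use.names = FALSE)
    })
    names(ms) <- states
    feat <- normalize_and_featurize(
      reconstruct_mueller(ms, check_physical = FALSE))
    first <- ii[1L]
    row <- data.frame(
      sample_id = meas$sample_id[first], slice_id = meas$slice_id[first],
      point_id = meas$point_id[first], stringsAsFactors = FALSE
    )
    if ("label" %in% names(meas)) row$label <- meas$label[first]
    rows[[g]] <- cbind(row, as.data.frame(as.list(feat)))
  }
  if (skipped > 0L && !quiet) {
    warning(skipped, " measurement point(s) lacked a complete six-state ",
            "set and were skipped")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Run the full simulate-train-evaluate pipeline
#'
#' End-to-end workflow under a single master seed: generate the synthetic
#' campaign, balance the training (and, by default, testing) partition by
#' oversampling, optionally grid-search the forest hyperparameters by
#' repeated cross-validation, fit the final forest, and evaluate it
#' (confusion matrix, precision/recall/F1, one-vs-rest AUC, feature
#' importances). When `out_dir` is given, the feature CSVs, the fitted model
#' JSON, the full report files and a manifest recording the seed and
#' configuration are written there, so a run documents itself.
#'
#' @param config A [dataset_config()]; its seed is overridden by `seed`.
#' @param seed Master seed for every stochastic stage.
#' @param ntree,max_depth Final forest hyperparameters (defaults 220 and 14),
#'   used directly when `search_grid` is `NULL`.
#' @param search_grid Optional list with `ntree` and `depth` vectors; when
#'   given, [grid_search()] picks the hyperparameters first.
#' @param oversample_test Also oversample the test partition before
#'   evaluation (default `TRUE`, matching the study design; a warning notes
#'   that this inflates the test set).
#' @param out_dir Optional output directory.
#' @return List: `model`, `confusion`, `metrics`, `auc`, `importance`,
#'   `grid` (if searched), `data` (the generated partitions).
#' @export
run_pipeline <- function(config = dataset_config(), seed = 1L,
                         ntree = 220L, max_depth = 14L, search_grid = NULL,
                         oversample_test = TRUE, out_dir = NULL) {
  config$seed <- as.integer(seed)
  d <- generate_dataset(config)
  train <- d$train
  test <- d$test
  if (oversample_test) {
    warning("oversampling the test partition duplicates test instances; ",
            "kept for fidelity to the study design", call. = FALSE)
    test <- oversample(test, seed = derive_seed(seed, 41L))
  }
  grid <- NULL
  if (!is.null(search_grid)) {
    balanced <- oversample(train, seed = derive_seed(seed, 17L))
    grid <- grid_search(balanced[, mm_feature_names()], balanced$label,
                        ntree_grid = search_grid$ntree,
                        depth_grid = search_grid$depth,
                        seed = derive_seed(seed, 53L))
    ntree <- grid$best[["ntree"]]
    max_depth <- grid$best[["max_depth"]]
  }
  model <- train_final(train, ntree = ntree, max_depth = max_depth,
                       seed = seed)
  pred <- predict(model, test[, mm_feature_names()])
  votes <- predict(model, test[, mm_feature_names()], type = "vote")
  cm <- confusion_matrix(test$label, pred)
  metrics <- precision_recall_f1(cm)
  auc <- roc_auc_ovr(test$label, votes)
  importance <- feature_importance(model)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_feature_csv(d$train, file.path(out_dir, "train.csv"))
    write_feature_csv(d$test, file.path(out_dir, "test.csv"))
    write_forest_json(model, file.path(out_dir, "model.json"))
    render_report(out_dir, cm, metrics, auc, importance)
    manifest <- list(
      package = "muellerforest",
      version = as.character(utils::packageVersion("muellerforest")),
      seed = seed, ntree = ntree, max_depth = max_depth,
      oversample_test = oversample_test,
      n_train = nrow(d$train), n_test = nrow(d$test),
      noise = unclass(config$noise),
      class_params = lapply(config$specs, function(s) unclass(s$params))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(model = model, confusion = cm, metrics = metrics, auc = auc,
       importance = importance, grid = grid,
       data = list(train = d$train, test = test))
}
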