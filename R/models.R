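#' Classification report from confusion counts
#'
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `sensitivity = TP/(TP+FN)` (ability to
#' recognize positives, i.e. caveolae / isotropic blobs), `specificity =
#' TN/(TN+FP)` (ability to recognize negatives).
#'
#' @param tp,tn,fp,fn non-negative confusion counts.
#' @return object of class `cav_report`: list with `counts` and the three
#'   metrics. A metric whose denominator is zero is `NA` with a warning.
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    abort("confusion counts must be non-negative integers")
  total <- sum(counts)
  if (total == 0) abort("no evaluated blobs")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (is.na(sens) || is.na(spec))
    warning("a class is absent from the evaluation; affected metric is NA")
  structure(list(counts = counts,
                 accuracy = (tp + tn) / total,
                 sensitivity = sens,
                 specificity = spec),
            class = "cav_report")
}

#' @export
print.cav_report <- function(x, ...) {
  cat(sprintf(paste0("<cav_report> n=%d  accuracy=%.4f  sensitivity=%.4f  ",
                     "specificity=%.4f\n  TP=%d TN=%d FP=%d FN=%d\n"),
              sum(x$counts), x$accuracy, x$sensitivity, x$specificity,
              x$counts["tp"], x$counts["tn"], x$counts["fp"], x$counts["fn"]))
  invisible(x)
}

#' Report from predicted and true labels
#'
#' @param predicted,truth vectors of `"positive"` / `"negative"` labels.
#' @return a `cav_report`.
#' @export
report_from_labels <- function(predicted, truth) {
  if (length(predicted) != length(truth)) abort("length mismatch")
  metrics_from_counts(
    tp = sum(predicted == "positive" & truth == "positive"),
    tn = sum(predicted == "negative" & truth == "negative"),
    fp = sum(predicted == "positive" & truth == "negative"),
    fn = sum(predicted == "negative" & truth == "positive")
  )
}

#' Mixed (cell-agnostic) train/validation/test split
#'
#' Blobs from all cells are pooled and drawn at random, stratified by class
#' so every set stays balanced when the input is balanced. The study split of
#' the 1714 balanced real blobs is 200 test / 100 validation / 1414 train.
#'
#' @param ids blob ids.
#' @param classes class label per id (`"positive"`/`"negative"`).
#' @param n_test,n_val sizes of the held-out sets (split evenly across
#'   classes); the remainder trains.
#' @param seed RNG seed.
#' @return list with `train_ids`, `val_ids`, `test_ids`, `mode`, `seed`.
#' @export
split_mixed <- function(ids, classes, n_test = 200L, n_val = 100L, seed = 1L) {
  if (n_test %% 2 || n_val %% 2)
    abort("n_test and n_val must be even (class-stratified split)")
  if (n_test + n_val > length(ids)) abort("split sizes exceed the dataset")
  pick <- with_seed(seed, {
    lapply(c("positive", "negative"), function(cl) {
      pool <- sample(ids[classes == cl])
      if (length(pool) < (n_test + n_val) / 2)
        abort("not enough ", cl, " blobs for the requested split")
      list(test = pool[seq_len(n_test / 2)],
           val = pool[n_test / 2 + seq_len(n_val / 2)])
    })
  })
  test <- c(pick[[1]]$test, pick[[2]]$test)
  val <- c(pick[[1]]$val, pick[[2]]$val)
  list(train_ids = setdiff(ids, c(test, val)), val_ids = val, test_ids = test,
       mode = "mixed", seed = as.integer(seed))
}

#' Cell-wise train/validation/test split
#'
#' Membership is determined solely by `cell_id`: one whole cell is held out
#' for testing and another for validation, so no blob of a test cell is ever
#' trained on. This probes generalization to unseen cells.
#'
#' @param ids blob ids.
#' @param cells cell id per blob.
#' @param test_cell,val_cell distinct cell ids.
#' @return list with `train_ids`, `val_ids`, `test_ids`, `mode`.
#' @export
split_cellwise <- function(ids, cells, test_cell, val_cell) {
  if (identical(test_cell, val_cell)) abort("test and validation cells must differ")
  if (!test_cell %in% cells) abort("unknown test cell: ", test_cell)
  if (!val_cell %in% cells) abort("unknown validation cell: ", val_cell)
  list(train_ids = ids[!cells %in% c(test_cell, val_cell)],
       val_ids = ids[cells == val_cell],
       test_ids = ids[cells == test_cell],
       mode = "cell_wise", test_cell = test_cell, val_cell = val_cell)
}

# internal: feature columns of a feature data frame, in frozen order
feature_matrix <- function(features) {
  miss <- setdiff(feature_names(), names(features))
  if (length(miss)) abort("feature matrix missing columns: ",
                          paste(miss, collapse = ", "))
  as.matrix(features[, feature_names()])
}

#' Train the bagged random-forest classifier
#'
#' 100 parallel bootstrap-aggregated trees on the 28-feature representation;
#' prediction is the majority vote. The fitted
#' model stores the frozen feature order and refuses to predict on a
#' mismatched one.
#'
#' @param features feature data frame from [featurize_blobs()] (or any data
#'   frame containing the 28 [feature_names()] columns).
#' @param labels `"positive"`/`"negative"` per row.
#' @param n_trees number of trees.
#' @param seed RNG seed.
#' @return object of class `cav_rf`.
#' @export
train_rf <- function(features, labels, n_trees = 100L, seed = 1L) {
  if (length(unique(labels)) < 2) abort("training labels contain a single class")
  x <- feature_matrix(features)
  y <- factor(labels, levels = c("positive", "negative"))
  fit <- with_seed(seed, randomForest::randomForest(x, y, ntree = n_trees))
  structure(list(fit = fit, feature_order = feature_names(),
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "cav_rf")
}

#' @export
predict.cav_rf <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- feature_matrix(newdata)
  } else if (!identical(colnames(newdata), object$feature_order)) {
    abort("feature columns do not match the order the forest was trained on")
  }
  as.character(predict(object$fit, newdata))
}

#' Stratified k-fold cross-validation of the random forest
#'
#' Blobs are assigned to k folds stratified by class (fold sizes differ by at
#' most one per class); each fold is predicted by a forest trained on the
#' remaining folds; confusion counts are pooled over folds. Per-fold reports
#' and per-blob predictions are kept alongside the pooled report.
#'
#' @param features feature data frame.
#' @param labels class labels per row.
#' @param k number of folds.
#' @param n_trees trees per forest.
#' @param seed RNG seed (fold assignment and forests).
#' @return list: `report` (pooled `cav_report`), `fold_reports`,
#'   `predictions` (data frame blob_id/truth/predicted/fold), `k`, `seed`.
#' @export
cross_validate_rf <- function(features, labels, k = 10L, n_trees = 100L,
                              seed = 1L) {
  n <- nrow(features)
  if (k < 2) abort("k must be >= 2")
  if (min(table(labels)) < k) abort("k exceeds the size of the smallest class")
  seeds <- spawn_seeds(seed, k + 1)
  fold <- integer(n)
  fold[] <- with_seed(seeds[1], {
    f <- integer(n)
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  pred <- character(n)
  fold_reports <- vector("list", k)
  for (i in seq_len(k)) {
    test <- fold == i
    model <- train_rf(features[!test, , drop = FALSE], labels[!test],
                      n_trees = n_trees, seed = seeds[i + 1])
    pred[test] <- predict(model, features[test, , drop = FALSE])
    fold_reports[[i]] <- report_from_labels(pred[test], labels[test])
  }
  list(report = report_from_labels(pred, labels),
       fold_reports = fold_reports,
       predictions = data.frame(
         blob_id = if ("blob_id" %in% names(features)) features$blob_id
                   else as.character(seq_len(n)),
         truth = labels, predicted = pred, fold = fold),
       k = as.integer(k), seed = as.integer(seed))
}

#' 2D t-SNE embedding of a feature space
#'
#' Projects any feature matrix (hand-crafted or learned) to two dimensions
#' for visual inspection of class separability.
#'
#' @param x numeric matrix or feature data frame (feature columns are
#'   auto-selected from a [featurize_blobs()] frame).
#' @param seed RNG seed (the embedding is deterministic given it).
#' @param perplexity t-SNE perplexity.
#' @return n x 2 matrix of embedding coordinates.
#' @export
embed_features_2d <- function(x, seed = 1L, perplexity = 30) {
  if (is.data.frame(x) && all(feature_names() %in% names(x)))
    x <- feature_matrix(x)
  x <- as.matrix(x)
  if (nrow(x) < 4) abort("need at least 4 rows to embed")
  keep <- apply(x, 2, function(v) stats::var(v) > 0)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " constant feature column(s) before t-SNE")
    x <- x[, keep, drop = FALSE]
  }
  perplexity <- min(perplexity, floor((nrow(x) - 1) / 3))
  emb <- with_seed(seed, Rtsne::Rtsne(scale(x), dims = 2,
                                      perplexity = perplexity,
                                      check_duplicates = FALSE))
  emb$Y
}
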