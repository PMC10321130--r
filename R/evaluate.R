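# Confusion-matrix metrics, MSE, stratified k-fold cross-validation and the
# consolidated benchmark table.

#' Confusion counts of a binary prediction
#'
#' @param y_true,y_pred equal-length binary label vectors (two distinct
#'   values at most).
#' @param positive_label the label counted as positive (the seizure class).
#' @return list of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(y_true, y_pred, positive_label) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop_validation("y_true and y_pred must have equal length")
  labs <- unique(c(y_true, y_pred))
  if (length(labs) > 2L)
    stop_validation("binary labels required, got: ", paste(labs, collapse = ", "))
  if (!positive_label %in% labs && length(labs) == 2L)
    stop_validation("positive_label not present in the labels")
  pos_t <- y_true == positive_label
  pos_p <- y_pred == positive_label
  structure(list(tp = sum(pos_t & pos_p), tn = sum(!pos_t & !pos_p),
                 fp = sum(!pos_t & pos_p), fn = sum(pos_t & !pos_p)),
            class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy (as percentages)
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / total`, each multiplied by 100. For balanced test
#' sets, accuracy equals the mean of sensitivity and specificity. Counts may
#' be fractional (useful when reconstructing counts from reported rates).
#'
#' @param counts a [confusion_counts()] object or a list with `tp`, `tn`,
#'   `fp`, `fn`.
#' @return list of class `metrics_row` with `sensitivity`, `specificity`,
#'   `accuracy` in `[0, 100]`.
#' @export
#' @examples
#' # balanced classes: sensitivity 97.92, specificity 100 -> accuracy 98.96
#' cc <- list(tp = 97.92, fn = 2.08, tn = 100, fp = 0)
#' classification_metrics(cc)$accuracy
classification_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (tp + fn <= 0 || tn + fp <= 0)
    stop_validation("undefined metric: a class has no instances")
  structure(list(sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 accuracy = 100 * (tp + tn) / (tp + tn + fp + fn)),
            class = "metrics_row")
}

#' Mean squared error between two equal-length series
#'
#' @param observed,target numeric vectors of equal length (>= 1).
#' @return `mean((observed - target)^2)`.
#' @export
#' @examples
#' mse(c(1, 2), c(0, 0))  # 2.5
mse <- function(observed, target) {
  if (length(observed) != length(target) || !length(observed))
    stop_validation("series must have equal positive length")
  mean((as.numeric(observed) - as.numeric(target))^2)
}

# Stratified fold assignment: within each class, a seeded shuffle is dealt
# round-robin into K folds, so every fold holds both classes.
stratified_folds <- function(y, K, seed) {
  y <- factor(y)
  if (K < 2L) stop_validation("K must be at least 2")
  if (any(table(y) < K))
    stop_validation("stratification error: K exceeds the size of a class")
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(K), length(idx))
    }
  })
  folds
}

#' Stratified k-fold benchmark of classifier specifications
#'
#' A single seeded stratified partition is shared by all specifications
#' (paired comparison). Per specification and fold, the classifier is fitted
#' on the other K - 1 folds and evaluated on the held-out fold; fold metrics
#' are averaged (the reported accuracy of a balanced benchmark therefore
#' equals the mean of its sensitivity and specificity). The per-fold MSE is
#' computed between 0/1-coded predicted and true labels.
#'
#' @param features feature matrix or the data frame from [dataset_features()]
#'   (feature columns `f1..fk` are extracted automatically).
#' @param labels class labels (ignored if `features` carries a `label`
#'   column and `labels` is `NULL`).
#' @param classifier_specs list of [classifier_spec()] objects (or kind
#'   names); names become table rows.
#' @param K number of folds (default 10).
#' @param seed integer seed fixing the partition.
#' @param positive_label label treated as positive; defaults to `"ictal"` or
#'   `"E"` when present, else the last factor level.
#' @param aggregate `"fold_mean"` (average of per-fold metrics, default) or
#'   `"pooled"` (metrics of the pooled confusion counts).
#' @return list of class `benchmark_result` with `table` (a
#'   `benchmark_table` data frame: classifier, sensitivity, specificity,
#'   accuracy, mse), `folds` (the fold assignment) and `per_fold` (per-spec
#'   data frames of fold metrics).
#' @export
run_kfold_benchmark <- function(features, labels = NULL, classifier_specs,
                                K = 10L, seed = 1L, positive_label = NULL,
                                aggregate = c("fold_mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  if (is.data.frame(features) && "label" %in% names(features)) {
    if (is.null(labels)) labels <- features$label
    X <- feature_matrix(features)
  } else {
    X <- as_matrix(features)
  }
  if (is.null(labels)) stop_validation("labels are required")
  y <- factor(labels)
  if (nlevels(y) != 2L) stop_validation("the benchmark is two-class")
  if (is.null(positive_label)) {
    positive_label <- if ("ictal" %in% levels(y)) "ictal"
      else if ("E" %in% levels(y)) "E" else levels(y)[2L]
  }
  specs <- lapply(classifier_specs, function(s)
    if (is.character(s)) classifier_spec(s) else s)
  if (is.null(names(specs)) || any(!nzchar(names(specs))))
    names(specs) <- vapply(specs, function(s) s$kind, character(1))
  folds <- stratified_folds(y, K, seed)
  per_fold <- list()
  rows <- list()
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    fm <- lapply(seq_len(K), function(f) {
      tr <- folds != f
      fit <- fit_classifier(build_classifier(spec),
                            X[tr, , drop = FALSE], y[tr])
      pred <- predict(fit, X[!tr, , drop = FALSE])
      cc <- confusion_counts(y[!tr], pred, positive_label)
      met <- classification_metrics(cc)
      data.frame(fold = f, sensitivity = met$sensitivity,
                 specificity = met$specificity, accuracy = met$accuracy,
                 mse = mse(as.integer(pred == positive_label),
                           as.integer(y[!tr] == positive_label)),
                 tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn)
    })
    fm <- do.call(rbind, fm)
    per_fold[[nm]] <- fm
    if (aggregate == "fold_mean") {
      rows[[nm]] <- data.frame(classifier = nm,
                               sensitivity = mean(fm$sensitivity),
                               specificity = mean(fm$specificity),
                               accuracy = mean(fm$accuracy),
                               mse = mean(fm$mse))
    } else {
      met <- classification_metrics(list(tp = sum(fm$tp), tn = sum(fm$tn),
                                         fp = sum(fm$fp), fn = sum(fm$fn)))
      rows[[nm]] <- data.frame(classifier = nm,
                               sensitivity = met$sensitivity,
                               specificity = met$specificity,
                               accuracy = met$accuracy,
                               mse = mean(fm$mse))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("benchmark_table", "data.frame")
  structure(list(table = tab, folds = folds, per_fold = per_fold,
                 positive_label = positive_label, K = K, seed = seed),
            class = "benchmark_result")
}

#' @export
print.benchmark_table <- function(x, digits = 5, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("%d-fold stratified benchmark (positive = '%s')\n",
              x$K, x$positive_label))
  print(x$table, ...)
  invisible(x)
}
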