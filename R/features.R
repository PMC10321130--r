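# Cluster-based data reduction into fixed-length feature vectors, and the
# entropy report quantifying per-class separability of the clustered
# features.

#' Sorted cluster-centroid features of one segment
#'
#' Clusters the segment's amplitude samples (one-dimensional points) into
#' `cfg$k` clusters with the named method and returns the k centroid values
#' sorted ascending: a fixed-length amplitude-distribution summary of the
#' segment.
#'
#' @param segment an [eeg_segment()].
#' @param method one of the six clusterer names (see [cluster_eeg()]).
#' @param k number of centroids (= feature-vector length), at most the
#'   segment length.
#' @param seed integer seed.
#' @param ... further arguments passed to [cluster_eeg()] (e.g. `nstart`,
#'   `params`).
#' @return numeric vector of length `k`, sorted ascending.
#' @export
segment_centroid_features <- function(segment, method, k, seed = 1L, ...) {
  stopifnot(inherits(segment, "eeg_segment"))
  if (k > length(segment$samples))
    stop_validation("k must not exceed the segment length")
  m <- cluster_eeg(segment$samples, method = method, k = k, seed = seed, ...)
  sort(as.numeric(m$centroids))
}

#' Feature matrix of a labelled dataset
#'
#' Applies [segment_centroid_features()] to every segment; per-segment seeds
#' are derived from `seed` and the segment id.
#'
#' @param dataset an [eeg_dataset()].
#' @param method clusterer name.
#' @param k features per segment.
#' @param seed master seed.
#' @param ... passed to [segment_centroid_features()].
#' @return data frame with columns `segment_id`, `label`, `f1..fk`, carrying
#'   attributes `method` and `k`.
#' @export
dataset_features <- function(dataset, method, k = 10L, seed = 1L, ...) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  rows <- lapply(dataset$segments, function(s) {
    f <- segment_centroid_features(s, method, k,
                                   seed = derive_seed(seed, method, s$segment_id),
                                   ...)
    c(list(segment_id = s$segment_id, label = s$label),
      stats::setNames(as.list(f), paste0("f", seq_len(k))))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  attr(out, "method") <- method
  attr(out, "k") <- as.integer(k)
  out
}

feature_matrix <- function(features) {
  as.matrix(features[, grep("^f[0-9]+$", names(features)), drop = FALSE])
}

#' Reduce a class matrix by clustering its columns
#'
#' Treats the `n_segments` columns of a `n_timepoints x n_segments` class
#' matrix as points in `n_timepoints`-dimensional space, clusters them into
#' `k` groups and returns the `k` centroid columns: a
#' `n_segments / k`-fold data reduction that preserves the time axis (e.g.
#' 4097 x 100 -> 4097 x 10, a ten-fold reduction).
#'
#' @param class_matrix numeric matrix, one column per segment.
#' @param method clusterer name.
#' @param k number of centroid columns, at most `ncol(class_matrix)`.
#' @param seed integer seed.
#' @param ... passed to [cluster_eeg()].
#' @return matrix of dimension `n_timepoints x k`.
#' @export
reduce_class_matrix <- function(class_matrix, method, k, seed = 1L, ...) {
  class_matrix <- as.matrix(class_matrix)
  if (k > ncol(class_matrix))
    stop_validation("k must not exceed the number of segments (columns)")
  m <- cluster_eeg(t(class_matrix), method = method, k = k, seed = seed, ...)
  t(m$centroids)
}

#' Entropy parameters
#'
#' @param m embedding dimension for ApEn/SampEn.
#' @param r tolerance as a fraction of the series sd.
#' @param bins histogram bins for Shannon entropy.
#' @return a list of class `entropy_params`.
#' @export
entropy_params <- function(m = 2L, r = 0.2, bins = 16L) {
  assert_number(m, "m", lower = 1)
  assert_number(r, "r", lower = .Machine$double.xmin)
  assert_number(bins, "bins", lower = 2)
  structure(list(m = as.integer(m), r = r, bins = as.integer(bins)),
            class = "entropy_params")
}

# Column means of the per-clusterer rows, skipping non-finite cells: the
# "Average" row of the entropy report. Exported because the report's
# self-consistency (and the published column means) are checked through it.

#' Average row of an entropy table
#'
#' Arithmetic mean of each numeric column, excluding non-finite entries
#' (e.g. the `Inf` sentinel SampEn returns when no templates match).
#'
#' @param tbl data frame of per-clusterer entropy values (numeric columns).
#' @return named numeric vector of column means.
#' @export
entropy_report_average <- function(tbl) {
  num <- vapply(tbl, is.numeric, logical(1))
  vapply(tbl[num], function(col) mean(col[is.finite(col)]), numeric(1))
}

#' Entropy-based separability report of clustered features
#'
#' For every (clusterer, class) cell, computes approximate, Shannon and
#' sample entropy on the concatenated feature values of that class, and
#' appends an `Average` row (the column means over clusterers, non-finite
#' cells excluded).
#'
#' @param feature_sets named list: clusterer name -> feature data frame from
#'   [dataset_features()] (with `label` column).
#' @param params an [entropy_params()].
#' @return data frame of class `entropy_report`: one row per clusterer plus
#'   `Average`, columns `apen_<class>`, `shannon_<class>`, `sampen_<class>`.
#' @export
entropy_report <- function(feature_sets, params = entropy_params()) {
  stopifnot(length(feature_sets) >= 1L, !is.null(names(feature_sets)))
  classes <- sort(unique(feature_sets[[1L]]$label))
  rows <- lapply(names(feature_sets), function(meth) {
    ft <- feature_sets[[meth]]
    vals <- list(clusterer = meth)
    for (cl in classes) {
      x <- as.numeric(t(feature_matrix(ft[ft$label == cl, , drop = FALSE])))
      vals[[paste0("apen_", cl)]] <-
        if (length(x)) approximate_entropy(x, params$m, params$r) else NA_real_
      vals[[paste0("shannon_", cl)]] <-
        if (length(x)) shannon_entropy(x, params$bins) else NA_real_
      vals[[paste0("sampen_", cl)]] <-
        if (length(x)) sample_entropy(x, params$m, params$r) else NA_real_
    }
    as.data.frame(vals, stringsAsFactors = FALSE)
  })
  tbl <- do.call(rbind, rows)
  avg <- entropy_report_average(tbl)
  tbl <- rbind(tbl, c(list(clusterer = "Average"), as.list(avg)))
  class(tbl) <- c("entropy_report", "data.frame")
  tbl
}

#' @export
print.entropy_report <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Export scatter and histogram source data for two feature classes
#'
#' Writes the plot *data* (no rendering): a scatter CSV pairing the feature
#' columns of the two classes, and a histogram CSV of binned feature counts
#' per class.
#'
#' @param features feature data frame (from [dataset_features()]) holding
#'   exactly two classes.
#' @param out_dir output directory.
#' @param bins histogram bin count.
#' @return named character vector of the two file paths, invisibly.
#' @export
export_cluster_views <- function(features, out_dir, bins = 16L) {
  classes <- sort(unique(features$label))
  if (length(classes) != 2L) stop_validation("exactly two classes required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fm <- lapply(classes, function(cl)
    feature_matrix(features[features$label == cl, , drop = FALSE]))
  n <- min(nrow(fm[[1]]), nrow(fm[[2]]))
  sc <- cbind(as.data.frame(fm[[1]][seq_len(n), , drop = FALSE]),
              as.data.frame(fm[[2]][seq_len(n), , drop = FALSE]))
  names(sc) <- c(paste0(classes[1], "_f", seq_len(ncol(fm[[1]]))),
                 paste0(classes[2], "_f", seq_len(ncol(fm[[2]]))))
  scatter_path <- file.path(out_dir, "scatter.csv")
  write.csv(sc, scatter_path, row.names = FALSE)
  hists <- lapply(seq_along(classes), function(i) {
    v <- as.numeric(fm[[i]])
    br <- seq(min(v), max(v), length.out = bins + 1L)
    idx <- findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
    data.frame(label = classes[i], bin = seq_len(bins),
               lower = br[-length(br)], upper = br[-1L],
               count = tabulate(idx, nbins = bins))
  })
  hist_path <- file.path(out_dir, "histogram.csv")
  write.csv(do.call(rbind, hists), hist_path, row.names = FALSE)
  invisible(c(scatter = scatter_path, histogram = hist_path))
}
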