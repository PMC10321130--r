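# Learning-based clustering, algorithm 1: alternating nearest-centroid
# assignment and prototype update. q = 2 updates the prototype as the cluster
# mean (k-means); q = 1 as the coordinate-wise median (k-median).

#' K-means / k-median clustering
#'
#' Initializes prototypes as a seeded random selection of `k` distinct data
#' points, then alternates (a) nearest-centroid assignment under the L_q
#' metric and (b) prototype update (mean for `q = 2`, coordinate-wise median
#' for `q = 1`) until the assignment repeats or `max_iter` is reached.
#' Empty clusters are reseeded at the point farthest from its assigned
#' centroid when `cfg$empty_repair` is `TRUE`. With `cfg$nstart > 1`, the
#' best of several seeded restarts is returned. Deterministic given
#' `(X, cfg)`.
#'
#' @param X numeric matrix (n x d) or vector (d = 1).
#' @param cfg a [cluster_config()]; `cfg$k <= n` is required.
#' @return a `cluster_model` (see [clustering_objective()] for the objective).
#' @export
#' @examples
#' X <- c(rnorm(10), rnorm(10, 8))
#' m <- kmeans_cluster(X, cluster_config(k = 2, seed = 1, nstart = 5))
#' coef(m)
kmeans_cluster <- function(X, cfg) {
  X <- as_matrix(X)
  stopifnot(inherits(cfg, "cluster_config"))
  n <- nrow(X)
  if (cfg$k > n) stop_validation("k must not exceed the number of points")
  best <- NULL
  for (s in seq_len(cfg$nstart)) {
    m <- kmeans_single(X, cfg, seed = derive_seed(cfg$seed, "restart", s))
    if (is.null(best) || m$objective < best$objective) best <- m
  }
  best
}

kmeans_single <- function(X, cfg, seed) {
  n <- nrow(X)
  centroids <- with_seed(seed, X[sample.int(n, cfg$k), , drop = FALSE])
  prev_assign <- NULL
  trace <- numeric(0)
  for (it in seq_len(cfg$max_iter)) {
    if (cfg$empty_repair) centroids <- repair_empty(X, centroids, cfg$q)
    ob <- clustering_objective(X, centroids, q = cfg$q)
    assign <- ob$assignment
    for (j in seq_len(cfg$k)) {
      idx <- which(assign == j)
      if (!length(idx)) next
      centroids[j, ] <- if (cfg$q == 2) colMeans(X[idx, , drop = FALSE])
                        else apply(X[idx, , drop = FALSE], 2L, median)
    }
    trace <- c(trace, clustering_objective(X, centroids, q = cfg$q)$objective)
    if (!is.null(prev_assign) && identical(assign, prev_assign)) break
    prev_assign <- assign
  }
  new_cluster_model(if (cfg$q == 1) "kmedian" else "kmeans",
                    X, centroids, cfg, trace)
}
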