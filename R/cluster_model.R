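# The shared result container of all six clusterers, plus the within-cluster
# objective they all optimize.

#' Clustering configuration
#'
#' @param k number of clusters (>= 1, at most the number of points).
#' @param q distance exponent: 2 (squared Euclidean, k-means/metaheuristics)
#'   or 1 (Manhattan, k-median).
#' @param max_iter iteration cap for the alternating updates.
#' @param tol convergence tolerance (> 0).
#' @param seed integer seed controlling initialization.
#' @param nstart number of seeded restarts (best objective kept).
#' @param empty_repair reseed empty clusters at the point farthest from its
#'   assigned centroid (`TRUE`, default) or leave them empty (`FALSE`).
#' @return a list of class `cluster_config`.
#' @export
cluster_config <- function(k, q = 2, max_iter = 100L, tol = 1e-8, seed = 1L,
                           nstart = 1L, empty_repair = TRUE) {
  assert_number(k, "k", lower = 1)
  if (!q %in% c(1, 2)) stop_validation("q must be 1 or 2")
  assert_number(max_iter, "max_iter", lower = 1)
  assert_number(tol, "tol", lower = .Machine$double.xmin)
  assert_number(nstart, "nstart", lower = 1)
  structure(list(k = as.integer(k), q = as.integer(q),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), nstart = as.integer(nstart),
                 empty_repair = isTRUE(empty_repair)),
            class = "cluster_config")
}

#' Within-cluster objective under nearest-centroid assignment
#'
#' Assigns every row of `X` to its nearest centroid under the L_q metric
#' (ties broken toward the lowest cluster index) and returns the objective
#' `sum_j ||x_j - b_assigned(j)||_q^q`: the within-cluster sum of squares for
#' `q = 2`, the within-cluster sum of absolute deviations for `q = 1`. This is
#' the fitness shared by all metaheuristic clusterers.
#'
#' @param X numeric matrix (n x d) of points, or a vector (treated as d = 1).
#' @param centroids numeric matrix (k x d) of cluster prototypes.
#' @param q distance exponent, 1 or 2.
#' @return list with `objective` (scalar), `assignment` (integer vector in
#'   `1..k`) and `point_cost` (per-point contribution).
#' @export
#' @examples
#' clustering_objective(c(0, 2), matrix(1), q = 2)$objective  # 1 + 1 = 2
clustering_objective <- function(X, centroids, q = 2) {
  X <- as_matrix(X)
  centroids <- as_matrix(centroids)
  if (nrow(X) == 0L) stop_validation("empty data")
  if (ncol(X) != ncol(centroids))
    stop_validation("X and centroids must have the same dimension")
  if (!q %in% c(1, 2)) stop_validation("q must be 1 or 2")
  .nearest_assignment_cpp(X, centroids, as.integer(q))
}

# Internal constructor: recomputes the hard objective from centroids + data
# so the stored objective always matches clustering_objective().
new_cluster_model <- function(method, X, centroids, cfg, trace,
                              membership = NULL, objective = NULL,
                              extra = list()) {
  X <- as_matrix(X)
  centroids <- as_matrix(centroids)
  ob <- clustering_objective(X, centroids, q = cfg$q)
  structure(list(method = method, k = nrow(centroids), q = cfg$q,
                 centroids = centroids,
                 assignment = ob$assignment,
                 membership = membership,
                 objective = if (is.null(objective)) ob$objective else objective,
                 hard_objective = ob$objective,
                 trace = as.numeric(trace),
                 config = cfg, n = nrow(X), d = ncol(X),
                 extra = extra),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model: %s> k=%d, q=%d, n=%d, d=%d\n",
              x$method, x$k, x$q, x$n, x$d))
  cat(sprintf("  objective: %.6g (%d trace points)\n",
              x$objective, length(x$trace)))
  invisible(x)
}

#' @export
summary.cluster_model <- function(object, ...) {
  sizes <- tabulate(object$assignment, nbins = object$k)
  out <- list(method = object$method, k = object$k, q = object$q,
              objective = object$objective, cluster_sizes = sizes,
              centroids = object$centroids,
              iterations = length(object$trace))
  class(out) <- "summary.cluster_model"
  out
}

#' @export
print.summary.cluster_model <- function(x, ...) {
  cat(sprintf("%s clustering, k = %d (q = %d)\n", x$method, x$k, x$q))
  cat(sprintf("objective %.6g after %d recorded iterations\n",
              x$objective, x$iterations))
  cat("cluster sizes:", paste(x$cluster_sizes, collapse = " "), "\n")
  cat("centroids:\n")
  print(round(x$centroids, 4))
  invisible(x)
}

#' @export
coef.cluster_model <- function(object, ...) object$centroids

#' Assign new points to the fitted centroids
#' @param object a `cluster_model`.
#' @param newdata matrix or vector of new points (same dimension as the fit).
#' @param ... unused.
#' @return integer vector of cluster indices.
#' @export
predict.cluster_model <- function(object, newdata, ...) {
  clustering_objective(newdata, object$centroids, q = object$q)$assignment
}

#' Plot the objective trace of a fitted clustering
#' @param x a `cluster_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cluster_model <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "b", pch = 20,
                 xlab = "iteration", ylab = "objective",
                 main = sprintf("%s (k = %d)", x$method, x$k), ...)
  invisible(x)
}

# Empty-cluster repair: reseed each empty centroid at the point currently
# farthest from its assigned centroid (then that point seeds the cluster).
repair_empty <- function(X, centroids, q) {
  ob <- clustering_objective(X, centroids, q = q)
  sizes <- tabulate(ob$assignment, nbins = nrow(centroids))
  while (any(sizes == 0L)) {
    # nothing left to separate (all points sit on a centroid): degenerate
    # data such as a constant segment keeps duplicated prototypes
    if (max(ob$point_cost) <= 0) break
    far <- which.max(ob$point_cost)
    centroids[which(sizes == 0L)[1L], ] <- X[far, ]
    ob <- clustering_objective(X, centroids, q = q)
    sizes <- tabulate(ob$assignment, nbins = nrow(centroids))
  }
  centroids
}
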