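# Learning-based clustering, algorithm 2: fuzzy c-means with the standard
# Lagrange-multiplier membership/centroid updates, plus validity-index-driven
# selection of the cluster count.

#' Fuzzy c-means configuration
#'
#' @param k number of clusters.
#' @param p fuzziness index, `p > 1` (memberships harden as `p -> 1`).
#' @param xi convergence threshold on the change of the objective (> 0).
#' @param i_max maximum number of iterations.
#' @param seed integer seed for the random initial fuzzy partition.
#' @return a list of class `fcm_config`.
#' @export
fcm_config <- function(k, p = 2, xi = 1e-6, i_max = 200L, seed = 1L) {
  assert_number(k, "k", lower = 1)
  assert_number(p, "p", lower = 1 + 1e-12)
  assert_number(xi, "xi", lower = .Machine$double.xmin)
  assert_number(i_max, "i_max", lower = 1)
  structure(list(k = as.integer(k), p = p, xi = xi,
                 i_max = as.integer(i_max), seed = as.integer(seed),
                 q = 2L),
            class = c("fcm_config", "cluster_config"))
}

# n x k matrix of squared Euclidean distances to the centroids.
sqdist_to_centroids <- function(X, W) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(W))) +
    outer(rep(1, nrow(X)), rowSums(W^2)) - 2 * X %*% t(W)
  pmax(d2, 0)
}

# Membership update: z_iq = 1 / sum_h (d_iq / d_hq)^(2/(p-1)); a point at
# zero distance from a centroid gets membership 1 there (limit case).
fcm_memberships <- function(D2, p) {
  expo <- 1 / (p - 1)
  inv <- D2^(-expo)                      # (1/d^2)^(1/(p-1))
  zero <- !is.finite(inv)
  Z <- inv / rowSums(inv)
  bad <- which(rowSums(zero) > 0L)
  for (i in bad) {
    Z[i, ] <- 0
    Z[i, which(zero[i, ])[1L]] <- 1
  }
  Z
}

#' Fuzzy c-means clustering
#'
#' Minimizes `H = sum_iq z_iq^p d_iq^2` by alternating the centroid update
#' (membership-weighted means) and the membership update, stopping when the
#' objective changes by less than `xi` or after `i_max` iterations. Every
#' membership row sums to 1; the returned `cluster_model` stores the fuzzy
#' membership matrix, the fuzzy objective and its per-iteration trace
#' (non-increasing), with the hard assignment taken as the membership argmax.
#'
#' @param X numeric matrix (n x d) or vector.
#' @param cfg an [fcm_config()].
#' @return a `cluster_model` with a `membership` matrix.
#' @export
fcm_cluster <- function(X, cfg) {
  X <- as_matrix(X)
  stopifnot(inherits(cfg, "fcm_config"))
  n <- nrow(X)
  if (cfg$k > n) stop_validation("k must not exceed the number of points")
  Z <- with_seed(cfg$seed, {
    M <- matrix(runif(n * cfg$k, min = 0.05), n, cfg$k)
    M / rowSums(M)
  })
  trace <- numeric(0)
  h_prev <- Inf
  W <- NULL
  for (t in seq_len(cfg$i_max)) {
    Zp <- Z^cfg$p
    W <- t(Zp) %*% X / colSums(Zp)
    D2 <- sqdist_to_centroids(X, W)
    h <- sum(Zp * D2)
    trace <- c(trace, h)
    if (abs(h_prev - h) < cfg$xi) break
    h_prev <- h
    Z <- fcm_memberships(D2, cfg$p)
  }
  m <- new_cluster_model("fcm", X, W, cfg, trace,
                         membership = Z, objective = trace[length(trace)])
  m$assignment <- max.col(Z, ties.method = "first")
  m
}

#' Xie-Beni validity index of a fuzzy clustering
#'
#' Compactness over separation: `sum_iq z_iq^p d_iq^2 / (n * min_{q != h}
#' ||w_q - w_h||^2)`. Lower is better.
#'
#' @param X the clustered data.
#' @param model a `cluster_model` with memberships (from [fcm_cluster()]).
#' @return the index value.
#' @export
xie_beni_index <- function(X, model) {
  X <- as_matrix(X)
  W <- model$centroids
  D2 <- sqdist_to_centroids(X, W)
  sep <- sqdist_to_centroids(W, W)
  diag(sep) <- Inf
  compact <- sum(model$membership^model$config$p * D2)
  compact / (nrow(X) * min(sep))
}

#' Select the number of fuzzy clusters by a validity index
#'
#' Runs [fcm_cluster()] for every candidate `k` in `[k_min, k_max]` and
#' returns the `k` optimizing the validity index (Xie-Beni by default,
#' minimized). The conventional search range is `k_min = 2` to
#' `k_max = floor(sqrt(n))`.
#'
#' @param X numeric matrix or vector.
#' @param k_min,k_max inclusive search range, `2 <= k_min <= k_max`.
#' @param validity index name (`"xie_beni"`) or a function
#'   `(X, model) -> value`, minimized.
#' @param p,xi,i_max,seed passed to [fcm_config()] (a per-k sub-seed is
#'   derived from `seed`).
#' @return the selected `k` (integer), with the per-k index values attached
#'   as attribute `"scores"`.
#' @export
fcm_select_k <- function(X, k_min = 2L, k_max = NULL, validity = "xie_beni",
                         p = 2, xi = 1e-6, i_max = 200L, seed = 1L) {
  X <- as_matrix(X)
  n <- nrow(X)
  if (is.null(k_max)) k_max <- max(2L, floor(sqrt(n)))
  if (k_min > k_max) stop_validation("k_min must not exceed k_max")
  if (k_min < 2L) stop_validation("k_min must be at least 2")
  vf <- if (is.function(validity)) validity
        else switch(validity, xie_beni = xie_beni_index,
                    stop_validation("unknown validity index '", validity, "'"))
  ks <- seq.int(k_min, k_max)
  scores <- vapply(ks, function(k) {
    m <- fcm_cluster(X, fcm_config(k = k, p = p, xi = xi, i_max = i_max,
                                   seed = derive_seed(seed, "fcmk", k)))
    vf(X, m)
  }, numeric(1))
  k_opt <- ks[which.min(scores)]
  attr(k_opt, "scores") <- stats::setNames(scores, ks)
  k_opt
}
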