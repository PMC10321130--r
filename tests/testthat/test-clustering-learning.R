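test_that("the within-cluster objective matches hand arithmetic", {
  expect_equal(clustering_objective(c(0, 2), matrix(1), q = 2)$objective, 2)
  expect_equal(clustering_objective(c(0, 2), matrix(1), q = 1)$objective, 2)
  # points coinciding with centroids -> zero objective
  B <- matrix(c(0, 0, 5, 5), 2, byrow = TRUE)
  X <- B[c(1, 2, 1, 2), ]
  ob <- clustering_objective(X, B, q = 2)
  expect_equal(ob$objective, 0)
  expect_identical(ob$assignment, c(1L, 2L, 1L, 2L))
  expect_error(clustering_objective(matrix(numeric(0), 0, 1), matrix(1)),
               "empty")
})

test_that("k-means assignment attains the exhaustive-enumeration optimum", {
  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(rnorm(16), ncol = 2)          # n = 8, d = 2
    m <- kmeans_cluster(X, cluster_config(k = 2, seed = seed, nstart = 20))
    oracle <- oracle_best_objective_k2(X, q = 2)
    expect_equal(m$objective, oracle, tolerance = 1e-9)
    # stored objective always equals recomputation from centroids + data
    expect_equal(m$objective,
                 clustering_objective(X, m$centroids, q = 2)$objective,
                 tolerance = 1e-12)
  }
})

test_that("two separated blobs yield the blob means and within-blob SSE", {
  X <- rbind(matrix(c(0, 0, 0.5, 0.5), 2, byrow = TRUE),
             matrix(c(9, 9, 9.5, 9.5), 2, byrow = TRUE))
  m <- kmeans_cluster(X, cluster_config(k = 2, seed = 1, nstart = 5))
  cent <- m$centroids[order(m$centroids[, 1]), ]
  expect_equal(cent, rbind(c(0.25, 0.25), c(9.25, 9.25)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m$objective, oracle_best_objective_k2(X), tolerance = 1e-12)
})

test_that("k = 1 gives the global mean (q = 2) and the median (q = 1)", {
  X <- matrix(c(1, 4, 7, 100), ncol = 1)
  m2 <- kmeans_cluster(X, cluster_config(k = 1, q = 2, seed = 1))
  expect_equal(as.numeric(m2$centroids), mean(X))
  m1 <- kmeans_cluster(c(0, 0, 10), cluster_config(k = 1, q = 1, seed = 1))
  expect_equal(as.numeric(m1$centroids), 0)
  expect_identical(m1$method, "kmedian")
})

test_that("k-means is deterministic given the seed and validates k", {
  X <- matrix(rnorm(30), ncol = 2)
  a <- kmeans_cluster(X, cluster_config(k = 3, seed = 7))
  b <- kmeans_cluster(X, cluster_config(k = 3, seed = 7))
  expect_identical(a$centroids, b$centroids)
  expect_error(kmeans_cluster(X, cluster_config(k = 16, seed = 1)), "exceed")
})

test_that("k-median attains the exhaustive L1 optimum under outliers", {
  set.seed(9)
  X <- matrix(c(rnorm(10), 50, 55), ncol = 1)   # heavy outliers, n = 12
  m <- kmeans_cluster(X, cluster_config(k = 2, q = 1, seed = 2, nstart = 10))
  expect_equal(m$objective, oracle_best_objective_k2(X, q = 1),
               tolerance = 1e-9)
})

test_that("fcm memberships sum to one and follow the closed-form limits", {
  X <- matrix(c(0, 1, 4, 5, 10, 11), ncol = 1)
  m <- fcm_cluster(X, fcm_config(k = 3, seed = 1))
  expect_equal(rowSums(m$membership), rep(1, 6), tolerance = 1e-12)
  expect_true(all(diff(m$trace) <= 1e-9))

  # a point exactly at a centroid takes membership one there
  D2 <- seizclust:::sqdist_to_centroids(matrix(c(0, 2), ncol = 1),
                                        matrix(c(0, 4), ncol = 1))
  Z <- seizclust:::fcm_memberships(D2, p = 2)
  expect_equal(Z[1, ], c(1, 0))
  # equidistant point splits 50/50
  expect_equal(Z[2, ], c(0.5, 0.5), tolerance = 1e-12)
})

test_that("fcm converges to the fixed point of direct update iteration", {
  X <- matrix(c(0, 1), ncol = 1)
  m <- fcm_cluster(X, fcm_config(k = 2, p = 2, xi = 1e-14, i_max = 500, seed = 3))
  # oracle: iterate the coupled updates directly from the model's memberships
  Z <- m$membership
  for (i in 1:10000) {
    Zp <- Z^2
    W <- t(Zp) %*% X / colSums(Zp)
    D2 <- seizclust:::sqdist_to_centroids(X, W)
    Z <- seizclust:::fcm_memberships(D2, 2)
  }
  W_fix <- t(Z^2) %*% X / colSums(Z^2)
  expect_equal(sort(as.numeric(m$centroids)), sort(as.numeric(W_fix)),
               tolerance = 1e-6)
})

test_that("fcm hardens toward k-means assignments as p approaches 1", {
  X <- make_two_blobs(10, gap = 8, sd = 0.3, seed = 5)
  m <- fcm_cluster(X, fcm_config(k = 2, p = 1.05, seed = 1))
  expect_true(all(pmax(m$membership[, 1], m$membership[, 2]) > 0.999))
  km <- kmeans_cluster(X, cluster_config(k = 2, seed = 1, nstart = 5))
  same <- mean((m$assignment == 1) == (km$assignment == 1))
  expect_true(same %in% c(0, 1))   # identical partition up to label swap
})

test_that("the validity search recovers the true blob count", {
  centers3 <- rbind(c(0, 0), c(5, 0), c(2.5, 5))
  X3 <- make_blobs(centers3, n_each = 20, sd = 0.25, seed = 11)  # n = 60
  k3 <- fcm_select_k(X3, 2, 7, seed = 4)
  expect_identical(as.integer(k3), 3L)

  # two coincident duplicated blobs -> 2 clusters
  X2 <- make_blobs(rbind(c(0, 0), c(0, 0), c(6, 6), c(6, 6)),
                   n_each = 10, sd = 0.25, seed = 12)
  expect_identical(as.integer(fcm_select_k(X2, 2, 4, seed = 4)), 2L)

  # degenerate range collapses to the single candidate
  expect_identical(as.integer(fcm_select_k(X3, 3, 3, seed = 1)), 3L)
  expect_error(fcm_select_k(X3, 5, 3), "k_min")
})
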