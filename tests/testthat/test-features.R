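test_that("centroid features summarise the amplitude distribution", {
  # constant segment with repair disabled: every centroid collapses to c
  const <- eeg_segment(rep(4, 50), fs = 100)
  f <- segment_centroid_features(const, "kmeans", k = 3, seed = 1)
  expect_equal(f, rep(4, 3))

  # two-level square wave, k = 2 -> exactly the two levels
  sq <- eeg_segment(rep(c(-2, 6), 25), fs = 100)
  f2 <- segment_centroid_features(sq, "kmeans", k = 2, seed = 1, nstart = 5)
  expect_equal(f2, c(-2, 6))
  # the two-level optimum has zero within-cluster scatter, and a short
  # instance of the same wave agrees with the exhaustive oracle
  expect_equal(clustering_objective(sq$samples, matrix(f2), q = 2)$objective, 0)
  short <- rep(c(-2, 6), 4)
  expect_equal(oracle_best_objective_k2(matrix(short)), 0)

  # contract: k sorted values for any method
  seg <- generate_segment("normal", synth_params(n_samples = 128), seed = 2)
  for (meth in c("kmeans", "fcm", "cuckoo")) {
    f3 <- segment_centroid_features(seg, meth, k = 5, seed = 3,
                                    params = if (meth == "cuckoo")
                                      cuckoo_params(iters = 30) else NULL)
    expect_length(f3, 5)
    expect_false(is.unsorted(f3))
  }
  expect_error(segment_centroid_features(sq, "kmeans", k = 51), "exceed")
})

test_that("feature extraction is invariant to sample order (sorted output)", {
  seg <- generate_segment("ictal", synth_params(n_samples = 200), seed = 4)
  perm <- seg
  set.seed(1)
  perm$samples <- sample(perm$samples)
  a <- segment_centroid_features(seg, "kmeans", k = 4, seed = 9, nstart = 10)
  b <- segment_centroid_features(perm, "kmeans", k = 4, seed = 9, nstart = 10)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("class-matrix reduction keeps the time axis and shrinks columns", {
  set.seed(5)
  M <- matrix(rnorm(200 * 30), nrow = 200, ncol = 30)
  R <- reduce_class_matrix(M, "kmeans", k = 3, seed = 1, nstart = 3)
  expect_identical(dim(R), c(200L, 3L))

  # identical columns: every centroid equals the common column
  M2 <- matrix(rep(rnorm(100), 20), nrow = 100)
  R2 <- reduce_class_matrix(M2, "kmeans", k = 4, seed = 1)
  for (j in 1:4) expect_equal(R2[, j], M2[, 1], tolerance = 1e-12)

  # k = n_segments: output is a column permutation of the input
  M3 <- matrix(rnorm(50 * 6), nrow = 50)
  R3 <- reduce_class_matrix(M3, "kmeans", k = 6, seed = 2)
  key <- function(A) sort(apply(A, 2, function(c) paste(round(c, 9),
                                                        collapse = ",")))
  expect_identical(key(R3), key(M3))
  expect_error(reduce_class_matrix(M3, "kmeans", k = 7), "exceed")
})

test_that("the entropy report is self-consistent and handles sentinels", {
  ds <- generate_dataset(6, synth_params(n_samples = 128), seed = 7)
  fts <- list(kmeans = dataset_features(ds, "kmeans", k = 4, seed = 1),
              fcm = dataset_features(ds, "fcm", k = 4, seed = 1))
  rep1 <- entropy_report(fts)
  expect_identical(rep1$clusterer, c("kmeans", "fcm", "Average"))
  body <- rep1[rep1$clusterer != "Average", -1]
  avg <- rep1[rep1$clusterer == "Average", -1]
  for (j in seq_along(body)) {
    v <- as.numeric(body[[j]])
    expect_equal(as.numeric(avg[[j]]), mean(v[is.finite(v)]),
                 tolerance = 1e-12)
  }

  # single clusterer: the Average row reproduces the single body row
  rep2 <- entropy_report(fts["kmeans"])
  expect_equal(as.numeric(rep2[2, -1]), as.numeric(rep2[1, -1]),
               tolerance = 1e-12)

  # Inf sentinel is excluded from the average, not propagated
  tbl <- data.frame(a = c(1, Inf), b = c(2, 4))
  expect_equal(unname(entropy_report_average(tbl)), c(1, 3))
})

test_that("plot-source exports conserve counts and are reproducible", {
  d <- withr::local_tempdir()
  ds <- generate_dataset(5, synth_params(n_samples = 128), seed = 9)
  ft <- dataset_features(ds, "kmeans", k = 2, seed = 2)
  paths <- export_cluster_views(ft, d, bins = 8)
  sc <- read.csv(paths["scatter"])
  expect_identical(ncol(sc), 4L)      # 2 feature columns per class
  hg <- read.csv(paths["histogram"])
  expect_equal(sum(hg$count), 2 * 5 * 2)  # all feature values binned
  first <- readLines(paths["scatter"])
  export_cluster_views(ft, d, bins = 8)
  expect_identical(readLines(paths["scatter"]), first)
})
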