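test_that("registry defaults match the benchmark configuration", {
  expect_equal(classifier_spec("knn")$params$k, 2L)
  expect_equal(classifier_spec("svm_rbf")$params$gamma, 2)
  expect_equal(classifier_spec("svm_poly")$params$order, 2)
  expect_equal(classifier_spec("ann")$params$cycles, 800L)
  expect_equal(classifier_spec("ann")$params$learning_rate, 0.3)
  expect_equal(classifier_spec("ann")$params$momentum, 0.5)
  expect_error(classifier_spec("madeup"), "arg")
})

test_that("every registry classifier separates an easy two-class toy set", {
  toy <- make_toy_xy(20, gap = 6, sd = 0.5, seed = 1)
  for (kind in c("ann", "knn", "ilda", "nbc", "svm_linear", "svm_poly",
                 "svm_rbf", "qda", "dtree", "rf")) {
    fit <- fit_classifier(build_classifier(kind), toy$X, toy$y)
    acc <- mean(as.character(predict(fit, toy$X)) == toy$y)
    expect_gte(acc, 0.95)
  }
})

test_that("stochastic learners are reproducible under a fixed spec seed", {
  toy <- make_toy_xy(15, gap = 3, sd = 1.2, seed = 2)
  for (kind in c("ann", "svm_linear", "rf")) {
    f1 <- fit_classifier(build_classifier(classifier_spec(kind, seed = 7)),
                         toy$X, toy$y)
    f2 <- fit_classifier(build_classifier(classifier_spec(kind, seed = 7)),
                         toy$X, toy$y)
    expect_identical(predict(f1, toy$X), predict(f2, toy$X))
  }
})

test_that("the Euclidean distance helper is a metric", {
  expect_equal(knn_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(knn_distance(c(0, 0), c(3, 4)), 5)
  expect_error(knn_distance(1:3, 1:4), "equal length")
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(4); b <- rnorm(4); c <- rnorm(4)
    expect_lte(knn_distance(a, c), knn_distance(a, b) + knn_distance(b, c) + 1e-12)
    expect_equal(knn_distance(a, b), knn_distance(b, a))
  }
})

test_that("knn with k = 2 breaks split votes by the single nearest point", {
  X <- rbind(c(0, 0), c(1, 0), c(10, 0))
  y <- c("a", "a", "b")
  fit <- fit_classifier(build_classifier("knn"), X, y)
  # query at 6.1: nearest is b (3.9) then a (5.1) -> tie, nearest wins
  expect_identical(as.character(predict(fit, matrix(c(6.1, 0), 1))), "b")
  expect_identical(as.character(predict(fit, matrix(c(0.4, 0), 1))), "a")
})

test_that("incremental LDA equals batch LDA on streamed toy sets", {
  for (seed in 1:3) {
    toy <- make_toy_xy(12, gap = 3, sd = 1, seed = seed)
    set.seed(seed)
    ord <- sample(nrow(toy$X))
    m <- ilda_new()
    for (i in ord)
      m <- ilda_partial_fit(m, toy$X[i, , drop = FALSE], toy$y[i])
    w <- ilda_direction(m)
    ref <- MASS::lda(toy$X, grouping = factor(toy$y))$scaling[, 1]
    cosang <- abs(sum(w * ref)) / sqrt(sum(w^2) * sum(ref^2))
    expect_lt(acos(min(1, cosang)), 1e-8)
    # predictions match batch LDA as well
    fit <- fit_classifier(build_classifier("ilda"), toy$X, toy$y)
    expect_identical(as.character(predict(fit, toy$X)),
                     as.character(predict(MASS::lda(toy$X,
                                                    grouping = factor(toy$y)),
                                          toy$X)$class))
  }
})

test_that("ilda state handling: empty updates and single-class prediction", {
  toy <- make_toy_xy(5, seed = 4)
  m <- ilda_partial_fit(ilda_new(), toy$X, toy$y)
  m2 <- ilda_partial_fit(m, toy$X[0, , drop = FALSE], character(0))
  expect_identical(m, m2)
  single <- ilda_partial_fit(ilda_new(), toy$X[1:5, , drop = FALSE],
                             toy$y[1:5])
  expect_error(seizclust:::ilda_predict(single, toy$X), "state error")
})

test_that("the kernel-sum regularization ratio behaves as a ratio", {
  one <- matrix(1, 1, 1)   # N = 1, linear K(y1, ybar) = 1 -> Q = 1
  expect_equal(svm_regularization_q(one, "linear"), 1)
  set.seed(5)
  X <- matrix(rnorm(40), ncol = 2)
  q1 <- svm_regularization_q(X, "rbf", gamma = 0.5)
  q2 <- svm_regularization_q(rbind(X, X), "rbf", gamma = 0.5)
  expect_equal(q1, q2, tolerance = 1e-12)
  # hand-computed linear ratio on a fixed matrix
  Xs <- rbind(c(1, 0), c(0, 1), c(1, 1))
  ybar <- colMeans(Xs)
  expect_equal(svm_regularization_q(Xs, "linear"),
               3 / sum(Xs %*% ybar))
  expect_error(svm_regularization_q(matrix(c(1, -1), 2), "linear"),
               "degenerate")
})

test_that("pairwise voting reduces to the sign rule and validates counts", {
  expect_identical(pairwise_vote(3.2, 2), 1L)
  expect_identical(pairwise_vote(-0.1, 2), 2L)
  expect_identical(pairwise_vote(rep(0, 6), 4), 1L)  # tie -> lowest index
  expect_error(pairwise_vote(rep(1, 5), 4), "6 pair")
  # 3 classes, class 2 wins both of its pairs
  expect_identical(pairwise_vote(c(-1, 1, 1), 3), 2L)
})

test_that("the MSE search table has the schedule-by-grid shape", {
  toy <- make_toy_xy(15, gap = 5, sd = 0.6, seed = 6)
  sched <- c(50, 100, 150, 200)
  out <- mse_hyperparam_search("svm_rbf", grid = c(0.2, 1, 2),
                               schedule = sched, X = toy$X, y = toy$y,
                               seed = 1)
  expect_identical(dim(out$table), c(4L, 3L))
  expect_identical(rownames(out$table), as.character(sched))
  expect_true(all(out$table >= 0, na.rm = TRUE))
  # the chosen value minimises the final-step MSE among qualifying columns
  expect_equal(unname(out$final_mse[as.character(out$chosen)]),
               min(out$final_mse))
  # a single-value grid is returned unchanged
  single <- mse_hyperparam_search("knn", grid = 2, schedule = c(10, 20, 30),
                                  X = toy$X, y = toy$y)
  expect_equal(single$chosen, 2)
  expect_error(mse_hyperparam_search("knn", numeric(0), 1:3, toy$X, toy$y),
               "nonempty")
})

test_that("iteration-controlled linear SVM training improves with budget", {
  toy <- make_toy_xy(25, gap = 4, sd = 0.8, seed = 7)
  out <- mse_hyperparam_search("svm_linear", grid = NA,
                               schedule = c(25, 200, 1000, 2000),
                               X = toy$X, y = toy$y, seed = 2)
  expect_identical(dim(out$table), c(4L, 1L))
  expect_lte(out$table[4, 1], out$table[1, 1])
})

test_that("the alarm rule counts consecutive positives after smoothing", {
  expect_identical(seizure_alarm(rep(0, 20), 3), integer(0))
  expect_identical(seizure_alarm(c(0, 1, 1, 1, 0), 3), 4L)
  # median_width = 1 is the identity filter
  expect_identical(seizure_alarm(c(1, 1, 0, 1, 1), 2, median_width = 1),
                   c(2L, 5L))
  # a width-3 median removes the isolated spike; the run then fires at its
  # 2nd and 4th positions (filtered stream 0,0,0,0,1,1,1,1,0)
  expect_identical(seizure_alarm(c(0, 1, 0, 0, 1, 1, 1, 1, 0), 2,
                                 median_width = 3), c(6L, 8L))
  # counter resets after an alarm: a run of 6 with threshold 3 fires twice
  expect_identical(seizure_alarm(rep(1, 6), 3), c(3L, 6L))
  expect_error(seizure_alarm(c(0, 2), 1), "binary")
  expect_error(seizure_alarm(c(0, 1), 1, median_width = 2), "odd")
})
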