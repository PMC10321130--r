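# The ten-classifier registry, the MSE-versus-iterations hyperparameter
# search, incremental LDA and the alarm rule. Standard learners are
# delegated (e1071 for naive Bayes and kernel SVMs, MASS for QDA, rpart,
# randomForest); the ANN (gradient descent with momentum), the SGD linear
# SVM (iteration-controlled training), KNN (custom k = 2 tie rule) and
# incremental LDA are implemented here.

CLASSIFIER_KINDS <- c("ann", "knn", "ilda", "nbc", "svm_linear", "svm_poly",
                      "svm_rbf", "qda", "dtree", "rf")

classifier_defaults <- function(kind) {
  switch(kind,
    ann = list(hidden = 32L, learning_rate = 0.3, momentum = 0.5, cycles = 800L),
    knn = list(k = 2L),
    ilda = list(),
    nbc = list(laplace = 0),
    svm_linear = list(iters = 1000L, lambda = 0.01),
    svm_poly = list(order = 2, cost = 1, coef0 = 1, gamma = 1),
    svm_rbf = list(gamma = 2, cost = 1),
    qda = list(),
    dtree = list(minsplit = 10L, cp = 0.01),
    rf = list(ntree = 200L),
    stop_validation("unknown classifier kind '", kind, "'"))
}

#' Classifier specification
#'
#' Registry defaults follow the benchmark configuration: the ANN trains for
#' 800 cycles with learning rate 0.3 and momentum 0.5 through one sigmoid
#' hidden layer of 32 units (the input layer is sized to the feature count);
#' KNN uses k = 2 with Euclidean distance; the RBF SVM uses gamma = 2; the
#' polynomial SVM uses order 2; the linear SVM trains by stochastic gradient
#' descent.
#'
#' @param kind one of `"ann"`, `"knn"`, `"ilda"`, `"nbc"`, `"svm_linear"`,
#'   `"svm_poly"`, `"svm_rbf"`, `"qda"`, `"dtree"`, `"rf"`.
#' @param params named list overriding kind-specific defaults.
#' @param seed integer seed making stochastic learners reproducible.
#' @return a list of class `classifier_spec`.
#' @export
#' @examples
#' classifier_spec("knn")$params$k  # 2
classifier_spec <- function(kind, params = list(), seed = 1L) {
  kind <- match.arg(kind, CLASSIFIER_KINDS)
  p <- classifier_defaults(kind)
  p[names(params)] <- params
  structure(list(kind = kind, params = p, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Build a classifier handle from a specification
#'
#' @param spec a [classifier_spec()] (or a kind name, which is promoted with
#'   default parameters).
#' @return an object of class `seiz_clf` supporting [fit_classifier()].
#' @export
build_classifier <- function(spec) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  stopifnot(inherits(spec, "classifier_spec"))
  structure(list(spec = spec), class = c(paste0("seiz_clf_", spec$kind), "seiz_clf"))
}

#' @export
print.seiz_clf <- function(x, ...) {
  p <- x$spec$params
  cat(sprintf("<classifier: %s> %s\n", x$spec$kind,
              if (length(p)) paste(names(p), unlist(p), sep = "=", collapse = ", ")
              else "(no parameters)"))
  invisible(x)
}

prepare_xy <- function(X, y) {
  X <- as_matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2L) stop_validation("need at least two classes to fit")
  stopifnot(nrow(X) == length(y))
  list(X = X, y = y)
}

#' Fit a registry classifier
#'
#' @param clf a handle from [build_classifier()].
#' @param X feature matrix (rows = instances).
#' @param y class labels (coerced to factor).
#' @return a fitted object of class `seiz_fit` with a [predict()] method
#'   returning a factor with the training levels. Deterministic given the
#'   spec seed.
#' @export
fit_classifier <- function(clf, X, y) {
  stopifnot(inherits(clf, "seiz_clf"))
  d <- prepare_xy(X, y)
  X <- d$X; y <- d$y
  spec <- clf$spec
  p <- spec$params
  model <- switch(spec$kind,
    ann = mlp_fit(X, y, hidden = p$hidden, lr = p$learning_rate,
                  momentum = p$momentum, cycles = p$cycles, seed = spec$seed),
    knn = list(X = X, y = y, k = p$k),
    ilda = {
      m <- ilda_new()
      ilda_partial_fit(m, X, y)
    },
    nbc = e1071::naiveBayes(x = as.data.frame(X), y = y, laplace = p$laplace),
    svm_linear = svm_sgd_fit(X, y, iters = p$iters, lambda = p$lambda,
                             seed = spec$seed),
    svm_poly = e1071::svm(x = X, y = y, kernel = "polynomial",
                          degree = p$order, coef0 = p$coef0, gamma = p$gamma,
                          cost = p$cost, scale = FALSE),
    svm_rbf = e1071::svm(x = X, y = y, kernel = "radial", gamma = p$gamma,
                         cost = p$cost, scale = FALSE),
    qda = MASS::qda(x = X, grouping = y),
    dtree = {
      df <- data.frame(.label = y, X)
      rpart::rpart(.label ~ ., data = df, method = "class",
                   control = rpart::rpart.control(minsplit = p$minsplit,
                                                  cp = p$cp))
    },
    rf = with_seed(spec$seed,
                   randomForest::randomForest(x = X, y = y, ntree = p$ntree)))
  structure(list(kind = spec$kind, model = model, levels = levels(y),
                 spec = spec),
            class = "seiz_fit")
}

#' @export
predict.seiz_fit <- function(object, newdata, ...) {
  X <- as_matrix(newdata)
  lev <- object$levels
  m <- object$model
  out <- switch(object$kind,
    ann = mlp_predict(m, X),
    knn = knn_predict(m, X),
    ilda = ilda_predict(m, X),
    nbc = as.character(predict(m, as.data.frame(X))),
    svm_linear = svm_sgd_predict(m, X),
    svm_poly = as.character(predict(m, X)),
    svm_rbf = as.character(predict(m, X)),
    qda = as.character(predict(m, X)$class),
    dtree = as.character(predict(m, data.frame(X), type = "class")),
    rf = as.character(predict(m, X)))
  factor(out, levels = lev)
}

# ---- ANN: one sigmoid hidden layer, batch gradient descent with momentum --

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_fit <- function(X, y, hidden, lr, momentum, cycles, seed) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  K <- nlevels(y)
  Tgt <- diag(K)[as.integer(y), , drop = FALSE]
  d <- ncol(Xs); n <- nrow(Xs)
  with_seed(seed, {
    W1 <- matrix(runif(d * hidden, -0.5, 0.5), d, hidden)
    b1 <- runif(hidden, -0.5, 0.5)
    W2 <- matrix(runif(hidden * K, -0.5, 0.5), hidden, K)
    b2 <- runif(K, -0.5, 0.5)
    vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- b2 * 0
    for (cy in seq_len(cycles)) {
      H <- sigmoid(sweep(Xs %*% W1, 2L, b1, "+"))
      O <- sigmoid(sweep(H %*% W2, 2L, b2, "+"))
      dO <- (O - Tgt) * O * (1 - O) / n        # squared-error loss
      dH <- (dO %*% t(W2)) * H * (1 - H)
      gW2 <- t(H) %*% dO; gb2 <- colSums(dO)
      gW1 <- t(Xs) %*% dH; gb1 <- colSums(dH)
      vW2 <- momentum * vW2 - lr * gW2; W2 <- W2 + vW2
      vb2 <- momentum * vb2 - lr * gb2; b2 <- b2 + vb2
      vW1 <- momentum * vW1 - lr * gW1; W1 <- W1 + vW1
      vb1 <- momentum * vb1 - lr * gb1; b1 <- b1 + vb1
    }
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, center = ctr, scale = scl,
         levels = levels(y))
  })
}

mlp_predict <- function(m, X) {
  Xs <- sweep(sweep(X, 2L, m$center), 2L, m$scale, "/")
  H <- sigmoid(sweep(Xs %*% m$W1, 2L, m$b1, "+"))
  O <- sigmoid(sweep(H %*% m$W2, 2L, m$b2, "+"))
  m$levels[max.col(O, ties.method = "first")]
}

# ---- KNN with the k = 2 tie rule (fall back to the nearest neighbour) -----

#' Euclidean distance between two feature vectors
#'
#' @param z1,z2 numeric vectors of equal length.
#' @return `sqrt(sum((z1 - z2)^2))`.
#' @export
#' @examples
#' knn_distance(c(0, 0), c(3, 4))  # 5
knn_distance <- function(z1, z2) {
  if (length(z1) != length(z2)) stop_validation("vectors must have equal length")
  sqrt(sum((z1 - z2)^2))
}

knn_predict <- function(m, X) {
  tr <- m$X
  D2 <- sqdist_to_centroids(X, tr)      # n_test x n_train squared distances
  vapply(seq_len(nrow(X)), function(i) {
    ord <- order(D2[i, ])
    nb <- m$y[ord[seq_len(m$k)]]
    tab <- table(nb)
    win <- names(tab)[tab == max(tab)]
    if (length(win) > 1L) as.character(m$y[ord[1L]]) else win
  }, character(1))
}

# ---- Incremental LDA -------------------------------------------------------

#' Create an empty incremental-LDA state
#'
#' @return an object of class `ilda_model`; feed it samples with
#'   [ilda_partial_fit()].
#' @export
ilda_new <- function() {
  structure(list(classes = character(0), n = integer(0), means = list(),
                 S = NULL, d = NULL),
            class = "ilda_model")
}

#' Update an incremental LDA with new samples
#'
#' Class counts, class means and the pooled within-class scatter are updated
#' one observation at a time (Welford recurrences), so streaming the same
#' sample set in any order yields the same discriminant as batch LDA.
#'
#' @param model an [ilda_new()] state (or a previous update's result).
#' @param new_features matrix (rows = new samples) or single vector.
#' @param new_labels labels of the new samples (zero-length input returns the
#'   model unchanged).
#' @return the updated `ilda_model`.
#' @export
ilda_partial_fit <- function(model, new_features, new_labels) {
  stopifnot(inherits(model, "ilda_model"))
  if (length(new_labels) == 0L) return(model)
  X <- as_matrix(new_features)
  labs <- as.character(new_labels)
  stopifnot(nrow(X) == length(labs))
  if (is.null(model$d)) {
    model$d <- ncol(X)
    model$S <- matrix(0, model$d, model$d)
  }
  if (ncol(X) != model$d) stop_validation("feature dimension changed")
  for (i in seq_len(nrow(X))) {
    cl <- labs[i]
    x <- X[i, ]
    j <- match(cl, model$classes)
    if (is.na(j)) {
      model$classes <- c(model$classes, cl)
      model$n <- c(model$n, 0L)
      model$means[[length(model$classes)]] <- numeric(model$d)
      j <- length(model$classes)
    }
    model$n[j] <- model$n[j] + 1L
    delta <- x - model$means[[j]]
    model$means[[j]] <- model$means[[j]] + delta / model$n[j]
    model$S <- model$S + tcrossprod(delta, x - model$means[[j]])
  }
  model
}

#' Discriminant direction of a fitted incremental LDA (two classes)
#' @param model an updated `ilda_model` with two observed classes.
#' @return numeric vector `Sigma^-1 (mu_2 - mu_1)` (classes in first-seen
#'   order).
#' @export
ilda_direction <- function(model) {
  if (length(model$classes) != 2L)
    stop_validation("discriminant direction requires exactly two observed classes")
  Sigma <- model$S / (sum(model$n) - length(model$classes))
  solve(Sigma, model$means[[2L]] - model$means[[1L]])
}

ilda_predict <- function(model, X) {
  if (length(model$classes) < 2L)
    stop_validation("state error: both classes must be observed before prediction")
  X <- as_matrix(X)
  Sigma <- model$S / (sum(model$n) - length(model$classes))
  Si <- solve(Sigma)
  pri <- model$n / sum(model$n)
  scores <- vapply(seq_along(model$classes), function(j) {
    mu <- model$means[[j]]
    as.numeric(X %*% (Si %*% mu)) - 0.5 * sum(mu * (Si %*% mu)) + log(pri[j])
  }, numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X))
  model$classes[max.col(scores, ties.method = "first")]
}

# ---- Linear SVM by stochastic gradient descent (Pegasos) -------------------

# Mini-batch Pegasos: per iteration a random batch contributes the averaged
# hinge subgradient, with step size 1/(lambda * t); the returned solution
# averages the second half of the iterates.
svm_sgd_fit <- function(X, y, iters, lambda, seed, batch = 16L) {
  lev <- levels(y)
  yy <- ifelse(as.integer(y) == 2L, 1, -1)
  ctr <- colMeans(X); scl <- apply(X, 2L, sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  n <- nrow(Xs); d <- ncol(Xs)
  bsize <- min(batch, n)
  with_seed(seed, {
    w <- numeric(d); b <- 0
    w_avg <- numeric(d); b_avg <- 0
    burn <- floor(iters / 2)
    for (t in seq_len(iters)) {
      idx <- sample.int(n, bsize)
      eta <- 1 / (lambda * t)
      margins <- yy[idx] * (as.numeric(Xs[idx, , drop = FALSE] %*% w) + b)
      viol <- idx[margins < 1]
      w <- (1 - eta * lambda) * w
      if (length(viol)) {
        g <- colSums(Xs[viol, , drop = FALSE] * yy[viol]) / bsize
        w <- w + eta * g
        b <- b + eta * sum(yy[viol]) / bsize
      }
      if (t > burn) {
        w_avg <- w_avg + w
        b_avg <- b_avg + b
      }
    }
    keep <- max(1L, iters - burn)
    list(w = w_avg / keep, b = b_avg / keep, center = ctr, scale = scl,
         levels = lev)
  })
}

svm_sgd_predict <- function(m, X) {
  Xs <- sweep(sweep(X, 2L, m$center), 2L, m$scale, "/")
  s <- as.numeric(Xs %*% m$w) + m$b
  m$levels[ifelse(s > 0, 2L, 1L)]
}

# ---- SVM regularization ratio, pairwise voting -----------------------------

#' Kernel-sum regularization ratio
#'
#' `Q = N / sum_j K(y_j, y_bar)` with `y_bar` the training mean vector: a
#' data-driven regularization scale that stays bounded as the training set
#' grows (duplicating every point leaves it unchanged).
#'
#' @param train_features training matrix (rows = samples).
#' @param kernel `"linear"`, `"rbf"` or `"poly"`.
#' @param gamma,degree,coef0 kernel constants.
#' @return the positive scalar `Q`.
#' @export
svm_regularization_q <- function(train_features, kernel = c("linear", "rbf", "poly"),
                                 gamma = 1, degree = 2, coef0 = 1) {
  kernel <- match.arg(kernel)
  X <- as_matrix(train_features)
  if (nrow(X) == 0L) stop_validation("empty training set")
  ybar <- colMeans(X)
  kv <- switch(kernel,
    linear = as.numeric(X %*% ybar),
    rbf = exp(-gamma * rowSums(sweep(X, 2L, ybar)^2)),
    poly = (gamma * as.numeric(X %*% ybar) + coef0)^degree)
  s <- sum(kv)
  if (!is.finite(s) || s <= 0)
    stop_validation("degenerate kernel sum (<= 0); Q undefined")
  nrow(X) / s
}

#' Pairwise-voting class decision
#'
#' Combines the `n(n-1)/2` signed pairwise decision scores `f_kh` (ordered as
#' `combn(n_classes, 2)`: (1,2), (1,3), ...) by sign voting: a positive score
#' votes for the first class of the pair, a negative one for the second, zero
#' for neither. Returns the class with most votes; ties break toward the
#' lowest class index.
#'
#' @param decisions numeric vector of length `n_classes * (n_classes - 1) / 2`.
#' @param n_classes number of classes (>= 2).
#' @return the winning class index (1-based).
#' @export
#' @examples
#' pairwise_vote(c(1), 2)           # class 1
#' pairwise_vote(rep(0, 6), 4)      # all-zero scores: class 1 by tie rule
pairwise_vote <- function(decisions, n_classes) {
  assert_number(n_classes, "n_classes", lower = 2)
  pairs <- combn(n_classes, 2L)
  if (length(decisions) != ncol(pairs))
    stop_validation(sprintf("expected %d pair decisions, got %d",
                            ncol(pairs), length(decisions)))
  votes <- numeric(n_classes)
  for (p in seq_len(ncol(pairs))) {
    s <- sign(decisions[p])
    if (s > 0) votes[pairs[1L, p]] <- votes[pairs[1L, p]] + 1
    if (s < 0) votes[pairs[2L, p]] <- votes[pairs[2L, p]] + 1
  }
  which.max(votes)
}

# ---- MSE-vs-iterations hyperparameter search -------------------------------

iteration_param <- function(kind) {
  switch(kind, ann = "cycles", svm_linear = "iters", NULL)
}

grid_param_default <- function(kind) {
  switch(kind, knn = "k", svm_rbf = "gamma", svm_poly = "order",
         svm_linear = NA_character_,
         stop_validation("no default grid parameter for kind '", kind, "'"))
}

#' Training-MSE hyperparameter search over a grid and iteration schedule
#'
#' Trains the classifier at every (grid value, iteration cap) cell, records
#' the training MSE between predicted and true binary labels, and selects the
#' grid value whose MSE column is non-increasing over the final three
#' schedule steps (no local-minimum / flattening disqualification) and
#' attains the lowest final-step MSE; ties break toward the first such value.
#' For classifiers without an iteration knob the column is constant and the
#' rule reduces to the minimum-MSE value. Cells whose training fails are
#' recorded as `NA` and excluded from selection.
#'
#' @param kind classifier kind (see [classifier_spec()]).
#' @param grid vector of candidate values of the searched parameter (use
#'   `NA` for the single-column search of `"svm_linear"`).
#' @param schedule increasing vector of iteration caps (table rows).
#' @param X,y training data.
#' @param seed integer seed shared by all cells.
#' @param grid_param name of the searched parameter; defaults to `"k"` for
#'   knn, `"gamma"` for svm_rbf, `"order"` for svm_poly.
#' @return list with `table` (data frame, `length(schedule)` rows x
#'   `length(grid)` columns), `chosen` (the selected grid value) and
#'   `final_mse` (named final-row MSEs).
#' @export
mse_hyperparam_search <- function(kind, grid, schedule, X, y, seed = 1L,
                                  grid_param = NULL) {
  if (!length(grid) || !length(schedule))
    stop_validation("grid and schedule must be nonempty")
  if (is.unsorted(schedule, strictly = TRUE))
    stop_validation("schedule must be strictly increasing")
  if (is.null(grid_param)) grid_param <- grid_param_default(kind)
  it_par <- iteration_param(kind)
  d <- prepare_xy(X, y)
  y01 <- as.integer(d$y) - 1L
  tab <- matrix(NA_real_, length(schedule), length(grid))
  for (gi in seq_along(grid)) {
    for (ti in seq_along(schedule)) {
      prm <- list()
      if (!is.na(grid_param) && !is.na(grid[gi])) prm[[grid_param]] <- grid[gi]
      if (!is.null(it_par)) prm[[it_par]] <- schedule[ti]
      fitted <- tryCatch(
        fit_classifier(build_classifier(classifier_spec(kind, prm, seed = seed)),
                       d$X, d$y),
        error = function(e) NULL)
      if (is.null(fitted)) next
      pred01 <- as.integer(predict(fitted, d$X)) - 1L
      tab[ti, gi] <- mse(pred01, y01)
    }
  }
  colnames(tab) <- if (all(is.na(grid))) kind else as.character(grid)
  rownames(tab) <- as.character(schedule)
  last3 <- tail(seq_along(schedule), 3L)
  eligible <- vapply(seq_along(grid), function(gi) {
    v <- tab[last3, gi]
    all(is.finite(v)) && all(diff(v) <= 0)
  }, logical(1))
  final <- tab[nrow(tab), ]
  cand <- if (any(eligible)) which(eligible) else which(is.finite(final))
  if (!length(cand)) stop_validation("all search cells failed")
  chosen <- grid[cand[which.min(final[cand])]]
  list(table = as.data.frame(tab), chosen = chosen, final_mse = final)
}

# ---- Alarm rule ------------------------------------------------------------

#' Raise seizure alarms from a binary per-window decision stream
#'
#' The 0/1 stream is median-filtered (odd width, edges padded by
#' replication); an alarm fires at every position where `alarm_threshold`
#' consecutive 1s complete (the consecutive counter resets after each alarm).
#'
#' @param binary_stream vector of 0/1 window decisions.
#' @param alarm_threshold required count of consecutive positive windows
#'   (>= 1); patient-dependent, supplied by the caller.
#' @param median_width odd median-filter width (1 = no smoothing).
#' @return integer vector of alarm positions (1-based indices into the
#'   stream).
#' @export
#' @examples
#' seizure_alarm(c(0, 1, 1, 1, 0), alarm_threshold = 3)  # alarm at index 4
seizure_alarm <- function(binary_stream, alarm_threshold, median_width = 1L) {
  if (!all(binary_stream %in% c(0, 1)))
    stop_validation("stream must be binary 0/1")
  assert_number(alarm_threshold, "alarm_threshold", lower = 1)
  assert_number(median_width, "median_width", lower = 1)
  if (median_width %% 2 == 0) stop_validation("median_width must be odd")
  x <- as.numeric(binary_stream)
  n <- length(x)
  if (median_width > 1L && n) {
    h <- (median_width - 1L) / 2L
    padded <- c(rep(x[1L], h), x, rep(x[n], h))
    x <- vapply(seq_len(n), function(i) median(padded[i:(i + 2L * h)]),
                numeric(1))
  }
  alarms <- integer(0)
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (x[i] == 1) run + 1L else 0L
    if (run == alarm_threshold) {
      alarms <- c(alarms, i)
      run <- 0L
    }
  }
  alarms
}
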