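# Independent oracles used across the suite. They deliberately avoid the
# package's own code paths: exhaustive enumeration for the clustering
# optimum, double loops for the entropies.

# Global optimum of 2-cluster hard clustering by enumerating all 2^n
# assignments (per-assignment optimal prototypes: mean for q = 2, median
# for q = 1).
oracle_best_objective_k2 <- function(X, q = 2) {
  X <- as.matrix(X)
  n <- nrow(X)
  best <- Inf
  for (code in 0:(2^n - 1)) {
    grp <- as.logical(bitwAnd(code, bitwShiftL(1L, 0:(n - 1L))))
    obj <- 0
    for (g in list(which(grp), which(!grp))) {
      if (!length(g)) next
      sub <- X[g, , drop = FALSE]
      proto <- if (q == 2) colMeans(sub) else apply(sub, 2, median)
      dev <- sweep(sub, 2, proto)
      obj <- obj + if (q == 2) sum(dev^2) else sum(abs(dev))
    }
    if (obj < best) best <- obj
  }
  best
}

# Brute-force ApEn: Pincus definition, double loop, self-inclusive counts.
oracle_apen <- function(x, m, r_frac) {
  n <- length(x)
  r <- r_frac * sd(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    cnt <- numeric(nt)
    for (i in 1:nt) {
      for (j in 1:nt) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r)
          cnt[i] <- cnt[i] + 1
      }
    }
    mean(log(cnt / nt))
  }
  phi(m) - phi(m + 1)
}

# Brute-force SampEn: n - m templates at both lengths, self-matches excluded.
oracle_sampen <- function(x, m, r_frac) {
  n <- length(x)
  r <- r_frac * sd(x)
  nt <- n - m
  a <- 0; b <- 0
  for (i in 1:nt) {
    for (j in 1:nt) {
      if (i == j) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) b <- b + 1
      if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) a <- a + 1
    }
  }
  if (b == 0) return(NaN)
  if (a == 0) return(Inf)
  -log(a / b)
}

# Two well-separated Gaussian blobs in d = 2 (the standard metaheuristic
# test instance).
make_two_blobs <- function(n_per_blob = 20, gap = 6, sd = 0.4, seed = 1) {
  set.seed(seed)
  rbind(matrix(rnorm(2 * n_per_blob, 0, sd), ncol = 2),
        matrix(rnorm(2 * n_per_blob, gap, sd), ncol = 2))
}

make_blobs <- function(centers, n_each, sd = 0.2, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_each, centers[i, 1], sd), rnorm(n_each, centers[i, 2], sd))))
}

# Linearly separable two-class toy set (for classifier sanity checks).
make_toy_xy <- function(n_per_class = 20, gap = 6, sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n_per_class, 0, sd), ncol = 2),
             matrix(rnorm(2 * n_per_class, gap, sd), ncol = 2))
  list(X = X, y = rep(c("neg", "pos"), each = n_per_class))
}
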