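# Optional signal conditioning before clustering: per-segment
# standardization (default on) and component-based artifact suppression
# (off by default; see the methods vignette for why).

#' Standardize a segment to zero mean and unit variance
#'
#' Uses the unbiased (n - 1) denominator. Metadata (id, label, fs) is
#' preserved. Idempotent and commutes with a sign flip of the input.
#'
#' @param segment an [eeg_segment()] with positive sample variance.
#' @return the standardized [eeg_segment()].
#' @export
standardize_segment <- function(segment) {
  stopifnot(inherits(segment, "eeg_segment"))
  s <- sd(segment$samples)
  if (!is.finite(s) || s <= 0)
    stop_validation("degenerate input: constant segment cannot be standardized")
  segment$samples <- (segment$samples - mean(segment$samples)) / s
  segment
}

# Excess kurtosis (population moments): mean((x - m)^4) / var^2 - 3.
excess_kurtosis <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v <= 0) return(0)
  mean((x - m)^4) / v^2 - 3
}

# Compact FastICA (logcosh contrast, symmetric decorrelation) on a
# channels x time matrix. Returns sources S (comp x time), mixing A
# (channels x comp) and the channel means, so that X ~ A %*% S + means.
fastica_decompose <- function(X, n_components, max_iter = 200, tol = 1e-8,
                              seed = 1) {
  n_ch <- nrow(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  nt <- ncol(X)
  eg <- eigen(Xc %*% t(Xc) / nt, symmetric = TRUE)
  d <- pmax(eg$values[seq_len(n_components)], .Machine$double.eps)
  E <- eg$vectors[, seq_len(n_components), drop = FALSE]
  K <- diag(1 / sqrt(d), n_components) %*% t(E)       # whitening
  Kinv <- E %*% diag(sqrt(d), n_components)           # de-whitening
  Z <- K %*% Xc
  W <- with_seed(seed, matrix(rnorm(n_components^2), n_components))
  sw <- svd(W); W <- sw$u %*% t(sw$v)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- G %*% t(Z) / nt - diag(rowMeans(1 - G^2), n_components) %*% W
    sw <- svd(W1)
    W1 <- sw$u %*% t(sw$v)
    if (max(abs(abs(diag(W1 %*% t(W))) - 1)) < tol) { W <- W1; break }
    W <- W1
  }
  list(S = W %*% Z, A = Kinv %*% t(W), means = mu)
}

#' Suppress high-kurtosis independent components within each class
#'
#' Stacks same-class segments as pseudo-channels (segments x time), extracts
#' `n_components` maximally non-Gaussian components, zeroes every component
#' whose absolute excess kurtosis exceeds `kurtosis_threshold`, and
#' reconstructs the segments. With `kurtosis_threshold = Inf` and
#' `n_components` equal to the class segment count, reconstruction is the
#' identity up to numerical tolerance.
#'
#' @param dataset an [eeg_dataset()].
#' @param n_components components per class, `2 <= n_components <=` segments
#'   in each class.
#' @param kurtosis_threshold absolute excess-kurtosis rejection threshold
#'   (default 5, a standard artifact heuristic).
#' @param seed seed for the decomposition's random initialization.
#' @return the reconstructed [eeg_dataset()], with an attribute
#'   `n_removed` giving the number of zeroed components.
#' @export
remove_artifact_components <- function(dataset, n_components,
                                       kurtosis_threshold = 5, seed = 1) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  labs <- dataset_labels(dataset)
  segs <- dataset$segments
  n_removed <- 0L
  for (cls in unique(labs)) {
    idx <- which(labs == cls)
    if (n_components < 2 || n_components > length(idx))
      stop_validation("n_components must be in [2, segments per class]; class '",
                      cls, "' has ", length(idx))
    X <- do.call(rbind, lapply(segs[idx], function(s) s$samples))
    dec <- fastica_decompose(X, n_components, seed = derive_seed(seed, cls))
    kur <- apply(dec$S, 1L, excess_kurtosis)
    drop <- abs(kur) > kurtosis_threshold
    n_removed <- n_removed + sum(drop)
    S <- dec$S
    S[drop, ] <- 0
    Xr <- dec$A %*% S + dec$means
    for (j in seq_along(idx)) segs[[idx[j]]]$samples <- as.numeric(Xr[j, ])
  }
  out <- eeg_dataset(segs)
  attr(out, "n_removed") <- n_removed
  out
}
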