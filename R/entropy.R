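# Regularity statistics used for cluster-separability analysis. ApEn and
# SampEn count template matches of length m within tolerance r under the
# Chebyshev distance; Shannon entropy is histogram-based, in bits.

# n_templates x n_templates logical match matrix at embedding length m:
# chebyshev distance between templates <= r. Computed incrementally so the
# m+1 matrix reuses the m matrix.
template_matches <- function(x, m, r) {
  n <- length(x)
  nt <- n - m + 1L
  M <- matrix(TRUE, nt, nt)
  for (off in 0:(m - 1L)) {
    v <- x[(1L + off):(nt + off)]
    M <- M & (abs(outer(v, v, "-")) <= r)
  }
  M
}

resolve_r <- function(x, r) {
  s <- sd(x)
  if (!is.finite(s)) s <- 0
  r * s
}

#' Approximate entropy (ApEn)
#'
#' `ApEn(m, r) = Phi_m - Phi_(m+1)` with `Phi_m` the mean natural log of the
#' self-inclusive fraction of length-`m` templates within Chebyshev tolerance
#' `r*sd(x)` of each template. A constant series has ApEn 0; irregular
#' series score higher than regular ones of the same length.
#'
#' @param x numeric series of length at least `m + 2`.
#' @param m embedding dimension (>= 1); default 2 (the usual convention).
#' @param r tolerance as a fraction of the series standard deviation;
#'   default 0.2.
#' @return the ApEn value (natural log units).
#' @export
approximate_entropy <- function(x, m = 2L, r = 0.2) {
  x <- as.numeric(x)
  assert_number(m, "m", lower = 1)
  assert_number(r, "r", lower = .Machine$double.xmin)
  n <- length(x)
  if (n < m + 2L) stop_validation("series too short: need length >= m + 2")
  rr <- resolve_r(x, r)
  phi <- function(mm) {
    M <- template_matches(x, mm, rr)
    mean(log(rowMeans(M)))
  }
  phi(m) - phi(m + 1L)
}

#' Sample entropy (SampEn)
#'
#' `-ln(A / B)` where `B` and `A` count ordered template pairs (excluding
#' self-matches) within Chebyshev tolerance `r*sd(x)` at lengths `m` and
#' `m + 1`, both over the first `n - m` templates (the standard convention
#' removing the self-match bias of ApEn). Returns `Inf` when no length-`m + 1`
#' pair matches (`A = 0`); callers should treat that as missing.
#'
#' @inheritParams approximate_entropy
#' @return the SampEn value, or `Inf` when `A = 0` (or `NaN` if `B = 0` too).
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2) {
  x <- as.numeric(x)
  assert_number(m, "m", lower = 1)
  assert_number(r, "r", lower = .Machine$double.xmin)
  n <- length(x)
  if (n < m + 2L) stop_validation("series too short: need length >= m + 2")
  rr <- resolve_r(x, r)
  nt <- n - m                    # templates used at both lengths
  Mm <- template_matches(x, m, rr)[seq_len(nt), seq_len(nt), drop = FALSE]
  Mm1 <- template_matches(x, m + 1L, rr)
  b <- sum(Mm) - nt              # exclude self-matches
  a <- sum(Mm1) - nt
  if (b == 0) return(NaN)
  if (a == 0) return(Inf)
  -log(a / b)
}

#' Shannon entropy of a histogram, in bits
#'
#' Bins the series into `bins` equal-width bins over `[min(x), max(x)]` and
#' returns `-sum p_i log2 p_i` with `0 log 0 = 0`. A constant series occupies
#' a single bin and has entropy 0; a sample exactly uniform over the bins
#' attains the maximum `log2(bins)`.
#'
#' @param x numeric series.
#' @param bins number of bins (>= 2); default 16.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(x, bins = 16L) {
  x <- as.numeric(x)
  assert_number(bins, "bins", lower = 2)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(0)
  br <- seq(lo, hi, length.out = bins + 1L)
  idx <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(idx, nbins = bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}
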