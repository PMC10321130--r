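# Internal helpers: seeded evaluation and seed derivation.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards so library code never perturbs it.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a master seed and context tokens
#'
#' Deterministic integer hash of a master seed plus arbitrary tokens
#' (character or numeric), used so that per-segment / per-restart seeds do not
#' depend on generation order. The result is always in `[1, 2^31 - 20]`.
#'
#' @param master integer master seed.
#' @param ... character or numeric tokens identifying the consumer.
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(1, "ictal", 7)
derive_seed <- function(master, ...) {
  toks <- c(master, unlist(list(...), use.names = FALSE))
  h <- 0
  for (t in toks) {
    v <- if (is.character(t)) sum(utf8ToInt(t)) else as.numeric(t)
    if (!is.finite(v)) stop("seed tokens must be finite")
    h <- (h * 31 + abs(v)) %% 2147483629
  }
  as.integer(h %% 2147483627 + 1)
}

stop_validation <- function(...) stop(..., call. = FALSE)

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop_validation(sprintf("'%s' must be a single finite number in [%s, %s]",
                            name, format(lower), format(upper)))
  x
}

as_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(as.numeric(X), ncol = 1L)
  storage.mode(X) <- "double"
  X
}
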