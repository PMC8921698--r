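#' @importFrom stats cor dist hclust cutree rnorm runif rbinom sd var
#'   predict quantile setNames
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a per-stream seed from a global seed
#'
#' All generators in the package are pure functions of (parameters, seed).
#' When one global seed has to feed several independent random streams
#' (e.g. geometry placement vs. activity noise), sub-seeds are derived by a
#' fixed affine scheme so that streams do not collide and the whole
#' synthetic study is reproducible from a single integer.
#'
#' @param seed integer global seed.
#' @param stream integer stream index (>= 0).
#' @return an integer seed strictly below 2^31.
#' @export
derive_seed <- function(seed, stream = 0L) {
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  as.integer((abs(seed) + 10007 * (as.integer(stream) + 1L)) %% .Machine$integer.max)
}

# Run code under a temporary RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Euclidean distance between two 3-vectors.
vec_dist <- function(a, b) sqrt(sum((a - b)^2))

# n x m distance matrix between rows of two coordinate matrices.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
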