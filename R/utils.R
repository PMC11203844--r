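# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

STATE_LEVELS <- c("active", "intermediate", "inactive")

state_factor <- function(x) factor(x, levels = STATE_LEVELS)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stopf("'%s' = %g is outside the allowed range", name, x)
  as.numeric(x)
}

#' Derive a stage seed from a master seed
#'
#' One master seed fans out to per-stage seeds through a splitmix-style
#' integer mix of the seed and a stage label, so any stage of an experiment
#' can be re-run in isolation with the seed it actually used.
#'
#' @param seed master seed (integer).
#' @param label character stage label.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  seed <- assert_count(seed, "seed", min = 0L)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  x <- (as.numeric(seed) + h + 1) %% 2147483647
  # a few LCG rounds; multipliers small enough that doubles stay exact
  for (i in 1:3) x <- (69069 * x + 1234567) %% 2147483647
  as.integer(x)
}

# largest-remainder apportionment of n into round(n * p) integer counts
largest_remainder <- function(n, p) {
  if (abs(sum(p) - 1) > 1e-9) stopf("proportions must sum to 1")
  raw <- n * p
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    take <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

# truncated normal sampling by inverse-CDF; vectorized over n
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo < 1e-12)
    stopf("truncation interval [%g, %g] has negligible mass", lower, upper)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

# random unit vectors in R^3, n x 3
runit3 <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# squared Euclidean cross-distance matrix, clamped at zero
cross_dist <- function(A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# indices of the k nearest rows of B for each row of A; ties broken by
# lowest index. exclude_self drops the identical row index (A == B case).
knn_index <- function(A, B = A, k, exclude_self = identical(A, B)) {
  D <- cross_dist(A, B)
  n <- nrow(A)
  out <- matrix(NA_integer_, n, k)
  for (i in seq_len(n)) {
    d <- D[i, ]
    if (exclude_self) d[i] <- Inf
    out[i, ] <- order(d, seq_along(d))[seq_len(k)]
  }
  out
}
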