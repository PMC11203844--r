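# Shared fixtures, built once per test run and memoized. Everything is
# generated in code; no stored data files.

fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name, build) {
  if (!exists(name, envir = fixture_cache))
    assign(name, build(), envir = fixture_cache)
  get(name, envir = fixture_cache)
}

# small synthetic study: 300 frames, default imbalance and planted residues
small_study <- function() get_fixture("small_study", function() {
  sim <- generate_ensemble(synth_config(n_frames = 300, seed = 101))
  lf <- label_ensemble(sim$ensemble)
  sp <- split_data(lf$X, lf$y, 0.2, seed = 102)
  list(sim = sim, lf = lf, sp = sp)
})

# a small but genuinely trained CNN on the study above
small_cnn <- function() get_fixture("small_cnn", function() {
  d <- small_study()
  cnn1d(d$sp$train$X, d$sp$train$y,
        model_config(conv_blocks = list(c(8L, 7L, 2L)),
                     dense_units = 16L, dropout = 0,
                     epochs = 10, early_stop_patience = 4, seed = 103),
        validation = d$sp$validation)
})

# hand-built linear "network" wrapped as a cnn1d: logit_k = W[, k] . x + b
linear_cnn <- function(W, b = numeric(ncol(W)),
                       levels = paste0("c", seq_len(ncol(W))),
                       channels = 1L) {
  structure(list(
    layers = list(list(type = "dense", activation = "linear",
                       W = W, b = b)),
    levels = levels, channels = channels,
    in_L = nrow(W) %/% channels,
    center = rep(0, nrow(W)), scale = rep(1, nrow(W))),
    class = "cnn1d")
}

# brute-force Euclidean distance matrix (independent of the package's
# cross_dist; used as the oracle in neighbor-based tests)
oracle_dist <- function(A, B = A) {
  D <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      D[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  D
}

# 2D Gaussian-blob toy with controllable imbalance
gaussian_toy <- function(n_per_class, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- NULL; y <- character(0)
  for (i in seq_along(n_per_class)) {
    X <- rbind(X, cbind(rnorm(n_per_class[i], centers[[i]][1], sd),
                        rnorm(n_per_class[i], centers[[i]][2], sd)))
    y <- c(y, rep(names(n_per_class)[i], n_per_class[i]))
  }
  list(X = X, y = factor(y))
}
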