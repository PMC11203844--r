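# A compact 1D convolutional network over residue position sequences
# (3 xyz channels per residue), written directly in R so that every
# layer's weights and activations stay accessible to the relevance
# propagation in explain.R. Convolutions are realized as compiled
# im2col gathers (src/conv_ops.cpp) followed by dense matrix products
# (BLAS); max-pooling stores its winners for both backprop and
# winner-take-all relevance routing.

#' Network and training configuration
#'
#' @param conv_blocks list of `(filters, kernel_size, pool_size)` triples
#'   applied in order; an empty list gives a plain dense network.
#' @param dense_units sizes of the fully connected hidden layers.
#' @param dropout dropout fraction on dense hidden activations, in
#'   `[0, 1)`.
#' @param learning_rate Adam step size.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping (training-loss when no validation set is supplied).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout; identical seeds give identical fits.
#' @return an object of class `model_config`.
#' @export
model_config <- function(conv_blocks = list(c(16L, 7L, 2L),
                                            c(32L, 7L, 2L)),
                         dense_units = 64L,
                         dropout = 0.2,
                         learning_rate = 1e-3,
                         epochs = 40L,
                         batch_size = 64L,
                         early_stop_patience = 6L,
                         seed = 1L) {
  if (!is.list(conv_blocks))
    stopf("'conv_blocks' must be a list of (filters, kernel, pool) triples")
  for (b in conv_blocks) {
    if (length(b) != 3L || any(b < 1L) || any(b != round(b)))
      stopf("each conv block must be three positive integers (filters, kernel, pool)")
  }
  dropout <- assert_number(dropout, "dropout", lower = 0)
  if (dropout >= 1) stopf("'dropout' must be in [0, 1)")
  structure(list(conv_blocks = lapply(conv_blocks, as.integer),
                 dense_units = as.integer(dense_units),
                 dropout = dropout,
                 learning_rate = assert_number(learning_rate,
                                               "learning_rate", lower = 0,
                                               strict_lower = TRUE),
                 epochs = assert_count(epochs, "epochs"),
                 batch_size = assert_count(batch_size, "batch_size"),
                 early_stop_patience = assert_count(early_stop_patience,
                                                    "early_stop_patience",
                                                    min = 0L),
                 seed = assert_count(seed, "seed", min = 0L)),
            class = "model_config")
}

build_network <- function(cfg, in_L, in_C, n_classes) {
  layers <- list()
  L <- in_L; C <- in_C
  for (b in cfg$conv_blocks) {
    f <- b[1]; k <- b[2]; pool <- b[3]
    if (k > L)
      stopf("conv kernel %d exceeds current sequence length %d", k, L)
    conv_L <- L - k + 1L
    pool <- min(pool, conv_L)
    kC <- k * C
    layers[[length(layers) + 1L]] <- list(
      type = "conv",
      W = matrix(stats::rnorm(kC * f, sd = sqrt(2 / kC)), kC, f),
      b = numeric(f),
      k = k, pool = pool, in_L = L, in_C = C,
      conv_L = conv_L, out_L = conv_L %/% pool, kC = kC, filters = f)
    L <- conv_L %/% pool
    if (L < 1L) stopf("pooling reduced the sequence below length 1")
    C <- f
  }
  d_in <- L * C
  for (u in cfg$dense_units) {
    layers[[length(layers) + 1L]] <- list(
      type = "dense", activation = "relu",
      W = matrix(stats::rnorm(d_in * u, sd = sqrt(2 / d_in)), d_in, u),
      b = numeric(u))
    d_in <- u
  }
  layers[[length(layers) + 1L]] <- list(
    type = "dense", activation = "linear",
    W = matrix(stats::rnorm(d_in * n_classes, sd = sqrt(1 / d_in)),
               d_in, n_classes),
    b = numeric(n_classes))
  layers
}

relu <- function(x) pmax(x, 0)

# forward pass over standardized inputs; returns logits and, optionally,
# per-layer caches needed by backprop and LRP
nn_forward <- function(layers, X, cache = FALSE, dropout = 0,
                       training = FALSE) {
  n <- nrow(X)
  caches <- if (cache) vector("list", length(layers)) else NULL
  A <- X
  for (li in seq_along(layers)) {
    ly <- layers[[li]]
    if (ly$type == "conv") {
      M <- conv_im2col(A, ly$in_C, ly$k, ly$conv_L)
      Z <- M %*% ly$W
      Z <- sweep(Z, 2, ly$b, "+")
      pf <- conv_pool_fwd(relu(Z), n, ly$conv_L, ly$pool, ly$out_L)
      A <- pf$A
      if (cache)
        caches[[li]] <- list(M = M, Z = Z, win = pf$win, n = n)
    } else {
      Z <- A %*% ly$W
      Z <- sweep(Z, 2, ly$b, "+")
      if (ly$activation == "relu") {
        H <- relu(Z)
        mask <- NULL
        if (training && dropout > 0) {
          mask <- matrix(stats::runif(length(H)) >= dropout,
                         nrow(H), ncol(H)) / (1 - dropout)
          H <- H * mask
        }
        if (cache)
          caches[[li]] <- list(A_in = A, Z = Z, mask = mask)
        A <- H
      } else {
        if (cache) caches[[li]] <- list(A_in = A, Z = Z)
        A <- Z
      }
    }
  }
  list(logits = A, caches = caches)
}

# backward pass; dLogits is n x K. Returns gradients per layer and,
# when input_grad = TRUE, the gradient with respect to the network input.
nn_backward <- function(layers, caches, dLogits, input_grad = FALSE) {
  n <- nrow(dLogits)
  grads <- vector("list", length(layers))
  dA <- dLogits
  for (li in rev(seq_along(layers))) {
    ly <- layers[[li]]
    ch <- caches[[li]]
    if (ly$type == "dense") {
      dZ <- dA
      if (ly$activation == "relu") {
        if (!is.null(ch$mask)) dZ <- dZ * ch$mask
        dZ <- dZ * (ch$Z > 0)
      }
      grads[[li]] <- list(W = crossprod(ch$A_in, dZ), b = colSums(dZ))
      dA <- tcrossprod(dZ, ly$W)
    } else {
      dH <- conv_pool_bwd(dA, ch$win, n, ly$conv_L, ly$pool, ly$out_L)
      dZ <- dH * (ch$Z > 0)
      grads[[li]] <- list(W = crossprod(ch$M, dZ), b = colSums(dZ))
      dM <- tcrossprod(dZ, ly$W)
      dA <- conv_col2im(dM, n, ly$in_L, ly$in_C, ly$k)
    }
  }
  list(grads = grads, dX = if (input_grad) dA else NULL)
}

# chunked forward pass: the im2col expansion is ~kC-fold, so large
# inputs are pushed through in row blocks to bound memory
nn_logits_chunked <- function(layers, X, chunk = 512L) {
  n <- nrow(X)
  if (n <= chunk) return(nn_forward(layers, X)$logits)
  out <- NULL
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    out <- rbind(out, nn_forward(layers, X[s:e, , drop = FALSE])$logits)
  }
  out
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Fit the 1D convolutional conformational-state classifier
#'
#' Trains a small convolutional network (conv/ReLU/max-pool blocks, dense
#' ReLU layers, softmax head) on flattened residue-coordinate features by
#' minibatch Adam on the (optionally class-weighted) cross-entropy.
#' Inputs are standardized internally with the training-set mean and
#' standard deviation, stored in the fitted object and applied at
#' prediction time. All randomness (initialization, shuffling, dropout)
#' is driven by `config$seed`, so fits are exactly reproducible.
#'
#' @param x numeric feature matrix, `n x (channels * length)` with
#'   position-major, channel-minor columns (the layout of
#'   [flatten_features()]).
#' @param y class factor; its level order fixes the class order of all
#'   outputs.
#' @param config a [model_config()].
#' @param class_weights optional positive per-class loss weights (named
#'   by class or in level order), e.g. from [class_weights()].
#' @param validation optional list with elements `X` and `y` used for
#'   early stopping and the training log.
#' @param channels input channels per position (3 for xyz coordinates).
#' @param standardize center/scale inputs with training statistics.
#' @return an object of class `cnn1d` with `predict`, `print`,
#'   `summary`, `plot` and `coef` methods.
#' @export
cnn1d <- function(x, y, config = model_config(), class_weights = NULL,
                  validation = NULL, channels = 3L, standardize = TRUE,
                  verbose = FALSE) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stopf("'x' contains non-finite values")
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  K <- nlevels(y)
  if (K < 2L) stopf("need at least two classes")
  channels <- assert_count(channels, "channels")
  if (ncol(x) %% channels != 0L)
    stopf("ncol(x) = %d is not a multiple of channels = %d",
          ncol(x), channels)
  in_L <- ncol(x) %/% channels

  w <- rep(1, K)
  if (!is.null(class_weights)) {
    if (length(class_weights) != K || any(class_weights <= 0))
      stopf("'class_weights' needs one positive weight per class")
    w <- if (!is.null(names(class_weights)))
      as.numeric(class_weights[levels(y)]) else as.numeric(class_weights)
    if (anyNA(w)) stopf("'class_weights' names do not match class levels")
  }

  set.seed(config$seed)
  center <- if (standardize) colMeans(x) else rep(0, ncol(x))
  scale <- if (standardize) {
    s <- apply(x, 2, stats::sd)
    s[s < 1e-8] <- 1
    s
  } else rep(1, ncol(x))
  Xs <- sweep(sweep(x, 2, center), 2, scale, "/")

  has_val <- !is.null(validation)
  if (has_val) {
    Xv <- sweep(sweep(as.matrix(validation$X), 2, center), 2, scale, "/")
    yv <- factor(validation$y, levels = levels(y))
    Yv1 <- diag(K)[as.integer(yv), , drop = FALSE]
  }

  layers <- build_network(config, in_L, channels, K)
  adam <- lapply(layers, function(ly)
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0

  n <- nrow(Xs)
  Y1 <- diag(K)[as.integer(y), , drop = FALSE]
  samp_w <- w[as.integer(y)]

  eval_loss <- function(X, Y1h, sw) {
    p <- softmax(nn_forward(layers, X)$logits)
    ll <- -log(pmax(rowSums(p * Y1h), 1e-12))
    sum(sw * ll) / sum(sw)
  }

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_acc = numeric(0))
  best_loss <- Inf; best_layers <- layers; patience_left <- config$early_stop_patience
  for (epoch in seq_len(config$epochs)) {
    idx <- sample.int(n)
    nb <- ceiling(n / config$batch_size)
    tot_loss <- 0; tot_w <- 0
    for (bi in seq_len(nb)) {
      rows <- idx[((bi - 1) * config$batch_size + 1):min(bi * config$batch_size, n)]
      Xb <- Xs[rows, , drop = FALSE]
      Yb <- Y1[rows, , drop = FALSE]
      wb <- samp_w[rows]
      fw <- nn_forward(layers, Xb, cache = TRUE,
                       dropout = config$dropout, training = TRUE)
      p <- softmax(fw$logits)
      ll <- -log(pmax(rowSums(p * Yb), 1e-12))
      loss <- sum(wb * ll)
      if (!is.finite(loss))
        stopf("NaN/Inf training loss at epoch %d, batch %d (lr too high?)",
              epoch, bi)
      tot_loss <- tot_loss + loss; tot_w <- tot_w + sum(wb)
      dLogits <- (p - Yb) * (wb / sum(wb))
      bw <- nn_backward(layers, fw$caches, dLogits)
      t_step <- t_step + 1
      for (li in seq_along(layers)) {
        g <- bw$grads[[li]]
        st <- adam[[li]]
        st$mW <- b1 * st$mW + (1 - b1) * g$W
        st$vW <- b2 * st$vW + (1 - b2) * g$W^2
        st$mb <- b1 * st$mb + (1 - b1) * g$b
        st$vb <- b2 * st$vb + (1 - b2) * g$b^2
        corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
        layers[[li]]$W <- layers[[li]]$W -
          config$learning_rate * (st$mW / corr1) /
          (sqrt(st$vW / corr2) + eps)
        layers[[li]]$b <- layers[[li]]$b -
          config$learning_rate * (st$mb / corr1) /
          (sqrt(st$vb / corr2) + eps)
        adam[[li]] <- st
      }
    }
    train_loss <- tot_loss / tot_w
    if (has_val) {
      pv <- softmax(nn_forward(layers, Xv)$logits)
      val_loss <- mean(-log(pmax(rowSums(pv * Yv1), 1e-12)))
      val_acc <- mean(max.col(pv) == as.integer(yv))
    } else {
      val_loss <- NA_real_; val_acc <- NA_real_
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = train_loss,
                                val_loss = val_loss, val_acc = val_acc))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                      epoch, train_loss, val_loss, val_acc))
    monitor <- if (has_val) val_loss else train_loss
    if (monitor < best_loss - 1e-6) {
      best_loss <- monitor
      best_layers <- layers
      patience_left <- config$early_stop_patience
    } else {
      patience_left <- patience_left - 1
      if (patience_left < 0) break
    }
  }

  structure(list(layers = best_layers, config = config,
                 levels = levels(y), channels = channels, in_L = in_L,
                 center = center, scale = scale,
                 class_weights = stats::setNames(w, levels(y)),
                 history = history),
            class = "cnn1d")
}

#' Pipeline-facing wrapper around [cnn1d()]
#'
#' Accepts the pipeline containers directly: `train` may be a list with
#' `X`/`y`, a `labeled_features` or a `resampled_dataset` (whose attached
#' class weights are honored unless overridden).
#'
#' @param train training data container.
#' @param cfg a [model_config()].
#' @param class_weights optional per-class weights.
#' @param validation optional validation container (list with `X`, `y`).
#' @return a fitted `cnn1d`.
#' @export
train_cnn <- function(train, cfg = model_config(), class_weights = NULL,
                      validation = NULL) {
  if (is.null(class_weights) && !is.null(train$class_weights))
    class_weights <- train$class_weights
  cnn1d(train$X, train$y, config = cfg, class_weights = class_weights,
        validation = validation)
}

# standardize raw features with the model's stored statistics
model_standardize <- function(object, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(object$center))
    stopf("expected %d feature columns, got %d",
          length(object$center), ncol(x))
  sweep(sweep(x, 2, object$center), 2, object$scale, "/")
}

# forward with caches on raw inputs (used by the explain module)
cnn_forward_cache <- function(object, x) {
  Xs <- model_standardize(object, x)
  fw <- nn_forward(object$layers, Xs, cache = TRUE)
  fw$Xs <- Xs
  fw
}

# gradient of the target-class logit with respect to the *raw* input
cnn_input_gradient <- function(object, x, target) {
  x <- as.matrix(x)
  fw <- cnn_forward_cache(object, x)
  K <- length(object$levels)
  ti <- target_index(object, target)
  dLogits <- matrix(0, nrow(x), K)
  dLogits[, ti] <- 1
  bw <- nn_backward(object$layers, fw$caches, dLogits, input_grad = TRUE)
  sweep(bw$dX, 2, object$scale, "/")
}

target_index <- function(object, target) {
  if (is.numeric(target)) return(as.integer(target))
  ti <- match(as.character(target), object$levels)
  if (is.na(ti)) stopf("unknown target class '%s'", target)
  ti
}

#' Predict method for cnn1d models
#'
#' @param object a fitted `cnn1d`.
#' @param x feature matrix in the training layout.
#' @param type `"class"` for labels, `"prob"` for softmax probabilities
#'   (rows sum to 1), `"logit"` for raw scores.
#' @param ... unused.
#' @export
predict.cnn1d <- function(object, x, type = c("class", "prob", "logit"),
                          ...) {
  type <- match.arg(type)
  Xs <- model_standardize(object, x)
  logits <- nn_logits_chunked(object$layers, Xs)
  colnames(logits) <- object$levels
  if (type == "logit") return(logits)
  p <- softmax(logits)
  colnames(p) <- object$levels
  if (type == "prob") return(p)
  factor(object$levels[max.col(p)], levels = object$levels)
}

#' @export
print.cnn1d <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b), 0))
  cat(sprintf("cnn1d: %d-position x %d-channel input, %d classes, %d parameters\n",
              x$in_L, x$channels, length(x$levels), np))
  for (ly in x$layers) {
    if (ly$type == "conv")
      cat(sprintf("  conv(%d filters, kernel %d) + relu + maxpool(%d)\n",
                  ly$filters, ly$k, ly$pool))
    else
      cat(sprintf("  dense(%d) [%s]\n", ncol(ly$W), ly$activation))
  }
  cat(sprintf("  trained %d epochs%s\n", nrow(x$history),
              if (!all(is.na(x$history$val_loss)))
                sprintf(", final val loss %.4f",
                        x$history$val_loss[nrow(x$history)]) else ""))
  invisible(x)
}

#' @export
summary.cnn1d <- function(object, ...) {
  print(object)
  cat("class weights:\n")
  print(round(object$class_weights, 4))
  cat("training history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
plot.cnn1d <- function(x, ...) {
  h <- x$history
  ylim <- range(c(h$train_loss, h$val_loss), na.rm = TRUE)
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
       ylab = "cross-entropy loss", ylim = ylim, ...)
  if (!all(is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::legend("topright", legend = c("train", "validation"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' @export
coef.cnn1d <- function(object, ...) {
  lapply(object$layers, function(ly) list(W = ly$W, b = ly$b))
}

#' Stratified train/validation split
#'
#' @param X feature matrix. @param y class factor.
#' @param val_fraction fraction held out per class.
#' @param seed integer seed.
#' @return list with `train` and `validation`, each a list of `X`, `y`
#'   and the original row indices `idx`.
#' @export
split_data <- function(X, y, val_fraction = 0.2, seed = 1L) {
  X <- as.matrix(X); y <- if (is.factor(y)) y else factor(y)
  val_fraction <- assert_number(val_fraction, "val_fraction", lower = 0,
                                upper = 1)
  set.seed(assert_count(seed, "seed", min = 0L))
  val_idx <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) == 0L) next
    if (length(idx) < 2L)
      stopf("class '%s' has fewer than 2 samples; cannot split", cl)
    n_val <- round(val_fraction * length(idx))
    n_val <- min(max(n_val, 0L), length(idx) - 1L)
    if (n_val > 0L) val_idx <- c(val_idx, sample(idx, n_val))
  }
  val_idx <- sort(val_idx)
  tr_idx <- setdiff(seq_along(y), val_idx)
  list(train = list(X = X[tr_idx, , drop = FALSE], y = y[tr_idx],
                    idx = tr_idx),
       validation = list(X = X[val_idx, , drop = FALSE], y = y[val_idx],
                         idx = val_idx))
}
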