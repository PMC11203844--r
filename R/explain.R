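# Residue-level attribution: layer-wise relevance propagation (epsilon
# rule), gradient saliency, LIME-style local surrogates, Kernel SHAP and
# permutation importance. Coordinate-level attributions are computed
# internally and summed over each residue's three coordinates; LIME and
# SHAP treat whole residues as players (the three coordinates toggle
# together), which keeps coalition sampling tractable at 282 players.

new_explanation <- function(values, target, method, sample_id = NA) {
  structure(list(values = as.numeric(values), target_class = target,
                 method = method, sample_id = sample_id),
            class = "explanation_vector")
}

#' @export
print.explanation_vector <- function(x, ...) {
  cat(sprintf("explanation_vector [%s] toward '%s': %d residues\n",
              x$method, x$target_class, length(x$values)))
  top <- order(abs(x$values), decreasing = TRUE)[seq_len(min(5, length(x$values)))]
  cat("top |contribution| residues (0-based):",
      paste(sprintf("%d (%.3g)", top - 1L, x$values[top]),
            collapse = ", "), "\n")
  invisible(x)
}

# sum a coordinate-level matrix (n x ch*R) into per-residue values
# (n x R); ch is the channels-per-position of the model (3 for xyz)
per_residue_sum <- function(V, channels = 3L) {
  if (channels == 1L) return(V)
  P <- ncol(V) %/% channels
  out <- V[, seq(1, by = channels, length.out = P), drop = FALSE]
  for (a in 2:channels)
    out <- out + V[, seq(a, by = channels, length.out = P), drop = FALSE]
  out
}

# column index groups treated as one interpretable unit: one group per
# position (channels consecutive columns); residue triplets for the
# coordinate models, single columns for flat toys
feature_groups <- function(p, channels = NULL) {
  if (is.null(channels)) channels <- if (p %% 3L == 0L) 3L else 1L
  lapply(seq_len(p %/% channels),
         function(r) (channels * (r - 1L) + 1L):(channels * r))
}

model_channels <- function(model) {
  if (inherits(model, "cnn1d")) model$channels else NULL
}

# probability-of-target evaluator for a cnn1d or a plain function(X)
prob_fun <- function(model, target) {
  if (inherits(model, "cnn1d")) {
    ti <- target_index(model, target)
    function(X) predict(model, X, type = "prob")[, ti]
  } else if (is.function(model)) {
    model
  } else stopf("'model' must be a cnn1d fit or a function(X) -> numeric")
}

sign0 <- function(z) ifelse(z >= 0, 1, -1)

#' Layer-wise relevance propagation (epsilon rule)
#'
#' Backward relevance pass from the target-class logit to the network
#' input. At every linear (dense or convolutional) layer the relevance of
#' neuron j with pre-activation `z_j` is redistributed to its inputs in
#' proportion to `x_i w_ij / (z_j + eps * sign(z_j))`; the bias share is
#' redistributed uniformly over the neuron's contributing inputs so that
#' relevance is conserved up to the epsilon stabilizer. Max-pooling
#' routes relevance to the pooling winner; the softmax is excluded
#' (logits are explained). The per-layer stabilizer is
#' `epsilon * mean(|z|)`.
#'
#' @param model a fitted [cnn1d()].
#' @param x a single feature vector or a matrix of samples.
#' @param target class label (or index) whose logit is decomposed; may be
#'   a vector with one entry per row of `x`.
#' @param epsilon relative stabilizer (default 1e-6).
#' @return for a single sample, an `explanation_vector` of per-residue
#'   signed relevances; for a matrix, an n x residues matrix. The
#'   attribute `"conservation"` carries `|sum(relevance) - logit|` per
#'   sample.
#' @export
lrp <- function(model, x, target, epsilon = 1e-6) {
  single <- is.null(dim(x))
  X <- if (single) matrix(x, 1) else as.matrix(x)
  V <- lrp_core(model, X, target, epsilon)
  ch <- model$channels
  if (single) {
    ev <- new_explanation(per_residue_sum(V$R, ch)[1, ], target, "lrp")
    attr(ev, "conservation") <- V$conservation[1]
    ev
  } else {
    out <- per_residue_sum(V$R, ch)
    attr(out, "conservation") <- V$conservation
    out
  }
}

lrp_core <- function(model, X, target, epsilon = 1e-6) {
  if (!inherits(model, "cnn1d"))
    stopf("LRP requires a cnn1d model (per-layer weight access)")
  n <- nrow(X)
  fw <- cnn_forward_cache(model, X)
  layers <- model$layers
  K <- length(model$levels)
  ti <- vapply(rep(target, length.out = n), function(t)
    target_index(model, t), 0L)
  logit <- fw$logits[cbind(seq_len(n), ti)]
  Rcur <- matrix(0, n, K)
  Rcur[cbind(seq_len(n), ti)] <- logit
  for (li in rev(seq_along(layers))) {
    ly <- layers[[li]]
    ch <- fw$caches[[li]]
    if (ly$type == "dense") {
      Z <- ch$Z
      eps_l <- epsilon * max(mean(abs(Z)), 1e-12)
      D <- Z + eps_l * sign0(Z)
      S <- Rcur / D
      n_in <- nrow(ly$W)
      bias_share <- (S %*% ly$b) / n_in
      Rcur <- ch$A_in * tcrossprod(S, ly$W) +
        matrix(bias_share, n, n_in)
    } else {
      RZ <- conv_pool_bwd(Rcur, ch$win, n, ly$conv_L, ly$pool,
                          ly$out_L)
      Z <- ch$Z
      eps_l <- epsilon * max(mean(abs(Z)), 1e-12)
      D <- Z + eps_l * sign0(Z)
      S <- RZ / D
      RM <- ch$M * tcrossprod(S, ly$W) +
        matrix((S %*% ly$b) / ly$kC, nrow(S), ly$kC)
      Rcur <- conv_col2im(RM, n, ly$in_L, ly$in_C, ly$k)
    }
  }
  list(R = Rcur, logit = logit,
       conservation = abs(rowSums(Rcur) - logit))
}

#' Gradient saliency
#'
#' Absolute gradient of the target-class logit with respect to the input,
#' summed over each residue's three coordinates; values are non-negative
#' by construction.
#'
#' @inheritParams lrp
#' @return as [lrp()], but all values `>= 0`.
#' @export
saliency <- function(model, x, target) {
  if (!inherits(model, "cnn1d"))
    stopf("saliency requires a cnn1d model")
  single <- is.null(dim(x))
  X <- if (single) matrix(x, 1) else as.matrix(x)
  n <- nrow(X)
  ti <- vapply(rep(target, length.out = n), function(t)
    target_index(model, t), 0L)
  fw <- cnn_forward_cache(model, X)
  K <- length(model$levels)
  dLogits <- matrix(0, n, K)
  dLogits[cbind(seq_len(n), ti)] <- 1
  bw <- nn_backward(model$layers, fw$caches, dLogits, input_grad = TRUE)
  G <- abs(sweep(bw$dX, 2, model$scale, "/"))
  V <- per_residue_sum(G, model$channels)
  if (single) new_explanation(V[1, ], target, "saliency") else V
}

#' LIME-style local surrogate explanation
#'
#' Perturbs the sample by toggling whole residues off (replacing their
#' three coordinates with baseline values, by default the training means
#' stored in the model), weights each perturbation by
#' `exp(-d^2 / kernel_width^2)` on the Euclidean distance to the original
#' sample, and fits a weighted ridge regression of the target-class
#' probability on the binary residue mask. The returned coefficients are
#' the per-residue local effects of switching a residue on.
#'
#' @param model a `cnn1d` or a function `f(X) -> numeric`.
#' @param x single feature vector.
#' @param target class explained (ignored for function models).
#' @param n_perturb number of perturbed samples; must be at least the
#'   number of players plus 2.
#' @param kernel_width proximity kernel width; default
#'   `0.75 * sqrt(n_features)` on standardized distances.
#' @param seed integer seed for the perturbation draw.
#' @param baseline replacement values for toggled-off residues; defaults
#'   to the model's stored training means.
#' @param ridge ridge penalty of the surrogate fit.
#' @return an `explanation_vector` of per-residue coefficients.
#' @export
lime_explain <- function(model, x, target = NULL, n_perturb = 1000L,
                         kernel_width = NULL, seed = 1L,
                         baseline = NULL, ridge = 1e-3) {
  x <- as.numeric(x)
  p <- length(x)
  groups <- feature_groups(p, model_channels(model))
  P <- length(groups)
  if (n_perturb < P + 2L)
    stopf("'n_perturb' = %d is below the minimum %d (players + 2)",
          n_perturb, P + 2L)
  f <- prob_fun(model, target)
  if (is.null(baseline))
    baseline <- if (inherits(model, "cnn1d")) model$center else
      rep(0, p)
  set.seed(seed)
  masks <- matrix(stats::rbinom(n_perturb * P, 1L, 0.5), n_perturb, P)
  masks[1, ] <- 1L
  Xp <- matrix(rep(x, each = n_perturb), n_perturb, p)
  off_template <- matrix(rep(baseline, each = n_perturb), n_perturb, p)
  for (g in seq_len(P)) {
    off <- masks[, g] == 0L
    if (any(off))
      Xp[off, groups[[g]]] <- off_template[off, groups[[g]]]
  }
  preds <- f(Xp)
  Dx <- if (inherits(model, "cnn1d")) {
    sweep(sweep(Xp, 2, x), 2, model$scale, "/")
  } else sweep(Xp, 2, x)
  d <- sqrt(rowSums(Dx^2))
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(p)
  wgt <- exp(-d^2 / kernel_width^2)
  Zm <- cbind(1, masks)
  A <- crossprod(Zm, Zm * wgt) + diag(ridge, P + 1L)
  beta <- tryCatch(solve(A, crossprod(Zm, wgt * preds)),
                   error = function(e)
                     stopf("singular surrogate fit; increase n_perturb"))
  new_explanation(beta[-1], target %||% "output", "lime")
}

shap_kernel_weight <- function(P, s) (P - 1) / (choose(P, s) * s * (P - s))

#' Kernel SHAP with residue players
#'
#' Shapley-value approximation by weighted regression over feature
#' coalitions. Residues are the players; absent residues take the mean
#' of the background set. Coalitions are enumerated exhaustively when
#' `2^P - 2 <= n_coalitions` (exact Shapley values for small toys),
#' otherwise sampled from the Shapley kernel distribution. The local
#' accuracy identity (attributions + base value = model output at `x`)
#' is enforced through the constrained regression.
#'
#' @param model a `cnn1d` or a function `f(X) -> numeric`.
#' @param x single feature vector.
#' @param target class explained (ignored for function models).
#' @param background matrix of background samples (rows).
#' @param n_coalitions coalition budget; at least players + 2.
#' @param seed integer seed.
#' @return an `explanation_vector`; attributes `"base_value"` and
#'   `"fx"` carry the background prediction and the prediction at `x`.
#' @export
kernel_shap <- function(model, x, target = NULL, background,
                        n_coalitions = NULL, seed = 1L) {
  x <- as.numeric(x)
  p <- length(x)
  groups <- feature_groups(p, model_channels(model))
  P <- length(groups)
  if (is.null(n_coalitions)) n_coalitions <- 2L * P + 512L
  if (n_coalitions < P + 2L)
    stopf("'n_coalitions' = %d is below the minimum %d (players + 2)",
          n_coalitions, P + 2L)
  background <- as.matrix(background)
  if (nrow(background) < 1L) stopf("'background' must be non-empty")
  bg <- colMeans(background)
  f <- prob_fun(model, target)
  set.seed(seed)

  exhaustive <- P <= 25 && (2^P - 2) <= n_coalitions
  if (exhaustive) {
    masks <- as.matrix(expand.grid(rep(list(0:1), P)))
    keep <- rowSums(masks) > 0 & rowSums(masks) < P
    masks <- masks[keep, , drop = FALSE]
    wgt <- vapply(rowSums(masks), function(s) shap_kernel_weight(P, s), 0)
  } else {
    sizes <- 1:(P - 1)
    size_prob <- (P - 1) / (sizes * (P - sizes))
    size_prob <- size_prob / sum(size_prob)
    s_draw <- sample(sizes, n_coalitions, replace = TRUE,
                     prob = size_prob)
    masks <- t(vapply(s_draw, function(s) {
      m <- integer(P); m[sample.int(P, s)] <- 1L; m
    }, integer(P)))
    wgt <- rep(1, n_coalitions)
  }

  build_inputs <- function(M) {
    n <- nrow(M)
    Xp <- matrix(rep(bg, each = n), n, p)
    for (g in seq_len(P)) {
      on <- M[, g] == 1L
      if (any(on))
        Xp[on, groups[[g]]] <- matrix(rep(x[groups[[g]]], each = sum(on)),
                                      sum(on))
    }
    Xp
  }
  v <- f(build_inputs(masks))
  base <- f(matrix(bg, 1))
  fx <- f(matrix(x, 1))

  # constrained WLS: phi_P eliminated through the local-accuracy identity
  zP <- masks[, P]
  y_adj <- v - base - zP * (fx - base)
  A <- masks[, -P, drop = FALSE] - zP
  fit <- stats::lm.wfit(A, y_adj, wgt)
  phi <- fit$coefficients
  phi[is.na(phi)] <- 0
  phi <- c(phi, (fx - base) - sum(phi))
  ev <- new_explanation(phi, target %||% "output", "shap")
  attr(ev, "base_value") <- base
  attr(ev, "fx") <- fx
  ev
}

#' Permutation importance
#'
#' Per-feature, per-class importance measured as the drop in accuracy on
#' the samples of each class when the feature's column is shuffled,
#' averaged over `n_repeats` shuffles. Negative values (noise) are
#' reported as-is.
#'
#' @param model a `cnn1d`, `tree_baseline`, `forest_baseline` or a
#'   function `f(X) -> factor` of predicted labels.
#' @param X labeled feature matrix. @param y true labels.
#' @param seed integer seed. @param n_repeats shuffles per feature.
#' @param group `"feature"` permutes single columns; `"residue"`
#'   permutes each residue's three coordinates jointly.
#' @return matrix of importances, features (or residues) x classes.
#' @export
permutation_importance <- function(model, X, y, seed = 1L,
                                   n_repeats = 5L,
                                   group = c("feature", "residue")) {
  group <- match.arg(group)
  X <- as.matrix(X)
  y <- if (is.factor(y)) y else factor(y)
  predict_labels <- if (is.function(model)) model else
    function(Xm) predict(model, Xm, type = "class")
  set.seed(seed)
  classes <- levels(y)
  base_pred <- predict_labels(X)
  base_acc <- vapply(classes, function(cl)
    mean(base_pred[y == cl] == cl), 0)
  cols <- if (group == "residue")
    feature_groups(ncol(X), model_channels(model)) else
    as.list(seq_len(ncol(X)))
  imp <- matrix(0, length(cols), length(classes),
                dimnames = list(NULL, classes))
  n <- nrow(X)
  for (j in seq_along(cols)) {
    acc_drop <- matrix(0, n_repeats, length(classes))
    for (r in seq_len(n_repeats)) {
      Xp <- X
      perm <- sample.int(n)
      Xp[, cols[[j]]] <- X[perm, cols[[j]], drop = FALSE]
      pred <- predict_labels(Xp)
      acc_drop[r, ] <- base_acc - vapply(classes, function(cl)
        mean(pred[y == cl] == cl), 0)
    }
    imp[j, ] <- colMeans(acc_drop)
  }
  imp
}

#' Average per-sample explanations into a per-class contribution map
#'
#' @param explanations n x residues matrix of per-sample explanation
#'   values (each row explained toward its sample's own class), or a
#'   list of `explanation_vector`s.
#' @param labels state factor of length n.
#' @param method attribution method identifier carried in the result.
#' @param imbalance_method optional identifier of the mitigation method.
#' @return object of class `contribution_map`: `map` is a states x
#'   residues matrix of mean contributions (rows of `NaN`, with a
#'   warning, for states without samples).
#' @export
aggregate_class_map <- function(explanations, labels, method = "unknown",
                                imbalance_method = NA_character_) {
  if (is.list(explanations) && !is.matrix(explanations))
    explanations <- do.call(rbind, lapply(explanations,
                                          function(e) e$values))
  explanations <- as.matrix(explanations)
  labels <- state_factor(as.character(labels))
  if (nrow(explanations) != length(labels))
    stopf("one explanation row per label is required")
  map <- matrix(NaN, length(STATE_LEVELS), ncol(explanations),
                dimnames = list(STATE_LEVELS, NULL))
  counts <- stats::setNames(integer(length(STATE_LEVELS)), STATE_LEVELS)
  for (s in STATE_LEVELS) {
    rows <- which(labels == s)
    counts[s] <- length(rows)
    if (length(rows) == 0L) {
      warning(sprintf("no samples with state '%s'; map row is NaN", s))
    } else {
      map[s, ] <- colMeans(explanations[rows, , drop = FALSE])
    }
  }
  structure(list(map = map, n_samples_per_state = counts,
                 method = method, imbalance_method = imbalance_method),
            class = "contribution_map")
}

#' @export
print.contribution_map <- function(x, ...) {
  cat(sprintf("contribution_map [%s%s]: %d states x %d residues\n",
              x$method,
              if (!is.na(x$imbalance_method))
                paste0(" / ", x$imbalance_method) else "",
              nrow(x$map), ncol(x$map)))
  print(x$n_samples_per_state)
  invisible(x)
}

#' Compute a contribution map for validation samples
#'
#' Explains every sample toward its own (true) class with the chosen
#' method and averages per state.
#'
#' @param model fitted `cnn1d`.
#' @param X validation features. @param y true labels.
#' @param method one of `"lrp"`, `"saliency"`, `"lime"`, `"shap"`,
#'   `"perm"`.
#' @param seed seed for the stochastic explainers.
#' @param background background samples for SHAP (defaults to 20 rows
#'   of `X`).
#' @param n_perturb,n_coalitions budgets for LIME / SHAP.
#' @param imbalance_method identifier stored in the result.
#' @return a `contribution_map`.
#' @export
class_contribution_map <- function(model, X, y,
                                   method = c("lrp", "saliency", "lime",
                                              "shap", "perm"),
                                   seed = 1L, background = NULL,
                                   n_perturb = 1000L,
                                   n_coalitions = NULL,
                                   imbalance_method = NA_character_) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- state_factor(as.character(y))
  n <- nrow(X)
  E <- switch(method,
    lrp = lrp(model, X, as.character(y)),
    saliency = saliency(model, X, as.character(y)),
    lime = t(vapply(seq_len(n), function(i)
      lime_explain(model, X[i, ], target = as.character(y[i]),
                   n_perturb = n_perturb,
                   seed = derive_seed(seed, paste0("lime", i)))$values,
      numeric(ncol(X) %/% 3L))),
    shap = {
      if (is.null(background))
        background <- X[seq_len(min(20L, n)), , drop = FALSE]
      t(vapply(seq_len(n), function(i)
        kernel_shap(model, X[i, ], target = as.character(y[i]),
                    background = background,
                    n_coalitions = n_coalitions,
                    seed = derive_seed(seed, paste0("shap", i)))$values,
        numeric(ncol(X) %/% 3L)))
    },
    perm = {
      imp <- permutation_importance(model, X, y, seed = seed,
                                    group = "residue")
      # same global map for every sample of a class
      t(imp)[as.character(y), , drop = FALSE]
    })
  aggregate_class_map(E, y, method = method,
                      imbalance_method = imbalance_method)
}

#' Explainer closures for the assessment layer
#'
#' Returns a function `(model, x, target, seed)` yielding a per-residue
#' numeric vector, the interface consumed by [robustness_score()] and
#' [stability_score()]. Deterministic methods (LRP, saliency) ignore the
#' seed.
#'
#' @param method attribution method identifier.
#' @param background,n_perturb,n_coalitions method parameters (as in the
#'   individual explainers).
#' @return an explainer closure.
#' @export
make_explainer <- function(method = c("lrp", "saliency", "lime", "shap"),
                           background = NULL, n_perturb = 1000L,
                           n_coalitions = NULL) {
  method <- match.arg(method)
  switch(method,
    lrp = function(model, x, target, seed = 1L)
      lrp(model, x, target)$values,
    saliency = function(model, x, target, seed = 1L)
      saliency(model, x, target)$values,
    lime = function(model, x, target, seed = 1L)
      lime_explain(model, x, target, n_perturb = n_perturb,
                   seed = seed)$values,
    shap = function(model, x, target, seed = 1L) {
      bg <- background %||% matrix(x, 1)
      kernel_shap(model, x, target, background = bg,
                  n_coalitions = n_coalitions, seed = seed)$values
    })
}
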