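# Decision-tree and random-forest baselines (CART via rpart, bagged
# ensembles via randomForest), with Gini-impurity feature importance.

#' Train a CART decision-tree baseline
#'
#' Recursive binary splits minimizing Gini impurity (rpart, `cp = 0`,
#' no surrogate or competitor splits, so the chosen splits are the exact
#' impurity-optimal ones).
#'
#' @param train list with `X` and `y` (factor).
#' @param depth_limit maximum tree depth.
#' @param seed integer seed (tie-breaking inside rpart is deterministic;
#'   kept for interface symmetry).
#' @return object of class `tree_baseline` wrapping the rpart fit.
#' @export
train_tree <- function(train, depth_limit = 10L, seed = 1L) {
  set.seed(seed)
  df <- as.data.frame(train$X)
  names(df) <- make.names(colnames(train$X) %||%
                            paste0("f", seq_len(ncol(train$X))))
  df$.y <- factor(train$y)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        maxdepth = depth_limit, cp = 0, minsplit = 2,
                        minbucket = 1, maxsurrogate = 0, maxcompete = 0,
                        xval = 0))
  structure(list(fit = fit, features = setdiff(names(df), ".y"),
                 levels = levels(df$.y)),
            class = "tree_baseline")
}

#' Gini importance of a fitted tree
#'
#' Total Gini impurity decrease attributed to each feature across the
#' tree's primary splits, normalized to sum 1.
#'
#' @param model a `tree_baseline` from [train_tree()].
#' @return named numeric vector over all training features (zeros for
#'   unused features).
#' @export
gini_importance <- function(model) {
  fit <- model$fit
  imp <- stats::setNames(numeric(length(model$features)), model$features)
  if (!is.null(fit$splits) && nrow(fit$splits) > 0) {
    frame <- fit$frame
    nonleaf <- which(frame$var != "<leaf>")
    # with maxcompete = maxsurrogate = 0 each non-leaf owns one splits row
    vars <- rownames(fit$splits)
    gain <- fit$splits[, "improve"]
    for (j in seq_along(vars))
      imp[vars[j]] <- imp[vars[j]] + gain[j]
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)
  imp
}

#' @export
predict.tree_baseline <- function(object, x,
                                  type = c("class", "prob"), ...) {
  type <- match.arg(type)
  df <- as.data.frame(as.matrix(x))
  names(df) <- object$features
  if (type == "class") {
    factor(as.character(predict(object$fit, df, type = "class")),
           levels = object$levels)
  } else {
    predict(object$fit, df, type = "prob")
  }
}

#' Train a random-forest baseline
#'
#' Bootstrap-aggregated CART trees with random feature subsets
#' (randomForest); class probabilities are vote fractions.
#'
#' @param train list with `X` and `y`.
#' @param n_trees number of trees.
#' @param seed integer seed.
#' @param bootstrap draw bootstrap resamples per tree (disable to make a
#'   single-tree forest coincide with an unpruned CART fit).
#' @param mtry features tried per split; defaults to `sqrt(p)` as usual
#'   for classification.
#' @return object of class `forest_baseline`.
#' @export
train_forest <- function(train, n_trees = 100L, seed = 1L,
                         bootstrap = TRUE, mtry = NULL) {
  set.seed(seed)
  X <- as.matrix(train$X)
  colnames(X) <- make.names(colnames(X) %||%
                              paste0("f", seq_len(ncol(X))))
  y <- factor(train$y)
  if (is.null(mtry))
    mtry <- if (bootstrap) max(1L, floor(sqrt(ncol(X)))) else ncol(X)
  fit <- randomForest::randomForest(
    x = X, y = y, ntree = n_trees, mtry = mtry,
    replace = bootstrap,
    sampsize = if (bootstrap) nrow(X) else nrow(X),
    importance = FALSE)
  structure(list(fit = fit, features = colnames(X), levels = levels(y)),
            class = "forest_baseline")
}

#' @export
predict.forest_baseline <- function(object, x,
                                    type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  colnames(x) <- object$features
  if (type == "class") {
    factor(as.character(predict(object$fit, x, type = "response")),
           levels = object$levels)
  } else {
    unclass(predict(object$fit, x, type = "prob"))
  }
}
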