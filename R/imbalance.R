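# Class-imbalance mitigation: SMOTE, ADASYN, SMOTEENN, NearMiss, random
# over/under-sampling, and class-weighted loss. All neighbor searches use
# Euclidean distance on the raw features; ties are broken by lowest index.

new_resampled <- function(X, y, provenance, class_weights = NULL) {
  structure(list(X = X, y = state_like(y), provenance = provenance,
                 class_weights = class_weights),
            class = "resampled_dataset")
}

# keep incoming factor levels if already a factor, else factor()
state_like <- function(y) if (is.factor(y)) y else factor(y)

#' @export
print.resampled_dataset <- function(x, ...) {
  cat(sprintf("resampled_dataset: %d samples (%d synthetic)\n",
              nrow(x$X), sum(x$provenance == "synthetic")))
  print(table(x$y))
  if (!is.null(x$class_weights)) {
    cat("class weights:\n"); print(round(x$class_weights, 4))
  }
  invisible(x)
}

#' Resampler configuration
#'
#' @param method one of `"smote"`, `"adasyn"`, `"smoteenn"`, `"nearmiss"`,
#'   `"random_over"`, `"random_under"`, `"weighted_loss"`, `"none"`.
#' @param k_neighbors nearest-neighbor count for SMOTE/ADASYN interpolation.
#' @param enn_neighbors neighbor count for the edited-nearest-neighbors
#'   cleaning rule.
#' @param nearmiss_version 1, 2 or 3.
#' @param seed integer seed.
#' @return an object of class `resampler_config`.
#' @export
resampler_config <- function(method = c("smote", "adasyn", "smoteenn",
                                        "nearmiss", "random_over",
                                        "random_under", "weighted_loss",
                                        "none"),
                             k_neighbors = 5L, enn_neighbors = 3L,
                             nearmiss_version = 1L, seed = 1L) {
  method <- match.arg(method)
  structure(list(method = method,
                 k_neighbors = assert_count(k_neighbors, "k_neighbors"),
                 enn_neighbors = assert_count(enn_neighbors,
                                              "enn_neighbors"),
                 nearmiss_version = assert_count(nearmiss_version,
                                                 "nearmiss_version"),
                 seed = assert_count(seed, "seed", min = 0L)),
            class = "resampler_config")
}

#' Apply a configured imbalance mitigation method
#'
#' Dispatches to the individual resamplers. `"weighted_loss"` leaves the
#' data untouched and attaches per-class loss weights; `"none"` is the
#' identity.
#'
#' @param X feature matrix. @param y class factor.
#' @param config a [resampler_config()].
#' @return a `resampled_dataset`.
#' @export
resample_dataset <- function(X, y, config = resampler_config()) {
  if (config$nearmiss_version < 1L || config$nearmiss_version > 3L)
    stopf("'nearmiss_version' must be 1, 2 or 3")
  switch(config$method,
    smote = smote(X, y, k = config$k_neighbors, seed = config$seed),
    adasyn = adasyn(X, y, k = config$k_neighbors, seed = config$seed),
    smoteenn = smoteenn(X, y, k = config$k_neighbors,
                        enn_neighbors = config$enn_neighbors,
                        seed = config$seed),
    nearmiss = nearmiss(X, y, version = config$nearmiss_version,
                        seed = config$seed),
    random_over = random_over(X, y, seed = config$seed),
    random_under = random_under(X, y, seed = config$seed),
    weighted_loss = new_resampled(X, y,
                                  rep("original", length(y)),
                                  class_weights = class_weights(y)),
    none = new_resampled(X, y, rep("original", length(y))))
}

# interpolate n_new synthetic points within class rows `idx` of X
smote_points <- function(X, idx, k, n_new, lambda = NULL) {
  if (n_new <= 0L) return(NULL)
  Xc <- X[idx, , drop = FALSE]
  nn <- knn_index(Xc, Xc, k, exclude_self = TRUE)
  base_i <- sample.int(length(idx), n_new, replace = TRUE)
  nn_pick <- nn[cbind(base_i, sample.int(k, n_new, replace = TRUE))]
  lam <- if (is.null(lambda)) stats::runif(n_new) else rep(lambda, n_new)
  Xc[base_i, , drop = FALSE] +
    lam * (Xc[nn_pick, , drop = FALSE] - Xc[base_i, , drop = FALSE])
}

#' SMOTE oversampling
#'
#' Each class below the target count is topped up with synthetic points
#' of the form `x + lambda * (x_nn - x)` where `x` is a class member,
#' `x_nn` one of its `k` nearest same-class neighbors, and
#' `lambda ~ U(0, 1)`.
#'
#' @param X feature matrix. @param y class factor. @param k neighbor
#'   count. @param target_counts optional named per-class target sizes;
#'   default brings every class to the majority count. @param seed seed.
#' @param lambda optional fixed interpolation factor in `[0, 1]`
#'   (random when `NULL`).
#' @return a `resampled_dataset` with per-row provenance.
#' @export
smote <- function(X, y, k = 5L, target_counts = NULL, seed = 1L,
                  lambda = NULL) {
  X <- as.matrix(X); y <- state_like(y)
  set.seed(seed)
  counts <- table(y)
  if (is.null(target_counts))
    target_counts <- stats::setNames(rep(max(counts), length(counts)),
                                     names(counts))
  Xs <- list(); ys <- character(0)
  for (cl in names(counts)) {
    need <- target_counts[[cl]] - counts[[cl]]
    if (need <= 0L) next
    if (counts[[cl]] <= k)
      stopf("class '%s' has %d samples, not enough for k = %d neighbors; use a smaller k",
            cl, counts[[cl]], k)
    P <- smote_points(X, which(y == cl), k, need, lambda)
    Xs[[cl]] <- P
    ys <- c(ys, rep(cl, nrow(P)))
  }
  Xnew <- do.call(rbind, c(list(X), unname(Xs)))
  ynew <- factor(c(as.character(y), ys), levels = levels(y))
  new_resampled(Xnew, ynew,
                c(rep("original", nrow(X)), rep("synthetic", length(ys))))
}

# ADASYN density ratios: fraction of other-class points among the k
# nearest neighbors (searched in the full dataset) of each class member
adasyn_ratios <- function(X, y, cl, k) {
  idx <- which(y == cl)
  r <- numeric(length(idx))
  for (i in seq_along(idx)) {
    d <- cross_dist(X[idx[i], , drop = FALSE], X)[1, ]
    d[idx[i]] <- Inf
    nbr <- order(d, seq_along(d))[seq_len(k)]
    r[i] <- mean(y[nbr] != cl)
  }
  r
}

#' ADASYN oversampling
#'
#' As SMOTE, but the per-sample generation quota is proportional to the
#' fraction of other-class points among each minority sample's `k`
#' nearest neighbors in the full dataset, so synthesis concentrates near
#' class boundaries. When a minority class sees no other-class neighbors
#' at all, quotas fall back to uniform with a warning.
#'
#' @inheritParams smote
#' @return a `resampled_dataset`.
#' @export
adasyn <- function(X, y, k = 5L, seed = 1L) {
  X <- as.matrix(X); y <- state_like(y)
  set.seed(seed)
  counts <- table(y)
  target <- max(counts)
  Xs <- list(); ys <- character(0)
  for (cl in names(counts)) {
    need <- target - counts[[cl]]
    if (need <= 0L) next
    if (counts[[cl]] <= k)
      stopf("class '%s' has %d samples, not enough for k = %d neighbors; use a smaller k",
            cl, counts[[cl]], k)
    idx <- which(y == cl)
    r <- adasyn_ratios(X, y, cl, k)
    if (sum(r) == 0) {
      warning(sprintf("ADASYN: class '%s' has no other-class neighbors; falling back to uniform quotas",
                      cl))
      r <- rep(1, length(idx))
    }
    quota <- largest_remainder(need, r / sum(r))
    Xc <- X[idx, , drop = FALSE]
    nn <- knn_index(Xc, Xc, k, exclude_self = TRUE)
    pieces <- vector("list", length(idx))
    for (i in seq_along(idx)) {
      if (quota[i] == 0L) next
      pick <- nn[i, sample.int(k, quota[i], replace = TRUE)]
      lam <- stats::runif(quota[i])
      pieces[[i]] <- Xc[rep(i, quota[i]), , drop = FALSE] +
        lam * (Xc[pick, , drop = FALSE] -
                 Xc[rep(i, quota[i]), , drop = FALSE])
    }
    P <- do.call(rbind, pieces)
    if (!is.null(P)) {
      Xs[[cl]] <- P
      ys <- c(ys, rep(cl, nrow(P)))
    }
  }
  Xnew <- do.call(rbind, c(list(X), unname(Xs)))
  ynew <- factor(c(as.character(y), ys), levels = levels(y))
  new_resampled(Xnew, ynew,
                c(rep("original", nrow(X)), rep("synthetic", length(ys))))
}

#' Edited-nearest-neighbors cleaning
#'
#' Removes every sample of the target class(es) whose label differs from
#' at least two of its three nearest neighbors (self excluded; ties
#' broken by lowest index). By default only the majority class is
#' cleaned; minority samples are never removed.
#'
#' @param X feature matrix. @param y class factor.
#' @param enn_neighbors neighbor count (default 3; removal requires a
#'   strict majority of disagreeing neighbors).
#' @param target_classes classes to clean; default the majority class
#'   of `y`.
#' @return list with `X`, `y`, `keep` (logical) and `removed` (row
#'   indices).
#' @export
enn_filter <- function(X, y, enn_neighbors = 3L, target_classes = NULL) {
  X <- as.matrix(X); y <- state_like(y)
  n <- nrow(X)
  if (n <= enn_neighbors)
    stopf("need more than enn_neighbors = %d samples", enn_neighbors)
  if (is.null(target_classes)) {
    counts <- table(y)
    target_classes <- names(counts)[which.max(counts)]
  }
  keep <- rep(TRUE, n)
  cand <- which(y %in% target_classes)
  if (length(cand)) {
    nn <- knn_index(X[cand, , drop = FALSE], X, enn_neighbors + 1L,
                    exclude_self = FALSE)
    for (j in seq_along(cand)) {
      i <- cand[j]
      nbr <- setdiff(nn[j, ], i)[seq_len(enn_neighbors)]
      if (sum(y[nbr] != y[i]) >= ceiling((enn_neighbors + 1L) / 2))
        keep[i] <- FALSE
    }
  }
  list(X = X[keep, , drop = FALSE], y = y[keep], keep = keep,
       removed = which(!keep))
}

#' SMOTE followed by edited-nearest-neighbors cleaning
#'
#' Oversamples every minority class with SMOTE, then cleans the original
#' majority class with the ENN rule on the combined dataset. Provenance
#' of the surviving rows is preserved.
#'
#' @inheritParams smote
#' @param enn_neighbors ENN neighbor count.
#' @return a `resampled_dataset`.
#' @export
smoteenn <- function(X, y, k = 5L, enn_neighbors = 3L, seed = 1L) {
  y0 <- state_like(y)
  majority <- names(which.max(table(y0)))
  sm <- smote(X, y, k = k, seed = seed)
  enn <- enn_filter(sm$X, sm$y, enn_neighbors = enn_neighbors,
                    target_classes = majority)
  new_resampled(enn$X, enn$y, sm$provenance[enn$keep])
}

#' NearMiss undersampling
#'
#' Reduces every class larger than the minority to the minority count.
#' Version 1 keeps majority samples with the smallest mean distance to
#' their 3 nearest minority samples; version 2 uses the 3 farthest
#' minority samples; version 3 pre-selects, for each minority sample, its
#' 3 nearest majority neighbors, then keeps the candidates with the
#' largest mean distance to their 3 nearest minority samples.
#'
#' @param X feature matrix. @param y class factor.
#' @param version 1, 2 or 3. @param seed seed (used only to break exact
#'   ranking ties reproducibly).
#' @param n_neighbors neighbor count in the distance criterion.
#' @return a `resampled_dataset` (all rows original).
#' @export
nearmiss <- function(X, y, version = 1L, seed = 1L, n_neighbors = 3L) {
  X <- as.matrix(X); y <- state_like(y)
  set.seed(seed)
  counts <- table(y)
  min_cl <- names(counts)[which.min(counts)]
  m <- min(counts)
  if (all(counts == m))
    return(new_resampled(X, y, rep("original", nrow(X))))
  min_idx <- which(y == min_cl)
  keep <- min_idx
  for (cl in names(counts)) {
    idx <- which(y == cl)
    if (cl == min_cl || length(idx) <= m) {
      if (cl != min_cl) keep <- c(keep, idx)
      next
    }
    D <- cross_dist(X[idx, , drop = FALSE], X[min_idx, , drop = FALSE])
    kk <- min(n_neighbors, ncol(D))
    if (version == 1L) {
      crit <- apply(D, 1, function(d) mean(sort(d)[seq_len(kk)]))
      sel <- idx[order(crit, seq_along(crit))[seq_len(m)]]
    } else if (version == 2L) {
      crit <- apply(D, 1, function(d)
        mean(sort(d, decreasing = TRUE)[seq_len(kk)]))
      sel <- idx[order(crit, seq_along(crit))[seq_len(m)]]
    } else {
      # candidates: union of each minority sample's kk nearest majority
      cand_rows <- unique(as.vector(apply(D, 2, function(d)
        order(d, seq_along(d))[seq_len(kk)])))
      if (length(cand_rows) < m) {
        warning("NearMiss-3: candidate pool smaller than minority count; keeping all candidates plus nearest extras")
        extra <- setdiff(seq_along(idx), cand_rows)
        crit_e <- apply(D[extra, , drop = FALSE], 1,
                        function(d) mean(sort(d)[seq_len(kk)]))
        cand_rows <- c(cand_rows,
                       extra[order(crit_e)[seq_len(m - length(cand_rows))]])
        sel <- idx[cand_rows]
      } else {
        crit <- apply(D[cand_rows, , drop = FALSE], 1,
                      function(d) mean(sort(d)[seq_len(kk)]))
        sel <- idx[cand_rows[order(crit, seq_along(crit),
                                   decreasing = TRUE)[seq_len(m)]]]
      }
    }
    keep <- c(keep, sel)
  }
  keep <- sort(keep)
  new_resampled(X[keep, , drop = FALSE], y[keep],
                rep("original", length(keep)))
}

#' Random oversampling / undersampling
#'
#' `random_over()` duplicates random minority instances until all classes
#' match the majority count; `random_under()` keeps a uniform random
#' subset of each larger class at the minority count.
#'
#' @param X feature matrix. @param y class factor. @param seed seed.
#' @return a `resampled_dataset`.
#' @export
random_over <- function(X, y, seed = 1L) {
  X <- as.matrix(X); y <- state_like(y)
  set.seed(seed)
  counts <- table(y)
  target <- max(counts)
  add <- integer(0)
  for (cl in names(counts)) {
    need <- target - counts[[cl]]
    if (need > 0L)
      add <- c(add, sample(which(y == cl), need, replace = TRUE))
  }
  Xnew <- rbind(X, X[add, , drop = FALSE])
  ynew <- factor(c(as.character(y), as.character(y[add])),
                 levels = levels(y))
  new_resampled(Xnew, ynew,
                c(rep("original", nrow(X)), rep("synthetic", length(add))))
}

#' @rdname random_over
#' @export
random_under <- function(X, y, seed = 1L) {
  X <- as.matrix(X); y <- state_like(y)
  set.seed(seed)
  counts <- table(y)
  m <- min(counts)
  keep <- integer(0)
  for (cl in names(counts)) {
    idx <- which(y == cl)
    keep <- c(keep, if (length(idx) > m) sample(idx, m) else idx)
  }
  keep <- sort(keep)
  new_resampled(X[keep, , drop = FALSE], y[keep],
                rep("original", length(keep)))
}

#' Per-class loss weights for imbalance-aware training
#'
#' Weight of class t is `1 - n_t / N` (class count over total), i.e. the
#' share of the dataset *not* in that class, renormalized to mean 1;
#' rarer classes receive strictly larger weights.
#'
#' @param y class factor with at least two classes present.
#' @return named numeric weights in class-level order.
#' @export
class_weights <- function(y) {
  y <- state_like(y)
  counts <- table(y)
  counts <- counts[counts > 0]
  if (length(counts) < 2L)
    stopf("class weights need at least two classes present")
  w <- 1 - as.numeric(counts) / sum(counts)
  w <- w / mean(w)
  stats::setNames(w, names(counts))
}
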