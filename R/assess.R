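# Assessment layer: imbalance-aware classification metrics, explanation
# robustness/stability via cosine similarity, IQR relevance filtering,
# Venn-style consensus, and recovery scoring against planted truth.

#' Confusion matrix and per-class rates
#'
#' @param y_true,y_pred factors (or coercible) over a shared label set.
#' @return list with the confusion matrix (`truth` rows x `prediction`
#'   columns), per-class precision/recall/F1, their support-weighted
#'   averages, and accuracy.
#' @export
confusion_and_rates <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stopf("empty input")
  if (length(y_true) != length(y_pred)) stopf("length mismatch")
  lev <- if (is.factor(y_true)) levels(y_true) else
    sort(unique(c(as.character(y_true), as.character(y_pred))))
  y_true <- factor(as.character(y_true), levels = lev)
  y_pred <- factor(as.character(y_pred), levels = lev)
  cm <- table(truth = y_true, prediction = y_pred)
  support <- rowSums(cm)
  tp <- diag(cm)
  precision <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- support / sum(support)
  list(confusion = cm,
       precision = precision, recall = recall, f1 = f1,
       support = support,
       weighted = c(precision = sum(w * precision),
                    recall = sum(w * recall),
                    f1 = sum(w * f1)),
       accuracy = sum(tp) / sum(cm))
}

#' Matthews correlation coefficient (multiclass R_k statistic)
#'
#' Generalized MCC computed from the full confusion matrix; reduces to
#' the classical binary formula for two classes. Ranges over `[-1, 1]`;
#' degenerate denominators yield 0 with a warning.
#'
#' @inheritParams confusion_and_rates
#' @return a single number in `[-1, 1]`.
#' @export
mcc <- function(y_true, y_pred) {
  lev <- if (is.factor(y_true)) levels(y_true) else
    sort(unique(c(as.character(y_true), as.character(y_pred))))
  y_true <- factor(as.character(y_true), levels = lev)
  y_pred <- factor(as.character(y_pred), levels = lev)
  if (length(unique(y_true[!is.na(y_true)])) < 2L)
    stopf("MCC needs at least two classes present in the truth")
  C <- table(y_true, y_pred)
  s <- sum(C)
  c_tr <- sum(diag(C))
  t_k <- rowSums(C)
  p_k <- colSums(C)
  num <- c_tr * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) {
    warning("undefined MCC denominator; returning 0")
    return(0)
  }
  num / den
}

#' One-vs-all ROC AUC per class
#'
#' Binarizes each class against the rest and integrates the ROC curve by
#' the trapezoidal rule over all score thresholds; tied scores are
#' grouped (equivalent to the Mann-Whitney rank statistic).
#'
#' @param y_true factor of true states.
#' @param scores n x K score matrix, columns in class-level order (or
#'   named by class).
#' @return named per-class AUCs; `NaN` for classes absent from the
#'   truth.
#' @export
roc_auc_ova <- function(y_true, scores) {
  y_true <- if (is.factor(y_true)) y_true else factor(y_true)
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) stopf("'scores' must be finite")
  if (nrow(scores) != length(y_true)) stopf("row/label count mismatch")
  lev <- levels(y_true)
  if (is.null(colnames(scores))) colnames(scores) <- lev
  out <- stats::setNames(rep(NaN, length(lev)), lev)
  for (cl in lev) {
    pos <- y_true == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) next
    s <- scores[, cl]
    ord <- order(s, decreasing = TRUE)
    s_ord <- s[ord]; pos_ord <- pos[ord]
    # group tied scores, accumulate trapezoids in (FPR, TPR) space
    grp <- cumsum(!duplicated(s_ord))
    tp_g <- tapply(as.numeric(pos_ord), grp, sum)
    fp_g <- tapply(as.numeric(!pos_ord), grp, sum)
    tpr <- c(0, cumsum(tp_g) / n1)
    fpr <- c(0, cumsum(fp_g) / n0)
    out[cl] <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }
  out
}

#' Cosine similarity of two non-zero vectors
#'
#' @param a,b numeric vectors of equal length, neither all-zero.
#' @return `a . b / (|a| |b|)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stopf("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stopf("cosine similarity requires non-zero vectors")
  sum(a * b) / (na * nb)
}

#' Robustness and stability configuration
#'
#' @param noise_sd standard deviation of the zero-mean Gaussian input
#'   perturbation (default 0.5, in feature units).
#' @param stability_repeats repeated explanations per sample, in
#'   `[2, 5]`.
#' @param subset_size number of samples assessed.
#' @param seed integer seed.
#' @return object of class `robustness_config`.
#' @export
robustness_config <- function(noise_sd = 0.5, stability_repeats = 3L,
                              subset_size = 50L, seed = 1L) {
  noise_sd <- assert_number(noise_sd, "noise_sd", lower = 0,
                            strict_lower = TRUE)
  stability_repeats <- assert_count(stability_repeats,
                                    "stability_repeats", min = 2L)
  if (stability_repeats > 5L)
    stopf("'stability_repeats' must be between 2 and 5")
  structure(list(noise_sd = noise_sd,
                 stability_repeats = stability_repeats,
                 subset_size = assert_count(subset_size, "subset_size"),
                 seed = assert_count(seed, "seed", min = 0L)),
            class = "robustness_config")
}

#' Explanation robustness under Gaussian input perturbation
#'
#' For each sample, the explanation of `x` and of `x + N(0, noise_sd^2)`
#' (toward the same class) are compared by cosine similarity; the mean
#' over the subset is returned. Samples whose explanation is all-zero
#' are skipped and counted.
#'
#' @param explainer a closure from [make_explainer()].
#' @param model the model being explained.
#' @param X_subset samples to assess (rows).
#' @param cfg a [robustness_config()].
#' @param targets class per sample; defaults to the model's prediction.
#' @return mean cosine similarity; attribute `"skipped"` counts skipped
#'   samples.
#' @export
robustness_score <- function(explainer, model, X_subset,
                             cfg = robustness_config(), targets = NULL) {
  X_subset <- as.matrix(X_subset)
  n <- nrow(X_subset)
  if (n == 0L) stopf("empty sample subset")
  if (is.null(targets))
    targets <- as.character(predict(model, X_subset, type = "class"))
  targets <- rep(as.character(targets), length.out = n)
  set.seed(cfg$seed)
  noise <- matrix(stats::rnorm(n * ncol(X_subset), sd = cfg$noise_sd),
                  n, ncol(X_subset))
  sims <- numeric(0); skipped <- 0L
  for (i in seq_len(n)) {
    s <- derive_seed(cfg$seed, paste0("robust", i))
    e1 <- explainer(model, X_subset[i, ], targets[i], seed = s)
    e2 <- explainer(model, X_subset[i, ] + noise[i, ], targets[i],
                    seed = s)
    if (all(e1 == 0) || all(e2 == 0)) {
      skipped <- skipped + 1L
      next
    }
    sims <- c(sims, cosine_similarity(e1, e2))
  }
  if (length(sims) == 0L) stopf("all explanations were zero vectors")
  out <- mean(sims)
  attr(out, "skipped") <- skipped
  out
}

#' Explanation stability across repetitions
#'
#' Repeats each sample's explanation `stability_repeats` times, re-drawing
#' only the explainer's internal randomness (or holding it fixed with
#' `reseed = FALSE`), and averages all pairwise cosine similarities over
#' repeats and samples. Deterministic explainers score exactly 1.
#'
#' @inheritParams robustness_score
#' @param reseed draw a fresh explainer seed per repetition (`TRUE`), or
#'   reuse one fixed seed so that seeded explainers are bit-reproducible
#'   across repeats (`FALSE`).
#' @return mean pairwise cosine similarity.
#' @export
stability_score <- function(explainer, model, X_subset,
                            cfg = robustness_config(), targets = NULL,
                            reseed = TRUE) {
  X_subset <- as.matrix(X_subset)
  n <- nrow(X_subset)
  if (n == 0L) stopf("empty sample subset")
  if (is.null(targets))
    targets <- as.character(predict(model, X_subset, type = "class"))
  targets <- rep(as.character(targets), length.out = n)
  r <- cfg$stability_repeats
  sims <- numeric(0)
  for (i in seq_len(n)) {
    reps <- lapply(seq_len(r), function(j) {
      s <- if (reseed) derive_seed(cfg$seed, paste0("stab", i, "_", j))
           else derive_seed(cfg$seed, paste0("stab", i))
      explainer(model, X_subset[i, ], targets[i], seed = s)
    })
    for (a in seq_len(r - 1)) for (b in (a + 1):r) {
      if (all(reps[[a]] == 0) || all(reps[[b]] == 0)) next
      sims <- c(sims, cosine_similarity(reps[[a]], reps[[b]]))
    }
  }
  if (length(sims) == 0L) stopf("all explanations were zero vectors")
  mean(sims)
}

#' IQR-based relevant-residue selection
#'
#' Per state, flags residues whose mean contribution falls outside the
#' Tukey fences `[Q1 - m * IQR, Q3 + m * IQR]` of that state's row, so
#' both strongly positive and strongly negative contributors are
#' captured.
#'
#' @param map a `contribution_map` (or bare states x residues matrix).
#' @param multiplier fence multiplier `m` (conventional 1.5).
#' @return object of class `relevant_set`: per state a data.frame of
#'   0-based residue ids, mean contributions and signs.
#' @export
iqr_relevant <- function(map, multiplier = 1.5) {
  M <- if (inherits(map, "contribution_map")) map$map else as.matrix(map)
  out <- list()
  for (s in rownames(M)) {
    row <- M[s, ]
    if (all(is.nan(row))) {
      out[[s]] <- data.frame(residue = integer(0), contribution = numeric(0),
                             sign = integer(0))
      next
    }
    q <- stats::quantile(row, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - multiplier * iqr
    hi <- q[2] + multiplier * iqr
    sel <- which(row < lo | row > hi)
    out[[s]] <- data.frame(residue = sel - 1L,
                           contribution = unname(row[sel]),
                           sign = ifelse(row[sel] > 0, 1L, -1L))
  }
  structure(list(per_state = out, multiplier = multiplier),
            class = "relevant_set")
}

#' @export
print.relevant_set <- function(x, ...) {
  for (s in names(x$per_state))
    cat(sprintf("%-13s %d relevant residues\n", s,
                nrow(x$per_state[[s]])))
  invisible(x)
}

# union of 0-based residue ids over all states of a relevant_set
relevant_union <- function(rs) {
  sort(unique(unlist(lapply(rs$per_state, function(d) d$residue))))
}

#' Venn-style consensus of relevant-residue sets
#'
#' Decomposes 2-4 named sets into their exclusive Venn regions and
#' reports the full intersection.
#'
#' @param sets named list of integer vectors (residue ids) or
#'   `relevant_set` objects (their per-state unions are used).
#' @return object of class `consensus_result`: `regions` is a named list
#'   (names like `"A&B"`) of exclusive-region members, `counts` the
#'   region sizes, `intersection` the members common to all sets.
#' @export
consensus <- function(sets) {
  if (length(sets) < 2L || length(sets) > 4L)
    stopf("consensus expects between 2 and 4 named sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stopf("sets must be named")
  sets <- lapply(sets, function(s)
    if (inherits(s, "relevant_set")) relevant_union(s) else
      sort(unique(as.integer(s))))
  nm <- names(sets)
  regions <- list()
  for (size in seq_along(nm)) {
    for (combo in utils::combn(nm, size, simplify = FALSE)) {
      inside <- Reduce(intersect, sets[combo])
      outside <- unlist(sets[setdiff(nm, combo)])
      regions[[paste(combo, collapse = "&")]] <-
        sort(setdiff(inside, outside))
    }
  }
  structure(list(regions = regions,
                 counts = vapply(regions, length, 0L),
                 intersection = sort(Reduce(intersect, sets)),
                 sets = sets),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus regions (exclusive membership counts):\n")
  print(x$counts)
  cat(sprintf("full intersection: %d residues\n", length(x$intersection)))
  invisible(x)
}

#' Recovery of planted informative residues
#'
#' Treats the union of per-state relevant residues as predictions and
#' scores them against the generator's planted informative residues.
#'
#' @param relevant a `relevant_set` (or integer vector of residue ids).
#' @param truth a `ground_truth` (or integer vector of planted ids).
#' @return list with `precision`, `recall` and the recovered ids.
#' @export
recovery_score <- function(relevant, truth) {
  pred <- if (inherits(relevant, "relevant_set")) relevant_union(relevant)
          else sort(unique(as.integer(relevant)))
  planted <- if (inherits(truth, "ground_truth")) truth$informative_residues
             else sort(unique(as.integer(truth)))
  hit <- intersect(pred, planted)
  list(precision = if (length(pred)) length(hit) / length(pred) else 0,
       recall = if (length(planted)) length(hit) / length(planted) else
         NaN,
       recovered = hit, predicted = pred, planted = planted)
}
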