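test_that("confusion rates match closed forms", {
  y <- factor(c("a", "a", "b", "b"))
  perfect <- confusion_and_rates(y, y)
  expect_equal(unname(perfect$precision), c(1, 1))
  expect_equal(unname(perfect$recall), c(1, 1))
  expect_equal(perfect$accuracy, 1)

  # TP=8, FP=2, FN=1, TN=9 for class "pos"
  y_true <- factor(rep(c("pos", "neg"), c(9, 11)),
                   levels = c("pos", "neg"))
  y_pred <- factor(c(rep("pos", 8), "neg",
                     rep("pos", 2), rep("neg", 9)),
                   levels = c("pos", "neg"))
  r <- confusion_and_rates(y_true, y_pred)
  expect_equal(unname(r$precision["pos"]), 0.8)
  expect_equal(unname(r$recall["pos"]), 8 / 9)

  # weighted F1 is the support-weighted mean of per-class F1
  set.seed(2)
  yt <- factor(sample(c("a", "b", "c"), 60, replace = TRUE,
                      prob = c(0.2, 0.5, 0.3)))
  yp <- factor(sample(c("a", "b", "c"), 60, replace = TRUE))
  rr <- confusion_and_rates(yt, yp)
  expect_equal(unname(rr$weighted["f1"]),
               sum(rr$support / sum(rr$support) * rr$f1))
  expect_error(confusion_and_rates(factor(character(0)),
                                   factor(character(0))), "empty")
})

test_that("multiclass MCC agrees with the covariance-form oracle", {
  y <- factor(c("a", "b", "a", "b"))
  expect_equal(mcc(y, y), 1)
  flip <- factor(c("b", "a", "b", "a"), levels = levels(y))
  expect_equal(mcc(y, flip), -1)

  # oracle: cov(true one-hot, pred one-hot) direct summation form
  mcc_oracle <- function(yt, yp) {
    K <- nlevels(yt); n <- length(yt)
    Ti <- diag(K)[as.integer(yt), , drop = FALSE]
    P <- diag(K)[as.integer(yp), , drop = FALSE]
    cov2 <- function(A, B) {
      s <- 0
      for (k in seq_len(K))
        s <- s + sum((A[, k] - mean(A[, k])) * (B[, k] - mean(B[, k])))
      s / n
    }
    cov2(Ti, P) / sqrt(cov2(Ti, Ti) * cov2(P, P))
  }
  set.seed(7)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    yt <- factor(sample(c("a", "b", "c"), n, replace = TRUE),
                 levels = c("a", "b", "c"))
    yp <- factor(sample(c("a", "b", "c"), n, replace = TRUE),
                 levels = c("a", "b", "c"))
    if (length(unique(yt)) < 2) next
    o <- mcc_oracle(yt, yp)
    got <- suppressWarnings(mcc(yt, yp))
    if (is.nan(o)) expect_equal(got, 0) else expect_equal(got, o)
  }
  # degenerate prediction: undefined denominator -> 0 with warning
  expect_warning(
    z <- mcc(factor(c("a", "b")), factor(c("a", "a"),
                                         levels = c("a", "b"))),
    "denominator")
  expect_equal(z, 0)
})

test_that("one-vs-all AUC equals the Mann-Whitney statistic, ties included", {
  y <- factor(c("a", "a", "a", "b", "b", "b"))
  s_perfect <- cbind(a = c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3),
                     b = c(0.1, 0.2, 0.3, 0.9, 0.8, 0.7))
  expect_equal(unname(roc_auc_ova(y, s_perfect)), c(1, 1))

  auc_oracle <- function(pos_scores, neg_scores) {
    u <- 0
    for (p in pos_scores) for (q in neg_scores)
      u <- u + (p > q) + 0.5 * (p == q)
    u / (length(pos_scores) * length(neg_scores))
  }
  set.seed(10)
  for (i in 1:100) {
    n <- sample(6:25, 1)
    y_r <- factor(sample(c("x", "y"), n, replace = TRUE))
    if (length(unique(y_r)) < 2) next
    sc <- matrix(sample(seq(0, 1, 0.1), 2 * n, replace = TRUE), n, 2,
                 dimnames = list(NULL, levels(y_r)))
    a <- roc_auc_ova(y_r, sc)
    for (cl in levels(y_r)) {
      expect_equal(unname(a[cl]),
                   auc_oracle(sc[y_r == cl, cl], sc[y_r != cl, cl]))
    }
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(11)
  y <- factor(sample(c("a", "b", "c"), 50, replace = TRUE))
  sc <- matrix(runif(150), 50, 3, dimnames = list(NULL, levels(y)))
  a1 <- roc_auc_ova(y, sc)
  a2 <- roc_auc_ova(y, exp(3 * sc) + 1)
  expect_equal(a1, a2)
  # absent class gives NaN
  y2 <- factor(rep("a", 10), levels = c("a", "b"))
  expect_true(is.nan(roc_auc_ova(y2, cbind(a = runif(10),
                                           b = runif(10)))["b"]))
})

test_that("AUC agrees with the pROC reference implementation", {
  set.seed(12)
  y <- factor(sample(c("a", "b"), 80, replace = TRUE))
  sc <- matrix(runif(160), 80, 2, dimnames = list(NULL, levels(y)))
  ours <- roc_auc_ova(y, sc)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = as.integer(y == "a"), predictor = sc[, "a"],
    direction = "<", quiet = TRUE)))
  expect_equal(unname(ours["a"]), ref)
})

test_that("cosine similarity follows its defining identities", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2), c(-1, -2)), -1)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "non-zero")
})

test_that("robustness is 1 for vanishing noise and for constant explainers", {
  m <- small_cnn()
  d <- small_study()
  Xs <- d$sp$validation$X[1:5, ]
  ex <- make_explainer("lrp")
  r0 <- robustness_score(ex, m, Xs,
                         robustness_config(noise_sd = 1e-9, seed = 1))
  expect_equal(as.numeric(r0), 1, tolerance = 1e-6)
  # linear model: saliency is input-independent, robust at any noise
  W <- cbind(c(1, 2, -1), c(0.5, -1, 2))
  lm_ <- linear_cnn(W, levels = c("p", "q"))
  rs <- robustness_score(make_explainer("saliency"), lm_,
                         matrix(rnorm(9), 3, 3),
                         robustness_config(noise_sd = 5, seed = 2))
  expect_equal(as.numeric(rs), 1)
})

test_that("robustness declines as input perturbations grow", {
  m <- small_cnn()
  d <- small_study()
  Xs <- d$sp$validation$X[1:12, ]
  ex <- make_explainer("lrp")
  sims <- vapply(c(0.1, 2.0), function(sd_) {
    mean(vapply(1:3, function(s)
      as.numeric(robustness_score(ex, m, Xs,
                                  robustness_config(noise_sd = sd_,
                                                    seed = s))), 0))
  }, 0)
  expect_gt(sims[1], sims[2])
})

test_that("stability is exactly 1 for deterministic or seed-fixed explainers", {
  m <- small_cnn()
  d <- small_study()
  Xs <- d$sp$validation$X[1:4, ]
  cfg <- robustness_config(stability_repeats = 3, seed = 5)
  expect_equal(stability_score(make_explainer("lrp"), m, Xs, cfg), 1)
  bg <- d$sp$train$X[1:10, ]
  sh <- make_explainer("shap", background = bg, n_coalitions = 600)
  expect_equal(stability_score(sh, m, Xs, cfg, reseed = FALSE), 1)
  # LIME with re-drawn perturbations at small budget is not perfectly stable
  lm_ <- make_explainer("lime", n_perturb = 300)
  st <- stability_score(lm_, m, Xs, cfg, reseed = TRUE)
  expect_lt(st, 1 - 1e-6)
  expect_gt(st, -1)
})

test_that("IQR filtering flags exactly the fence outliers", {
  row <- c(rep(0, 19), 10)
  M <- rbind(active = row, intermediate = row * 0,
             inactive = -row)
  rel <- iqr_relevant(M)
  expect_equal(rel$per_state$active$residue, 19L)
  expect_equal(rel$per_state$active$sign, 1L)
  expect_equal(rel$per_state$inactive$residue, 19L)
  expect_equal(rel$per_state$inactive$sign, -1L)
  expect_equal(nrow(rel$per_state$intermediate), 0L)
  # symmetric positive and negative outliers both captured
  row2 <- c(rep(0.1, 18), 5, -5)
  rel2 <- iqr_relevant(rbind(active = row2, intermediate = row2 * 0,
                             inactive = row2 * 0))
  expect_setequal(rel2$per_state$active$residue, c(18L, 19L))
})

test_that("IQR fences match the sort-based oracle and shift with the row", {
  set.seed(13)
  for (i in 1:100) {
    vals <- round(rnorm(20, sd = sample(c(0.5, 2), 1)), 2)
    M <- rbind(active = vals, intermediate = vals * 0,
               inactive = vals * 0)
    got <- iqr_relevant(M, multiplier = 1.5)$per_state$active$residue
    q <- quantile(vals, c(0.25, 0.75), names = FALSE)
    fence <- c(q[1] - 1.5 * (q[2] - q[1]), q[2] + 1.5 * (q[2] - q[1]))
    oracle <- which(vals < fence[1] | vals > fence[2]) - 1L
    expect_equal(got, oracle)
    # adding a constant shifts the fences equally
    shifted <- iqr_relevant(M + 100, multiplier = 1.5)
    expect_equal(shifted$per_state$active$residue, oracle)
  }
})

test_that("consensus regions match brute-force membership enumeration", {
  a <- c(1, 2, 3)
  expect_equal(consensus(list(A = a, B = a))$counts,
               c("A" = 0L, "B" = 0L, "A&B" = 3L))
  expect_equal(consensus(list(A = 1:3, B = 4:6))$intersection,
               integer(0))
  set.seed(14)
  for (i in 1:30) {
    sets <- list(A = sample(0:29, 10), B = sample(0:29, 12),
                 C = sample(0:29, 8))
    cz <- consensus(sets)
    for (el in 0:29) {
      membership <- vapply(sets, function(s) el %in% s, TRUE)
      if (!any(membership)) next
      region <- paste(names(sets)[membership], collapse = "&")
      expect_true(el %in% cz$regions[[region]])
    }
    expect_equal(sum(cz$counts), length(unique(unlist(sets))))
  }
  expect_error(consensus(list(A = 1:3)), "between 2 and 4")
})

test_that("recovery scoring counts planted residues", {
  planted <- c(14L, 16L, 18L, 20L)
  r1 <- recovery_score(planted, planted)
  expect_equal(r1$precision, 1)
  expect_equal(r1$recall, 1)
  r2 <- recovery_score(integer(0), planted)
  expect_equal(r2$recall, 0)
  r3 <- recovery_score(c(14L, 16L, 99L, 100L), planted)
  expect_equal(r3$recall, 0.5)
  expect_equal(r3$precision, 0.5)
})
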