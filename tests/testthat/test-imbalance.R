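test_that("SMOTE interpolates on segments between same-class neighbors", {
  # forced midpoint with k = 1: the only neighbor is the other point
  X <- rbind(c(0, 0), c(1, 1), c(10, 10), c(11, 11), c(10, 11),
             c(11, 10), c(12, 12), c(10.5, 11.5))
  y <- factor(c("min", "min", rep("maj", 6)))
  rs <- smote(X, y, k = 1, seed = 1, lambda = 0.5)
  synth <- rs$X[rs$provenance == "synthetic", , drop = FALSE]
  expect_equal(nrow(synth), 4L)
  expect_true(all(apply(synth, 1, function(p)
    isTRUE(all.equal(unname(p), c(0.5, 0.5))))))

  # betweenness: every synthetic point lies on a segment joining two
  # same-class originals (checked against all pairs)
  set.seed(11)
  X2 <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(80, 5), 40, 2))
  y2 <- factor(rep(c("min", "maj"), c(10, 40)))
  rs2 <- smote(X2, y2, k = 3, seed = 2)
  synth2 <- rs2$X[rs2$provenance == "synthetic" & rs2$y == "min", ,
                  drop = FALSE]
  minors <- X2[y2 == "min", ]
  on_some_segment <- apply(synth2, 1, function(s) {
    for (i in 1:(nrow(minors) - 1)) for (j in (i + 1):nrow(minors)) {
      a <- minors[i, ]; b <- minors[j, ]
      v <- b - a
      if (sum(v^2) < 1e-12) next
      t <- sum((s - a) * v) / sum(v^2)
      if (t >= -1e-8 && t <= 1 + 1e-8 &&
          sqrt(sum((a + t * v - s)^2)) < 1e-8) return(TRUE)
    }
    FALSE
  })
  expect_true(all(on_some_segment))
  # all classes reach the majority count
  expect_true(all(table(rs2$y) == 40L))
  expect_error(smote(X2, y2, k = 20, seed = 1), "smaller k")
})

test_that("ADASYN quotas follow the boundary-density ratios", {
  # each minority point sits inside its own majority cluster, so with
  # k = 1 every minority neighborhood is pure majority (r_i = 1)
  X <- rbind(c(0, 0), c(10, 0),
             c(0.3, 0), c(0.2, 0.2), c(-0.2, 0.1),
             c(10.3, 0), c(10.2, 0.2), c(9.8, 0.1))
  y <- factor(rep(c("min", "maj"), c(2, 6)))
  rs <- adasyn(X, y, k = 1, seed = 4)
  expect_true(all(table(rs$y) == 6L))
  # hand oracle for the r_i ratios
  D <- oracle_dist(X)
  for (i in 1:2) {
    d <- D[i, ]; d[i] <- Inf
    nb <- which.min(d)
    expect_equal(mean(y[nb] != "min"), 1)
  }
  # quotas sum to the requested additions
  expect_equal(sum(rs$provenance == "synthetic"), 4L)
  # synthetic points interpolate between the two minority originals
  synth <- rs$X[rs$provenance == "synthetic", , drop = FALSE]
  expect_true(all(abs(synth[, 2]) < 1e-12))
  expect_true(all(synth[, 1] >= 0 & synth[, 1] <= 10))

  # pure minority region: ratios all zero triggers the uniform fallback
  Xp <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
              matrix(rnorm(40, 50, 0.1), 20, 2))
  yp <- factor(rep(c("min", "maj"), c(5, 20)))
  expect_warning(rsp <- adasyn(Xp, yp, k = 3, seed = 1),
                 "uniform quotas")
  expect_true(all(table(rsp$y) == 20L))
})

test_that("ENN removes exactly the majority samples contradicted by their neighbors", {
  # a majority point amid minority is removed; one amid majority is kept
  X <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(0.05, 0.05),
             c(5, 5), c(5.1, 5), c(5, 5.1), c(5.05, 5.05))
  y <- factor(rep(c("min", "maj"), each = 4))
  intruder <- rbind(X, c(0.02, 0.02))  # majority point in minority cloud
  yi <- factor(c(as.character(y), "maj"), levels = levels(y))
  f <- enn_filter(intruder, yi)
  expect_true(9 %in% f$removed)
  expect_true(all(!(5:8 %in% f$removed)))
  expect_true(all(!(1:4 %in% f$removed)))  # minority never removed

  # oracle equivalence on random instances
  set.seed(21)
  for (rep in 1:5) {
    Xr <- matrix(rnorm(60), 30, 2)
    yr <- factor(sample(c("a", "b"), 30, replace = TRUE,
                        prob = c(0.3, 0.7)))
    if (length(unique(yr)) < 2) next
    maj <- names(which.max(table(yr)))
    D <- oracle_dist(Xr)
    expected_removed <- integer(0)
    for (i in which(yr == maj)) {
      d <- D[i, ]; d[i] <- Inf
      nb <- order(d, seq_along(d))[1:3]
      if (sum(yr[nb] != yr[i]) >= 2)
        expected_removed <- c(expected_removed, i)
    }
    f_r <- enn_filter(Xr, yr)
    expect_equal(f_r$removed, expected_removed)
  }
})

test_that("SMOTEENN composes oversampling with majority cleaning", {
  set.seed(31)
  X <- rbind(matrix(rnorm(16, 0, 1.2), 8, 2),
             matrix(rnorm(60, 2, 1.2), 30, 2))
  y <- factor(rep(c("min", "maj"), c(8, 30)))
  sm <- smote(X, y, k = 3, seed = 7)
  se <- smoteenn(X, y, k = 3, seed = 7)
  expect_lte(nrow(se$X), nrow(sm$X))
  expect_true(all(se$provenance %in% c("original", "synthetic")))
  # well-separated classes: nothing to clean
  Xs <- rbind(matrix(rnorm(16, 0, 0.1), 8, 2),
              matrix(rnorm(60, 50, 0.1), 30, 2))
  expect_equal(nrow(smoteenn(Xs, y, k = 3, seed = 7)$X),
               nrow(smote(Xs, y, k = 3, seed = 7)$X))
})

test_that("NearMiss retains majority samples by minority-distance ranking", {
  # 1D toy: v1 keeps the majority points closest to the minority cluster
  X <- cbind(c(0, 0.5, 10, 11, 12, 13), 0)
  y <- factor(rep(c("min", "maj"), c(2, 4)))
  rs <- nearmiss(X, y, version = 1, seed = 1)
  expect_equal(as.vector(table(rs$y)), c(2L, 2L))
  kept_maj <- rs$X[rs$y == "maj", 1]
  expect_equal(sort(kept_maj), c(10, 11))

  # brute-force ranking oracle, 20 points
  set.seed(5)
  Xr <- matrix(rnorm(40), 20, 2)
  yr <- factor(rep(c("min", "maj"), c(6, 14)))
  rs_r <- nearmiss(Xr, yr, version = 1, seed = 1)
  D <- oracle_dist(Xr[yr == "maj", ], Xr[yr == "min", ])
  crit <- apply(D, 1, function(d) mean(sort(d)[1:3]))
  keep_oracle <- which(yr == "maj")[order(crit, seq_along(crit))[1:6]]
  kept_rows <- rs_r$X[rs_r$y == "maj", , drop = FALSE]
  oracle_rows <- Xr[sort(keep_oracle), , drop = FALSE]
  expect_equal(kept_rows[order(kept_rows[, 1], kept_rows[, 2]), ],
               oracle_rows[order(oracle_rows[, 1], oracle_rows[, 2]), ])
  # versions 2 and 3 also hit the target count
  for (v in 2:3)
    expect_equal(as.vector(table(nearmiss(Xr, yr, version = v)$y)),
                 c(6L, 6L))
})

test_that("random over/undersampling balance counts with original rows", {
  d <- gaussian_toy(c(a = 10, b = 40), list(c(0, 0), c(3, 3)), seed = 2)
  ov <- random_over(d$X, d$y, seed = 3)
  un <- random_under(d$X, d$y, seed = 3)
  expect_true(all(table(ov$y) == 40L))
  expect_true(all(table(un$y) == 10L))
  # every oversampled row is an exact duplicate of an original minority row
  synth <- ov$X[ov$provenance == "synthetic", , drop = FALSE]
  orig_min <- d$X[d$y == "a", , drop = FALSE]
  expect_true(all(apply(synth, 1, function(r)
    any(apply(orig_min, 1, function(o) all(o == r))))))
  # seed reproducibility
  expect_identical(random_under(d$X, d$y, seed = 3)$X, un$X)
  expect_identical(random_over(d$X, d$y, seed = 3)$X, ov$X)
})

test_that("class weights decrease with class frequency per the adopted formula", {
  y <- factor(rep(c("active", "intermediate", "inactive"),
                  c(100, 800, 100)),
              levels = c("active", "intermediate", "inactive"))
  w <- class_weights(y)
  expect_gt(w[["active"]], w[["intermediate"]])
  expect_gt(w[["inactive"]], w[["intermediate"]])
  expect_equal(w[["active"]], w[["inactive"]])
  # two equal classes share the weight
  w2 <- class_weights(factor(rep(c("a", "b"), each = 5)))
  expect_equal(unname(w2[1]), unname(w2[2]))
  # counts (1, 9): weights 1 - 1/10 = 0.9 and 1 - 9/10 = 0.1, so the
  # rare class carries 9x the weight of the common one
  w3 <- class_weights(factor(rep(c("r", "c"), c(9, 1))))
  expect_equal(unname(w3[["c"]] / w3[["r"]]), 9)
  expect_error(class_weights(factor(rep("a", 5))), "two classes")
})

test_that("all resamplers preserve original labels and are seed-deterministic", {
  d <- gaussian_toy(c(x = 12, y = 30, z = 8),
                    list(c(0, 0), c(3, 0), c(0, 3)), seed = 6)
  for (m in c("smote", "adasyn", "smoteenn", "nearmiss", "random_over",
              "random_under", "weighted_loss", "none")) {
    cfg <- resampler_config(m, k_neighbors = 3L, seed = 17L)
    # ADASYN's pure-neighborhood fallback warning is expected on these
    # well-separated blobs
    r1 <- suppressWarnings(resample_dataset(d$X, d$y, cfg))
    r2 <- suppressWarnings(resample_dataset(d$X, d$y, cfg))
    expect_identical(r1$X, r2$X, info = m)
    expect_identical(r1$y, r2$y, info = m)
    orig <- r1$provenance == "original"
    # original rows keep their labels: match rows back to the input
    if (m %in% c("weighted_loss", "none", "smote", "adasyn",
                 "random_over"))
      expect_identical(as.character(r1$y[orig][seq_along(d$y)])[
        seq_len(min(length(d$y), sum(orig)))],
        as.character(d$y)[seq_len(min(length(d$y), sum(orig)))],
        info = m)
  }
  wl <- resample_dataset(d$X, d$y, resampler_config("weighted_loss"))
  expect_false(is.null(wl$class_weights))
  expect_null(resample_dataset(d$X, d$y,
                               resampler_config("smote",
                                                k_neighbors = 3L))$class_weights)
})
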