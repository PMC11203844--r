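test_that("LRP reduces to w*x on a bias-free linear layer and vanishes at zero input", {
  W <- cbind(c(1, 2, -1), c(0.5, -1, 2))
  m <- linear_cnn(W, levels = c("p", "q"))
  x <- c(1, -2, 3)
  e <- lrp(m, x, "p")
  expect_equal(e$values, x * W[, 1], tolerance = 1e-4)
  e0 <- lrp(m, rep(0, 3), "q")
  expect_equal(e0$values, rep(0, 3))
})

test_that("LRP matches a hand-unrolled epsilon-rule on a two-layer network", {
  # 3 inputs -> relu(2 hidden) -> 2 logits, all weights fixed by hand
  W1 <- rbind(c(1, -1), c(0.5, 2), c(-2, 1))
  b1 <- c(0.1, -0.2)
  W2 <- rbind(c(1, 0.5), c(-1, 2))
  b2 <- c(0, 0)
  m <- structure(list(
    layers = list(list(type = "dense", activation = "relu",
                       W = W1, b = b1),
                  list(type = "dense", activation = "linear",
                       W = W2, b = b2)),
    levels = c("p", "q"), channels = 1L, in_L = 3L,
    center = rep(0, 3), scale = rep(1, 3)), class = "cnn1d")
  x <- c(0.3, 1.2, -0.4)
  eps <- 1e-6
  # manual forward
  z1 <- as.vector(x %*% W1) + b1
  h1 <- pmax(z1, 0)
  z2 <- as.vector(h1 %*% W2) + b2
  # manual epsilon-rule backward toward class "p" (logit 1), with the
  # bias share of each neuron spread uniformly over its inputs
  R2 <- c(z2[1], 0)
  d2 <- z2 + eps * mean(abs(z2)) * ifelse(z2 >= 0, 1, -1)
  s2 <- R2 / d2
  R1 <- h1 * as.vector(W2 %*% s2) + sum(s2 * b2) / 2
  d1 <- z1 + eps * mean(abs(z1)) * ifelse(z1 >= 0, 1, -1)
  s1 <- R1 / d1
  R0 <- x * as.vector(W1 %*% s1) + sum(s1 * b1) / 3
  e <- lrp(m, x, "p", epsilon = eps)
  expect_equal(e$values, unname(R0), tolerance = 1e-9)
  # conservation to the logit
  expect_lt(abs(sum(e$values) - z2[1]), 0.05 * abs(z2[1]) + 10 * eps)
})

test_that("LRP conservation holds on the trained convolutional network", {
  m <- small_cnn()
  d <- small_study()
  X <- d$sp$validation$X[1:20, ]
  y <- as.character(d$sp$validation$y[1:20])
  E <- lrp(m, X, y)
  cons <- attr(E, "conservation")
  lg <- predict(m, X, type = "logit")
  tl <- lg[cbind(seq_len(20), match(y, m$levels))]
  expect_true(all(cons <= 0.05 * abs(tl) + 10 * 1e-6))
})

test_that("saliency equals |w| for linear models and passes a finite-difference check", {
  W <- cbind(c(1, 2, -1), c(0.5, -1, 2))
  m <- linear_cnn(W, levels = c("p", "q"))
  for (x in list(c(0, 0, 0), c(5, -3, 2))) {
    s <- saliency(m, x, "q")
    expect_equal(s$values, abs(W[, 2]))
  }
  # finite differences on the trained CNN
  mc <- small_cnn()
  d <- small_study()
  x0 <- d$sp$validation$X[1, ]
  g <- conformxplain:::cnn_input_gradient(mc, matrix(x0, 1), target = 1)
  h <- 1e-5
  idx <- c(1, 100, 500, 846)
  for (j in idx) {
    xp <- x0; xm <- x0
    xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
    fd <- (predict(mc, matrix(xp, 1), type = "logit")[, 1] -
             predict(mc, matrix(xm, 1), type = "logit")[, 1]) / (2 * h)
    expect_equal(unname(g[1, j]), unname(fd), tolerance = 1e-3)
  }
})

test_that("saliency is non-negative everywhere", {
  m <- small_cnn()
  d <- small_study()
  V <- saliency(m, d$sp$validation$X[1:15, ],
                as.character(d$sp$validation$y[1:15]))
  expect_true(all(V >= 0))
})

test_that("LIME gives near-zero weight to residues the model ignores", {
  f <- function(X) 1.5 * X[, 1] - 2 * X[, 4]   # residue 3 unused
  x <- c(2, 1, 0, -1, 0, 1, 5, 5, 5)
  e <- lime_explain(f, x, n_perturb = 2000, seed = 3,
                    baseline = rep(0, 9))
  expect_lt(abs(e$values[3]), 0.01)
  expect_equal(e$values[1], 3, tolerance = 0.05)
  expect_equal(e$values[2], 2, tolerance = 0.05)
})

test_that("LIME coefficients solve the weighted least-squares normal equations", {
  # response linear in the mask (3 residue players over 9 columns): the
  # ridge solution must match the independently coded closed form
  w <- c(1, 0.5, 2, -1, 0, 0.3, 0.2, -0.4, 1.1)
  f <- function(X) as.vector(X %*% w)
  x <- c(1, 2, 0.5, -1, 0.3, 0.2, 2, 1, -0.5)
  e <- lime_explain(f, x, n_perturb = 400, seed = 11,
                    baseline = rep(0, 9), ridge = 1e-3)
  # rebuild the identical design (same RNG stream, residue groups)
  set.seed(11)
  masks <- matrix(rbinom(400 * 3, 1, 0.5), 400, 3)
  masks[1, ] <- 1L
  Xp <- matrix(rep(x, each = 400), 400, 9)
  for (g in 1:3) Xp[masks[, g] == 0, (3 * g - 2):(3 * g)] <- 0
  preds <- f(Xp)
  dmat <- sweep(Xp, 2, x)
  wgt <- exp(-rowSums(dmat^2) / (0.75 * sqrt(9))^2)
  Zm <- cbind(1, masks)
  beta <- solve(t(Zm) %*% (Zm * wgt) + diag(1e-3, 4),
                t(Zm) %*% (wgt * preds))
  expect_equal(e$values, unname(beta[-1, 1]), tolerance = 1e-10)
})

test_that("LIME is reproducible under a fixed seed", {
  f <- function(X) X[, 1]^2 - X[, 2]
  x <- c(1, 2, 3)
  e1 <- lime_explain(f, x, n_perturb = 100, seed = 5,
                     baseline = rep(0, 3))
  e2 <- lime_explain(f, x, n_perturb = 100, seed = 5,
                     baseline = rep(0, 3))
  expect_identical(e1$values, e2$values)
})

test_that("Kernel SHAP recovers exact Shapley values on small games", {
  # two players, general (non-additive) tabulated game via enumeration
  f <- function(X) {
    on1 <- X[, 1] != 0
    on2 <- X[, 2] != 0
    ifelse(on1 & on2, 10, ifelse(on1, 4, ifelse(on2, 1, 0)))
  }
  x <- c(1, 1)
  sh <- kernel_shap(f, x, background = matrix(0, 1, 2),
                    n_coalitions = 10, seed = 1)
  # exact Shapley from both orderings:
  # phi1 = ((4-0) + (10-1))/2, phi2 = ((1-0) + (10-4))/2
  expect_equal(sh$values, c(6.5, 3.5), tolerance = 1e-9)
  # symmetric players share the payout equally
  g <- function(X) (X[, 1] != 0) + (X[, 2] != 0)
  shg <- kernel_shap(g, c(1, 1), background = matrix(0, 1, 2),
                     n_coalitions = 10, seed = 1)
  expect_equal(shg$values[1], shg$values[2], tolerance = 1e-9)
})

test_that("Kernel SHAP satisfies local accuracy on a 5-residue exhaustive toy", {
  set.seed(20)
  W <- rnorm(15)
  f <- function(X) as.vector(X %*% W) + 0.3 * X[, 1] * X[, 4]
  x <- rnorm(15)
  bg <- matrix(rnorm(5 * 15, sd = 0.2), 5, 15)
  sh <- kernel_shap(f, x, background = bg, n_coalitions = 64, seed = 2)
  expect_lt(abs(sum(sh$values) + attr(sh, "base_value") -
                  f(matrix(x, 1))), 1e-2)
  expect_error(kernel_shap(f, x, background = bg, n_coalitions = 4),
               "minimum")
})

test_that("Kernel SHAP sampling is seeded and close to the exhaustive solution", {
  set.seed(30)
  W <- rnorm(30)
  f <- function(X) as.vector(X %*% W)
  x <- rnorm(30)
  bg <- matrix(0, 1, 30)
  exact <- kernel_shap(f, x, background = bg, n_coalitions = 2000,
                       seed = 1)   # 2^10 - 2 = 1022 -> exhaustive
  sampled <- kernel_shap(f, x, background = bg, n_coalitions = 900,
                         seed = 1)
  expect_identical(sampled$values,
                   kernel_shap(f, x, background = bg,
                               n_coalitions = 900, seed = 1)$values)
  expect_equal(sampled$values, exact$values, tolerance = 0.15)
})

test_that("permutation importance isolates predictive features", {
  # deterministic model: class decided by feature 1 alone
  mod <- function(X) factor(ifelse(X[, 1] > 0, "pos", "neg"),
                            levels = c("neg", "pos"))
  set.seed(3)
  X <- cbind(c(rep(-1, 50), rep(1, 50)), rnorm(100))
  y <- mod(X)
  imp <- permutation_importance(mod, X, y, seed = 1, n_repeats = 10)
  # shuffling feature 1 sends per-class accuracy to ~0.5: drop ~ 0.5
  expect_equal(unname(imp[1, ]), c(0.5, 0.5), tolerance = 0.1)
  expect_equal(unname(imp[2, ]), c(0, 0), tolerance = 1e-9)
  imp2 <- permutation_importance(mod, X, y, seed = 1, n_repeats = 10)
  expect_identical(imp, imp2)
})

test_that("class maps average explanations per state", {
  E <- rbind(c(1, 2, 3), c(3, 2, 1), c(0, 0, 6), c(2, 2, 2))
  labs <- factor(c("active", "active", "intermediate", "inactive"),
                 levels = c("active", "intermediate", "inactive"))
  cm <- aggregate_class_map(E, labs, method = "lrp")
  expect_equal(unname(cm$map["active", ]), c(2, 2, 2))
  expect_equal(unname(cm$map["intermediate", ]), c(0, 0, 6))
  expect_equal(unname(cm$map["inactive", ]), c(2, 2, 2))
  # duplicating a sample leaves the mean unchanged
  cm2 <- aggregate_class_map(rbind(E, E[3, ]),
                             factor(c(as.character(labs),
                                      "intermediate"),
                                    levels = levels(labs)))
  expect_equal(cm2$map["intermediate", ], cm$map["intermediate", ])
  # absent state warns and yields NaN
  expect_warning(
    cm3 <- aggregate_class_map(E[1:3, ], labs[1:3]), "inactive")
  expect_true(all(is.nan(cm3$map["inactive", ])))
})

test_that("LRP and saliency maps concentrate on the planted residues", {
  m <- default_cnn()
  d <- default_study()
  planted <- d$sim$truth$informative_residues
  val <- d$sp$validation
  act <- which(val$y == "active")
  for (method in c("lrp", "saliency")) {
    V <- if (method == "lrp") lrp(m, val$X[act, ], "active") else
      saliency(m, val$X[act, ], "active")
    mean_map <- colMeans(V)
    top <- order(abs(mean_map), decreasing = TRUE)[seq_along(planted)]
    frac <- length(intersect(top - 1L, planted)) / length(planted)
    expect_gte(frac, 0.5)
  }
})
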