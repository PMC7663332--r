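test_that("PLS interpolates noiseless linear data and matches closed forms", {
  set.seed(2)
  X <- matrix(rnorm(180), 30, 6, dimnames = list(NULL, paste0("d", 1:6)))
  beta <- c(2, -1, 0.5, 0, 3, -2)
  y <- as.numeric(2 + X %*% beta)
  f <- plsFit(X, y, 6)
  expect_lt(max(abs(y - predict(f, X))), 1e-8)
  # single descriptor: slope = cov(x, y) / var(x)
  x1 <- X[, 1, drop = FALSE]
  f1 <- plsFit(x1, y, 1)
  expect_equal(coef(f1)[[1]], cov(X[, 1], y) / var(X[, 1]),
               tolerance = 1e-9)
  expect_error(plsFit(X, y, 7), "nComponents")
})

test_that("coefficients are invariant to descriptor column order", {
  set.seed(8)
  X <- matrix(rnorm(240), 40, 6, dimnames = list(NULL, paste0("d", 1:6)))
  y <- X %*% rnorm(6) + rnorm(40, sd = 0.2)
  perm <- c(4, 1, 6, 2, 5, 3)
  f1 <- plsFit(X, y, 3)
  f2 <- plsFit(X[, perm], y, 3)
  expect_equal(coef(f1)[descriptorNames(f2)], coef(f2),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("leave-one-out q2 behaves at both extremes and matches its loop", {
  set.seed(4)
  X <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, paste0("d", 1:4)))
  yPerfect <- as.numeric(X %*% c(1, 2, -1, 0.5))
  expect_gt(looQ2(X, yPerfect, 4), 0.999)
  # a response independent of X has no predictive power
  set.seed(99)
  yNull <- rnorm(60)
  Xn <- matrix(rnorm(240), 60, 4, dimnames = list(NULL, paste0("d", 1:4)))
  expect_lte(looQ2(Xn, yNull, 2), 0)
  # the literal leave-out loop is the definition
  yN <- as.numeric(X %*% c(1, 0, -1, 2)) + rnorm(30, sd = 0.5)
  expect_equal(looQ2(X, yN, 2), oracleLooQ2(X, yN, 2), tolerance = 1e-9)
  # the fast component scan agrees with it for every component count
  scan <- corrqsar:::.loo_q2_scan(X, yN, 4)
  for (a in 1:4) expect_equal(scan[a], oracleLooQ2(X, yN, a),
                              tolerance = 1e-9)
})

test_that("relative importance is a normalized coefficient magnitude", {
  # orthogonal standardized design with known effect ratio 2:1
  n <- 40
  x1 <- rep(c(-1, 1), 20); x2 <- rep(c(-1, -1, 1, 1), 10)
  X <- cbind(a = x1, b = x2)
  y <- 2 * x1 + 1 * x2
  f <- plsFit(X, y, 2)
  ri <- relativeImportance(f)
  expect_equal(ri[["a"]], 1.0)
  expect_equal(ri[["b"]], 0.5, tolerance = 1e-9)
  # a single descriptor always has RI exactly 1
  f1 <- plsFit(X[, 1, drop = FALSE], y, 1)
  expect_equal(unname(relativeImportance(f1)), 1)
})

test_that("iterative elimination stops cleanly and its trace shrinks", {
  set.seed(21)
  X <- matrix(rnorm(300), 50, 6, dimnames = list(NULL, paste0("d", 1:6)))
  y <- as.numeric(X %*% c(3, 2.5, 2, 2.2, 2.8, 2.6)) + rnorm(50, sd = 0.1)
  # comparable effects: nothing falls below the threshold -> identity
  el <- iterativeElimination(X, y, riThreshold = 0.1)
  expect_identical(sort(el$retained), colnames(X))
  expect_equal(nrow(el$trace), 1L)
  # weak + decoy columns are eliminated, sizes strictly decreasing
  X2 <- cbind(X[, 1:3], weak = rnorm(50, sd = 0.01),
              noise1 = rnorm(50), noise2 = rnorm(50))
  y2 <- as.numeric(X2[, 1:3] %*% c(3, 2, 2.5)) + rnorm(50, sd = 0.1)
  el2 <- iterativeElimination(X2, y2, riThreshold = 0.1)
  expect_true(all(c("d1", "d2", "d3") %in% el2$retained))
  expect_true(all(diff(el2$trace$nDescriptors) < 0))
  expect_true(is.finite(modelStats(el2$model)$r2_cv))
  expect_error(iterativeElimination(X, y, riThreshold = 1), "< 1")
})

test_that("r2pred and rmse follow their definitions", {
  # perfect predictions
  expect_equal(r2pred(c(5, 6), c(5, 6), 5.5)$r2_pred, 1)
  # predicting the training mean scores zero
  expect_equal(r2pred(c(5, 6), c(5.5, 5.5), 5.5)$r2_pred, 0)
  # hand-computed two-point case: SD = 1, PRESS = 0.5
  st <- r2pred(c(5, 6), c(5.5, 5.5), 5)
  expect_equal(c(st$SD, st$PRESS, st$r2_pred), c(1, 0.5, 0.5))
  expect_error(r2pred(c(5, 5), c(5, 5), 5), "SD = 0")
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(1, 2), c(0.7, 2.3)), 0.3)
  expect_equal(rmse(c(1, 2, 2), c(0, 0, 0)), sqrt(3), tolerance = 1e-7)
  expect_error(rmse(numeric(), numeric()), "non-empty")
})

test_that("r2pred never exceeds 1 and can go negative", {
  set.seed(13)
  for (i in 1:50) {
    obs <- rnorm(8); pred <- rnorm(8, sd = 3); m <- rnorm(1)
    r <- r2pred(obs, pred, m)$r2_pred
    expect_lte(r, 1)
  }
  # adversarial predictions push it below zero
  expect_lt(r2pred(c(5, 6), c(10, -10), 5.5)$r2_pred, 0)
})

test_that("external evaluation reports per-compound residuals", {
  set.seed(31)
  X <- matrix(rnorm(240), 40, 6, dimnames = list(NULL, paste0("d", 1:6)))
  y <- as.numeric(X %*% rep(1, 6)) + rnorm(40, sd = 0.2)
  f <- plsFit(X[1:30, ], y[1:30], 4)
  rep <- evaluateTest(f, X[31:40, ], y[31:40], mean(y[1:30]), ids = 31:40)
  expect_equal(rep$compounds$residual,
               rep$compounds$observed - rep$compounds$predicted)
  expect_equal(rep$r2_pred, (rep$SD - rep$PRESS) / rep$SD)
  expect_identical(rep$compounds$id, 31:40)
})

test_that("bootstrap coefficient SEs are positive, named and reproducible", {
  tab <- simulateTable(syntheticSpec(seed = 5, nNoise = 0))
  X <- as.matrix(tab$X)
  se1 <- bootstrapCoefSE(X, tab$y, nBoot = 15, nComponents = 6, seed = 2)
  se2 <- bootstrapCoefSE(X, tab$y, nBoot = 15, nComponents = 6, seed = 2)
  expect_identical(se1, se2)
  expect_named(se1, colnames(X))
  expect_true(all(se1 > 0))
})
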