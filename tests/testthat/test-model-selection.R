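test_that("Kennard-Stone reproduces hand-worked and degenerate cases", {
  # n = 2, both selected, empty test set
  sp <- kennardStoneSplit(matrix(c(0, 1), 2, 1), nTrain = 2, augment = FALSE,
                          scale = FALSE)
  expect_setequal(sp$trainIdx, 1:2)
  expect_length(sp$testIdx, 0L)
  # 1-D points {0,1,2,3,10}: seeds 0 and 10, then 3 (maximin)
  sp <- kennardStoneSplit(matrix(c(0, 1, 2, 3, 10), 5, 1), nTrain = 3,
                          augment = FALSE, scale = FALSE)
  expect_identical(sp$trainIdx, c(1L, 5L, 4L))
  # duplicated rows: deterministic lowest-index tie rule
  X <- matrix(c(0, 0, 5, 5, 9), 5, 1)
  sp1 <- kennardStoneSplit(X, nTrain = 3, augment = FALSE, scale = FALSE)
  sp2 <- kennardStoneSplit(X, nTrain = 3, augment = FALSE, scale = FALSE)
  expect_identical(sp1$trainIdx, sp2$trainIdx)
  expect_true(1L %in% sp1$trainIdx && !(2L %in% sp1$trainIdx))
  expect_error(kennardStoneSplit(X, nTrain = 1, augment = FALSE), ">= 2")
})

test_that("Kennard-Stone equals the greedy-maximin oracle on small instances", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(4:12, 1)
    p <- sample(1:4, 1)
    M <- matrix(rnorm(n * p), n, p)
    k <- sample(2:(n - 1), 1)
    sp <- kennardStoneSplit(M, nTrain = k, augment = FALSE, scale = FALSE)
    expect_identical(sp$trainIdx, oracleKennardStone(M, k))
  }
})

test_that("response augmentation changes the design when potency is informative", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  y <- c(rep(0, 19), 50)      # one extreme responder, unremarkable in X
  spNo <- kennardStoneSplit(X, y, nTrain = 10, augment = FALSE)
  spYes <- kennardStoneSplit(X, y, nTrain = 10, augment = TRUE)
  expect_true(20L %in% spYes$trainIdx)   # the outlier must be trained on
  expect_false(identical(spNo$trainIdx, spYes$trainIdx))
  expect_true(spYes$augmentedResponse)
})

test_that("constant columns are dropped with a warning before scaling", {
  X <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_warning(sc <- autoscale(X), "zero-variance")
  expect_identical(colnames(sc$X), "a")
  expect_identical(sc$dropped, "b")
})

test_that("manual splits flow through the same interface", {
  sp <- manualSplit(roster("A", "train"), roster("A", "test"))
  expect_s3_class(sp, "Split")
  expect_identical(sp$method, "manual")
  expect_error(manualSplit(1:5, 5:8), "overlap")
})

test_that("PCA scores match an eigendecomposition oracle", {
  # collinear data: one component explains everything
  x <- rnorm(15)
  lin <- cbind(x, 2 * x, -x)
  pc <- pcaScores(lin, 1)
  expect_equal(pc$explainedVariance[1], 1, tolerance = 1e-9)
  # random matrix: scores equal covariance eigenvectors up to column sign
  set.seed(11)
  X <- matrix(rnorm(100), 20, 5)
  pc <- pcaScores(X, 5)
  Xs <- scale(X)
  ev <- eigen(cov(Xs))
  want <- Xs %*% ev$vectors
  for (j in 1:5) {
    s <- sign(sum(pc$scores[, j] * want[, j]))
    expect_equal(pc$scores[, j], s * want[, j], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_true(all(diff(pc$explainedVariance) <= 1e-12))
  # appending a constant column changes nothing after the drop
  expect_warning(pc2 <- pcaScores(cbind(X, k = 1), 5), "zero-variance")
  expect_equal(abs(pc2$scores), abs(pc$scores), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pcaScores(lin, 4), "rank")
})

test_that("contingency scores capture association and ignore monotone scale", {
  set.seed(5)
  y <- rnorm(500)
  X <- cbind(same = y, flat = rep(1, 500), indep = rnorm(500))
  cr <- contingencyRank(X, y, nBins = 4, topK = 2)
  sc <- setNames(cr$ranking$score, cr$ranking$descriptor)
  expect_equal(sc[["same"]], 1.0)
  expect_equal(sc[["flat"]], 0)
  expect_lt(sc[["indep"]], 0.15)
  expect_identical(cr$retained, c("same", "indep"))
  # equal-frequency binning: a monotone transform leaves the score alone
  x <- rexp(300); yy <- x + rnorm(300, sd = 0.3)
  s1 <- contingencyRank(cbind(v = x), yy)$ranking$score
  s2 <- contingencyRank(cbind(v = log(x)), yy)$ranking$score
  expect_equal(s1, s2)
  expect_error(contingencyRank(X, y, nBins = 1), ">= 2")
})
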