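# PLS1 (NIPALS) regression with leave-one-out validation, relative
# importance, iterative descriptor elimination and the external
# predictivity statistic r2pred = (SD - PRESS) / SD.

# Core NIPALS PLS1 on an already autoscaled X and centred y.  Returns
# weights W, X-loadings P, inner coefficients q, and the coefficient
# matrix B (p x A) whose column a gives coefficients using a components --
# deflation is sequential, so column a equals a fresh a-component fit.
.pls_core <- function(Xs, yc, A) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  Xd <- Xs; yd <- yc
  for (a in seq_len(A)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { A <- a - 1L; break }
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    pvec <- crossprod(Xd, t) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pvec)
    yd <- yd - qa * t
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t; q[a] <- qa
  }
  if (A == 0L) stop("response is orthogonal to all descriptors")
  W <- W[, seq_len(A), drop = FALSE]
  P <- P[, seq_len(A), drop = FALSE]
  Tm <- Tm[, seq_len(A), drop = FALSE]
  q <- q[seq_len(A)]
  # coefficients for each nested component count
  B <- matrix(0, p, A)
  for (a in seq_len(A)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    B[, a] <- Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)])
  }
  list(W = W, P = P, Tm = Tm, q = q, B = B, A = A)
}

#' Fit a PLS1 regression model
#'
#' NIPALS partial least squares of a single response on an autoscaled
#' descriptor matrix (columns centred and scaled to unit variance;
#' zero-variance columns dropped with a warning; the response is centred).
#' Coefficients are back-transformed to the original descriptor scale, so
#' `intercept + X %*% coef` reproduces the fitted values.  Deterministic.
#'
#' @param X descriptor matrix or data.frame with column names.
#' @param y response vector.
#' @param nComponents number of latent variables (<= min(n - 1, p)).
#' @return a [PLSModel-class] with `r2_ncv` and training `rmse` filled in
#'   (`r2_cv` is NA until [looQ2()] is run).
#' @examples
#' X <- matrix(rnorm(120), 20, 6, dimnames = list(NULL, paste0("d", 1:6)))
#' y <- X %*% rnorm(6) + rnorm(20, sd = 0.1)
#' m <- plsFit(X, y, 3)
#' modelStats(m)$r2_ncv
#' @export
plsFit <- function(X, y, nComponents) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  sc <- autoscale(X)
  n <- nrow(sc$X); p <- ncol(sc$X)
  if (nComponents > min(n - 1L, p))
    stop("nComponents exceeds min(n - 1, p) = ", min(n - 1L, p))
  ym <- mean(y)
  core <- .pls_core(sc$X, y - ym, as.integer(nComponents))
  A <- core$A
  bScaled <- core$B[, A]
  bOrig <- bScaled / sc$sds
  icpt <- ym - sum(bOrig * sc$means)
  fitted <- icpt + as.numeric(X[, names(sc$means), drop = FALSE] %*% bOrig)
  res <- y - fitted
  tss <- sum((y - ym)^2)
  ri <- abs(bScaled)
  if (max(ri) == 0) stop("all coefficients are zero")
  ri <- ri / max(ri)
  names(ri) <- names(sc$means)
  new("PLSModel",
      descriptorNames = names(sc$means),
      xMeans = sc$means, xSds = sc$sds, yMean = ym,
      weights = core$W, loadings = core$P, yLoadings = core$q,
      scores = core$Tm, nComponents = A,
      coefScaled = unname(bScaled), coefficients = unname(bOrig),
      intercept = icpt, ri = ri,
      stats = list(r2_ncv = 1 - sum(res^2) / tss,
                   r2_cv = NA_real_,
                   rmse = sqrt(mean(res^2))))
}

#' Predict from a fitted PLS model
#'
#' @param object a [PLSModel-class].
#' @param newdata matrix or data.frame containing the model's descriptor
#'   columns (by name).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  newdata <- as.matrix(as.data.frame(newdata)[, object@descriptorNames,
                                              drop = FALSE])
  object@intercept + as.numeric(newdata %*% object@coefficients)
})

#' Leave-one-out cross-validated q2
#'
#' Each training sample is left out once, the model is refitted on the
#' remainder and the held-out sample predicted; r2_cv = 1 - PRESS_loo /
#' sum((y - mean(y))^2).
#'
#' @param X descriptor matrix.
#' @param y response vector (length >= 3).
#' @param nComponents latent variables per refit.
#' @return q2 (can be negative for models without predictive power).
#' @export
looQ2 <- function(X, y, nComponents) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out requires n >= 3")
  press <- 0
  for (i in seq_len(n)) {
    fit <- suppressWarnings(plsFit(X[-i, , drop = FALSE], y[-i], nComponents))
    press <- press + (y[i] - predict(fit, X[i, , drop = FALSE]))^2
  }
  1 - press / sum((y - mean(y))^2)
}

# q2 for every component count 1..maxComp in one LOO pass (nested NIPALS
# coefficient columns equal fresh fits with fewer components).
.loo_q2_scan <- function(X, y, maxComp) {
  X <- as.matrix(X)
  sc0 <- suppressWarnings(autoscale(X))
  X <- X[, colnames(sc0$X), drop = FALSE]
  n <- nrow(X)
  maxComp <- min(maxComp, n - 2L, ncol(X))
  press <- numeric(maxComp)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    sc <- suppressWarnings(autoscale(Xi))
    A <- min(maxComp, ncol(sc$X))
    core <- .pls_core(sc$X, yi - mean(yi), A)
    for (a in seq_len(core$A)) {
      bO <- core$B[, a] / sc$sds
      pred <- mean(yi) - sum(bO * sc$means) +
        sum(X[i, names(sc$means)] * bO)
      press[a] <- press[a] + (y[i] - pred)^2
    }
    if (core$A < maxComp)
      press[(core$A + 1L):maxComp] <-
        press[(core$A + 1L):maxComp] + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' Choose the component count by leave-one-out q2
#'
#' Scans 1..`maxComponents` latent variables (capped by sample size and
#' descriptor count) and returns the count maximizing the leave-one-out
#' q2; ties go to the smaller model.
#'
#' @param X descriptor matrix.
#' @param y response vector.
#' @param maxComponents largest count scanned (default 6).
#' @return list: `nComponents`, `q2` (the full scan), `best` (its max).
#' @export
chooseComponents <- function(X, y, maxComponents = 6L) {
  q2 <- .loo_q2_scan(X, y, maxComponents)
  a <- which.max(q2)
  list(nComponents = a, q2 = q2, best = q2[a])
}

#' Relative importance of the descriptors in a PLS model
#'
#' RI_j = |standardized coefficient_j| / max_k |standardized
#' coefficient_k|: values in (0, 1] with the most influential descriptor
#' at exactly 1.
#'
#' @param model a fitted [PLSModel-class].
#' @return named numeric vector.
#' @export
relativeImportance <- function(model) {
  riValues(model)
}

#' Iterative descriptor elimination by relative importance
#'
#' Repeats \{fit PLS, compute RI, drop every descriptor with RI below the
#' threshold\} until no descriptor is dropped or only one remains.  The
#' component count is re-chosen each round by leave-one-out q2 (see
#' [chooseComponents()]), or held fixed via `nComponents`.
#'
#' @param X descriptor matrix (>= 1 column).
#' @param y response vector.
#' @param riThreshold drop cutoff in (0, 1); default 0.10.
#' @param maxComponents cap for the per-round component scan.
#' @param nComponents fixed component count (overrides the scan).
#' @return list: `model` (final [PLSModel-class], `r2_cv` filled in),
#'   `retained` (descriptor names), `trace` (one row per round:
#'   nDescriptors, nComponents, q2, dropped names).
#' @export
iterativeElimination <- function(X, y, riThreshold = 0.10,
                                 maxComponents = 6L, nComponents = NULL) {
  if (riThreshold >= 1) stop("riThreshold must be < 1")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  cols <- colnames(X)
  trace <- list()
  repeat {
    Xc <- X[, cols, drop = FALSE]
    if (is.null(nComponents)) {
      ch <- chooseComponents(Xc, y, maxComponents)
      a <- ch$nComponents; q2 <- ch$best
    } else {
      a <- min(nComponents, nrow(Xc) - 1L, length(cols))
      q2 <- NA_real_
    }
    fit <- suppressWarnings(plsFit(Xc, y, a))
    ri <- relativeImportance(fit)
    drop <- names(ri)[ri < riThreshold]
    keep <- setdiff(descriptorNames(fit), drop)
    trace[[length(trace) + 1L]] <- data.frame(
      round = length(trace) + 1L, nDescriptors = length(cols),
      nComponents = fit@nComponents, q2 = q2,
      dropped = paste(drop, collapse = ";"), stringsAsFactors = FALSE)
    if (!length(drop) || length(keep) < 1L || length(keep) == length(cols)) {
      fit@stats$r2_cv <- if (is.na(q2))
        looQ2(Xc, y, fit@nComponents) else q2
      return(list(model = fit, retained = descriptorNames(fit),
                  trace = do.call(rbind, trace)))
    }
    cols <- keep
  }
}

#' Bootstrap standard errors of PLS coefficients
#'
#' Case-resampling bootstrap of the *whole* fitting procedure: each
#' replicate resamples rows with replacement, re-chooses the component
#' count by leave-one-out q2 (unless `nComponents` fixes it) and refits,
#' so the standard errors include component-selection variability -- the
#' honest uncertainty of a CV-tuned PLS fit.
#'
#' @param X descriptor matrix.
#' @param y response vector.
#' @param nBoot bootstrap replicates (default 60).
#' @param maxComponents cap for the per-replicate component scan.
#' @param nComponents fixed component count (skips the scan).
#' @param seed RNG seed for the resampling.
#' @return named numeric vector of standard errors, one per column of X.
#' @export
bootstrapCoefSE <- function(X, y, nBoot = 60L, maxComponents = 6L,
                            nComponents = NULL, seed = 1L) {
  X <- as.matrix(X)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  nms <- colnames(X)
  bo <- replicate(nBoot, {
    i <- sample(nrow(X), replace = TRUE)
    a <- if (is.null(nComponents))
      chooseComponents(X[i, , drop = FALSE], y[i], maxComponents)$nComponents
    else min(nComponents, nrow(X) - 1L, ncol(X))
    f <- suppressWarnings(plsFit(X[i, , drop = FALSE], y[i], a))
    co <- coef(f)
    vapply(nms, function(nm) if (nm %in% names(co)) co[[nm]] else NA_real_,
           numeric(1L))
  })
  apply(matrix(bo, nrow = length(nms), dimnames = list(nms, NULL)), 1L,
        stats::sd, na.rm = TRUE)
}

#' Root mean square error
#'
#' @param observed,predicted equal-length numeric vectors (length >= 1).
#' @return sqrt(mean((observed - predicted)^2)).
#' @export
rmse <- function(observed, predicted) {
  if (!length(observed) || length(observed) != length(predicted))
    stop("observed and predicted must be equal-length, non-empty")
  sqrt(mean((observed - predicted)^2))
}

#' External predictivity statistic r2pred
#'
#' r2pred = (SD - PRESS) / SD, where SD is the sum of squared deviations
#' of the test-set activities from the *training-set* mean and PRESS the
#' sum of squared test-set prediction errors.  Equals 1 for perfect
#' predictions, 0 when predictions are no better than the training mean,
#' and can be negative.
#'
#' @param observed test-set activities.
#' @param predicted test-set predictions.
#' @param yTrainMean mean activity of the training set.
#' @return list: `r2_pred`, `SD`, `PRESS`.
#' @export
r2pred <- function(observed, predicted, yTrainMean) {
  if (!length(observed)) stop("empty test set")
  SD <- sum((observed - yTrainMean)^2)
  if (SD == 0) stop("degenerate test set: SD = 0")
  PRESS <- sum((observed - predicted)^2)
  list(r2_pred = (SD - PRESS) / SD, SD = SD, PRESS = PRESS)
}

#' Evaluate a model on an external test set
#'
#' Predicts the test compounds and reports r2pred (see [r2pred()])
#' together with the per-compound predictions and residuals (the data
#' behind predicted-vs-experimental and residual plots).
#'
#' @param model a [PLSModel-class] (or any object with a `predict`
#'   method accepting `newdata`).
#' @param XTest test descriptor matrix (same columns as training).
#' @param yTest observed test activities.
#' @param yTrainMean training-set mean activity.
#' @param ids optional compound identifiers.
#' @return list: `r2_pred`, `SD`, `PRESS`, `rmse`, `compounds`
#'   (data.frame id/observed/predicted/residual).
#' @export
evaluateTest <- function(model, XTest, yTest, yTrainMean, ids = NULL) {
  pred <- as.numeric(predict(model, XTest))
  st <- r2pred(yTest, pred, yTrainMean)
  if (is.null(ids)) ids <- seq_along(yTest)
  c(st, list(
    rmse = rmse(yTest, pred),
    compounds = data.frame(id = ids, observed = yTest, predicted = pred,
                           residual = yTest - pred)))
}
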