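# Training/test design and descriptor pruning.

#' Column autoscaling with constant-column drop
#'
#' Centres each column to mean 0 and scales to standard deviation 1.
#' Columns with zero variance cannot be autoscaled; they are dropped with
#' a warning.
#'
#' @param X numeric matrix or data.frame.
#' @return list: `X` (scaled matrix), `means`, `sds` (named, for the kept
#'   columns), `dropped` (names of zero-variance columns).
#' @export
autoscale <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  mns <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  keep <- sds > 0
  if (!all(keep))
    warning("dropping zero-variance column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, mns[keep]), 2L,
              sds[keep], `/`)
  list(X = Xs, means = mns[keep], sds = sds[keep],
       dropped = colnames(X)[!keep])
}

#' Kennard-Stone training/test split
#'
#' Classic deterministic maximin selection on Euclidean distance: the first
#' two selections are the most distant pair of samples; each subsequent
#' selection maximizes its minimum distance to the already-selected set.
#' Remaining samples form the test set.  With `augment = TRUE` the
#' response is appended as an additional (autoscaled) column before
#' distances are computed, so training samples cover the response range as
#' well as descriptor space.  Ties are broken by the lowest row index, so
#' the split is fully deterministic.
#'
#' @param X descriptor matrix or data.frame (no missing values).
#' @param y optional response vector (required when `augment = TRUE`).
#' @param nTrain number of training samples (>= 2).
#' @param augment append the response as an extra column (default TRUE).
#' @param scale autoscale columns before distance computation (default
#'   TRUE; standard chemometric practice).
#' @param ids sample identifiers; default rownames or 1..n.
#' @return a `Split`: list with `trainIds`, `testIds`, `trainIdx`,
#'   `testIdx`, `method`, `scaling` (means/sds used), `augmentedResponse`.
#' @export
kennardStoneSplit <- function(X, y = NULL, nTrain, augment = TRUE,
                              scale = TRUE, ids = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (anyNA(X)) stop("missing values in X")
  if (nTrain < 2L) stop("nTrain must be >= 2")
  if (nTrain > n) stop("nTrain exceeds the number of samples")
  if (augment && is.null(y)) stop("augment = TRUE requires a response y")
  if (is.null(ids)) ids <- if (!is.null(rownames(X))) rownames(X)
                           else seq_len(n)
  M <- X
  if (augment) M <- cbind(M, .response. = as.numeric(y))
  scaling <- NULL
  if (scale) {
    sc <- autoscale(M)
    M <- sc$X
    scaling <- list(means = sc$means, sds = sc$sds, dropped = sc$dropped)
  }
  D <- as.matrix(stats::dist(M))
  # seed pair: most distant; ties -> smallest (i, j)
  best <- c(1L, 2L); bestD <- -Inf
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (D[i, j] > bestD) { bestD <- D[i, j]; best <- c(i, j) }
    }
  }
  sel <- best
  remaining <- setdiff(seq_len(n), sel)
  minD <- pmin(D[, sel[1L]], D[, sel[2L]])
  while (length(sel) < nTrain) {
    cand <- remaining[which.max(minD[remaining])]   # which.max: lowest index on ties
    sel <- c(sel, cand)
    remaining <- setdiff(remaining, cand)
    minD <- pmin(minD, D[, cand])
  }
  structure(list(
    trainIds = ids[sel], testIds = ids[remaining],
    trainIdx = sel, testIdx = remaining,
    method = "kennard_stone", scaling = scaling,
    augmentedResponse = augment
  ), class = "Split")
}

#' Manual training/test split
#'
#' Wraps a hand-picked membership list (e.g. the published model-A roster)
#' in the same `Split` structure [kennardStoneSplit()] produces, so both
#' designs flow through one interface.
#'
#' @param trainIds,testIds disjoint id vectors.
#' @return a `Split` with `method = "manual"`.
#' @export
manualSplit <- function(trainIds, testIds) {
  if (length(intersect(trainIds, testIds)))
    stop("train and test sets overlap")
  structure(list(
    trainIds = trainIds, testIds = testIds,
    trainIdx = NULL, testIdx = NULL,
    method = "manual", scaling = NULL, augmentedResponse = FALSE
  ), class = "Split")
}

#' @export
print.Split <- function(x, ...) {
  cat(sprintf("Split (%s): %d train / %d test%s\n", x$method,
              length(x$trainIds), length(x$testIds),
              if (isTRUE(x$augmentedResponse)) ", response-augmented" else ""))
  invisible(x)
}

#' Principal component scores of the autoscaled descriptor matrix
#'
#' Multivariate display: scores of the column-autoscaled matrix on the
#' leading principal axes, with explained-variance fractions.  Constant
#' columns are dropped (with a warning) before the decomposition.
#'
#' @param X numeric matrix or data.frame.
#' @param nComponents number of components (<= rank of the scaled matrix).
#' @return list: `scores` (n x nComponents), `explainedVariance`
#'   (fractions, non-increasing, sum <= 1), `loadings`.
#' @export
pcaScores <- function(X, nComponents = 2L) {
  sc <- autoscale(X)
  rk <- qr(sc$X)$rank
  if (nComponents > rk)
    stop("nComponents (", nComponents, ") exceeds matrix rank (", rk, ")")
  pc <- stats::prcomp(sc$X, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(nComponents), drop = FALSE],
       explainedVariance = ev[seq_len(nComponents)],
       loadings = pc$rotation[, seq_len(nComponents), drop = FALSE])
}

# Equal-frequency binning; falls back to the distinct values when there
# are fewer of them than bins.  Single distinct value -> single bin.
.ef_bin <- function(x, nBins) {
  ux <- unique(x)
  if (length(ux) <= 1L) return(factor(rep(1L, length(x))))
  if (length(ux) <= nBins) return(factor(x))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = nBins + 1L),
                               type = 7))
  if (length(br) < 3L) return(factor(x <= br[1L]))
  cut(x, breaks = br, include.lowest = TRUE)
}

#' Contingency-based descriptor ranking
#'
#' Discretizes each descriptor and the response into `nBins`
#' equal-frequency bins and scores the descriptor x response contingency
#' table with Cramer's V (chi-square based association in [0, 1]).
#' Descriptors are ranked by descending score and the top `topK` retained.
#' A constant descriptor scores 0; scores are invariant to strictly
#' monotone transforms of a descriptor (equal-frequency binning).
#'
#' @param X descriptor matrix or data.frame.
#' @param y continuous response vector.
#' @param nBins number of bins (>= 2; default 4).
#' @param topK number of descriptors to retain.
#' @return list: `ranking` (data.frame descriptor/score, descending),
#'   `retained` (top-k names), `nBins`.
#' @export
contingencyRank <- function(X, y, nBins = 4L, topK = 50L) {
  X <- as.matrix(X)
  if (nBins < 2L) stop("nBins must be >= 2")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  yb <- .ef_bin(as.numeric(y), nBins)
  score <- vapply(seq_len(ncol(X)), function(j) {
    xb <- .ef_bin(X[, j], nBins)
    tab <- table(xb, yb)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    k <- min(nrow(tab), ncol(tab))
    if (k < 2L) return(0)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chi2 <- sum((tab - e)^2 / e)
    sqrt(chi2 / (sum(tab) * (k - 1L)))
  }, numeric(1L))
  ord <- order(-score, seq_along(score))
  ranking <- data.frame(descriptor = colnames(X)[ord], score = score[ord],
                        stringsAsFactors = FALSE)
  k <- min(topK, nrow(ranking))
  list(ranking = ranking, retained = ranking$descriptor[seq_len(k)],
       nBins = as.integer(nBins))
}
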