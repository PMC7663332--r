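# Independent oracles used across the suite.  Each is written as directly
# as possible (closed forms, brute-force enumeration, literal loops) and
# shares no code with the implementation paths it checks.

# Exposed area of two overlapping spheres: total area minus the two
# buried spherical caps (valid for partial overlap, neither sphere
# swallowed: |R1 - R2| < d < R1 + R2).
oracleTwoSphereArea <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# Brute-force angle enumeration: try every (i, j, k) with i < k and test
# both required bonds against the bond list.
oracleAngles <- function(nAtoms, bondMat) {
  hasBond <- function(a, b) {
    any((bondMat[, 1] == a & bondMat[, 2] == b) |
        (bondMat[, 1] == b & bondMat[, 2] == a))
  }
  out <- NULL
  for (j in seq_len(nAtoms)) {
    for (i in seq_len(nAtoms)) {
      for (k in seq_len(nAtoms)) {
        if (i < k && i != j && k != j && hasBond(i, j) && hasBond(j, k))
          out <- rbind(out, c(i, j, k))
      }
    }
  }
  out
}

# Greedy maximin (Kennard-Stone) selection, written as a literal loop
# with full distance recomputation at every step.
oracleKennardStone <- function(M, nTrain) {
  n <- nrow(M)
  D <- as.matrix(dist(M))
  sel <- integer()
  best <- c(1L, 2L); bd <- -Inf
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (D[i, j] > bd) { bd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < nTrain) {
    rem <- setdiff(seq_len(n), sel)
    scores <- sapply(rem, function(r) min(D[r, sel]))
    sel <- c(sel, rem[which.max(scores)])
  }
  sel
}

# Ordinary least squares by the normal equations.
oracleOLS <- function(X, y) {
  A <- cbind(1, X)
  as.numeric(solve(crossprod(A), crossprod(A, y)))
}

# Literal leave-one-out loop around plsFit; this loop IS the definition
# of the cross-validated q2.
oracleLooQ2 <- function(X, y, nComponents) {
  press <- 0
  for (i in seq_len(nrow(X))) {
    f <- suppressWarnings(plsFit(X[-i, , drop = FALSE], y[-i], nComponents))
    press <- press + (y[i] - predict(f, X[i, , drop = FALSE]))^2
  }
  1 - press / sum((y - mean(y))^2)
}

# Angle (radians) at atom j of triplet (i, j, k).
oracleAngleAt <- function(xyz, i, j, k) {
  v1 <- xyz[i, ] - xyz[j, ]
  v2 <- xyz[k, ] - xyz[j, ]
  acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
}

# Random small molecule-like bond graph for property tests.
randomBondGraph <- function(nAtoms, nBonds, seed) {
  set.seed(seed)
  all <- t(combn(nAtoms, 2))
  all[sample(nrow(all), min(nBonds, nrow(all))), , drop = FALSE]
}
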