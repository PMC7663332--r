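# Solvent-accessible surface area by numerical sphere sampling
# (Shrake-Rupley style) on a deterministic Fibonacci lattice.

#' Deterministic unit-sphere sampling points
#'
#' Fibonacci (golden-spiral) lattice: near-uniform coverage for any point
#' count, and fully deterministic, so surface areas are bit-reproducible.
#'
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Canonical molecular frame: centre at the coordinate mean, axes along
# the principal axes of the atom cloud (decreasing spread), each axis
# signed so its largest-magnitude component is positive.  Sampling in
# this frame makes the numerical surface areas invariant under rigid-body
# motion of the input coordinates (up to eigendecomposition round-off),
# not merely invariant to within the lattice discretization error.
.canonical_frame <- function(xyz) {
  if (nrow(xyz) < 2L) return(xyz)
  ctr <- sweep(xyz, 2L, colMeans(xyz))
  e <- eigen(crossprod(ctr), symmetric = TRUE)
  tc <- ctr %*% e$vectors
  # orient each axis by the first atom with a non-negligible projection
  # (atom order, unlike eigenvector entries, is frame-independent)
  for (j in 1:3) {
    i <- which(abs(tc[, j]) > 1e-8)[1L]
    if (!is.na(i) && tc[i, j] < 0) tc[, j] <- -tc[, j]
  }
  tc
}

#' Solvent-accessible surface area
#'
#' Rolls a spherical probe over the van der Waals spheres: each atom is
#' expanded by the probe radius, sampled with a deterministic point
#' lattice, and a sample point counts as accessible when it lies outside
#' every other expanded sphere.  Per-atom area is the accessible fraction
#' of the expanded sphere's area, 4 * pi * (r_i + probe)^2.
#'
#' Sampling is performed in the molecule's principal-axes frame, so the
#' result is invariant under translation and rotation of the input
#' coordinates rather than merely accurate to the lattice error.
#'
#' @param mol a [Molecule-class] with coordinates and radii.
#' @param probeRadius probe radius in Angstrom; 1.4 approximates water.
#' @param nSpherePoints sampling points per atom (>= 92; 960 default).
#' @return a [SurfaceResult-class].
#' @examples
#' m <- molecule("C", matrix(0, 1, 3))  # lone carbon, r = 1.70
#' totalArea(accessibleSurfaceArea(m))  # ~ 4*pi*3.1^2
#' @export
accessibleSurfaceArea <- function(mol, probeRadius = 1.4,
                                  nSpherePoints = 960L) {
  if (nSpherePoints < 92L) stop("nSpherePoints must be >= 92")
  xyz <- coords(mol)
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  xyz <- .canonical_frame(xyz)
  n <- nAtoms(mol)
  rExp <- vdwRadii(mol) + probeRadius
  pts <- spherePoints(nSpherePoints)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * rExp[i], 2L, xyz[i, ], `+`)
    acc <- rep(TRUE, nSpherePoints)
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (dij >= rExp[i] + rExp[j]) next
      d2 <- (p[, 1L] - xyz[j, 1L])^2 + (p[, 2L] - xyz[j, 2L])^2 +
            (p[, 3L] - xyz[j, 3L])^2
      acc <- acc & d2 >= rExp[j]^2
      if (!any(acc)) break
    }
    areas[i] <- 4 * pi * rExp[i]^2 * sum(acc) / nSpherePoints
  }
  new("SurfaceResult", perAtomArea = areas,
      probeRadius = as.numeric(probeRadius),
      nSpherePoints = as.integer(nSpherePoints))
}

#' Charge-weighted accessible surface area terms
#'
#' Partitions the accessible area by the sign of the partial charge and
#' weights by an extreme charge: ASA+ (area over atoms with q > 0), ASA-
#' (area over atoms with q strictly < 0), CASA+ = ASA+ * max charge among
#' positive atoms, CASA- = ASA- * |extreme negative charge|.  The
#' "extreme" negative charge is, literally read, the *least* negative one
#' (the maximum over q < 0); `casaNegMode = "most_negative"` switches to
#' the minimum.  Both CASA terms are reported as non-negative magnitudes
#' in Angstrom^2 times elementary charge.
#'
#' @param surface a [SurfaceResult-class].
#' @param charges partial charges aligned with the surface atoms.
#' @param casaNegMode `"least_negative"` (literal reading, default) or
#'   `"most_negative"`.
#' @return named list: `ASA_pos`, `ASA_neg`, `ASA_zero`, `CASA_pos`,
#'   `CASA_neg`.
#' @export
casaTerms <- function(surface, charges,
                      casaNegMode = c("least_negative", "most_negative")) {
  casaNegMode <- match.arg(casaNegMode)
  area <- perAtomArea(surface)
  if (length(area) != length(charges))
    stop("surface and charges are not index-aligned")
  pos <- charges > 0
  neg <- charges < 0
  asaPos <- sum(area[pos])
  asaNeg <- sum(area[neg])
  qPos <- if (any(pos)) max(charges[pos]) else 0
  qNeg <- if (any(neg)) {
    if (casaNegMode == "least_negative") max(charges[neg])
    else min(charges[neg])
  } else 0
  list(
    ASA_pos = asaPos,
    ASA_neg = asaNeg,
    ASA_zero = sum(area[!pos & !neg]),
    CASA_pos = asaPos * qPos,
    CASA_neg = asaNeg * abs(qNeg)
  )
}
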