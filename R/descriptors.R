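# The six retained potency descriptors, computed from a 3D structure:
#   E_nb     nonbonded (Lennard-Jones + Coulomb) potential energy, kcal/mol
#   E_ang    harmonic angle-bend potential energy, kcal/mol
#   ASA_neg  water-accessible area of atoms with q < 0, A^2
#   CASA_pos ASA+ weighted by the largest positive charge, A^2 e
#   CASA_neg ASA- weighted by an extreme negative charge, A^2 e
#   vsa_pol  van der Waals surface area of atoms that are both hydrogen
#            bond donors and acceptors, A^2

.descriptor_names <- c("E_nb", "E_ang", "ASA_neg", "CASA_pos", "CASA_neg",
                       "vsa_pol")

#' Canonical descriptor names
#' @return character vector of the six descriptor column names, in order.
#' @export
descriptorNameSet <- function() .descriptor_names

#' Descriptor-engine configuration
#'
#' @param probeRadius solvent probe radius, Angstrom (1.4 = water).
#' @param nSpherePoints surface sampling points per atom.
#' @param casaNegMode negative-extreme convention for CASA-, see
#'   [casaTerms()].
#' @param forcefield parameter list, see [defaultForcefield()].
#' @return configuration list consumed by [computeDescriptors()].
#' @export
descriptorConfig <- function(probeRadius = 1.4, nSpherePoints = 960L,
                             casaNegMode = "least_negative",
                             forcefield = defaultForcefield()) {
  list(probeRadius = probeRadius, nSpherePoints = as.integer(nSpherePoints),
       casaNegMode = casaNegMode, forcefield = forcefield)
}

# Topological distances up to 3 bonds, for the 1-2/1-3 exclusions and the
# 1-4 scaling.  Returns an n x n integer matrix with Inf beyond 3.
.topo_dist3 <- function(n, b) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      d[b[k, 1L], b[k, 2L]] <- 1
      d[b[k, 2L], b[k, 1L]] <- 1
    }
    for (step in 2:3) {
      for (k in seq_len(nrow(b))) {
        i <- b[k, 1L]; j <- b[k, 2L]
        d[, j] <- pmin(d[, j], d[, i] + 1)
        d[, i] <- pmin(d[, i], d[, j] + 1)
        d[j, ] <- pmin(d[j, ], d[i, ] + 1)
        d[i, ] <- pmin(d[i, ], d[j, ] + 1)
      }
    }
  }
  d
}

#' Nonbonded potential energy
#'
#' Sum over intramolecular atom pairs that are not 1-2 or 1-3 bonded of a
#' Lennard-Jones term (eps_ij, rmin_ij by Lorentz-Berthelot combination)
#' plus a Coulomb term k q_i q_j / r; 1-4 pairs are scaled by
#' `forcefield$scale14` (default 1, i.e. unscaled).
#'
#' @param mol a [Molecule-class] with charges, radii and bonds populated.
#' @param forcefield parameter list, see [defaultForcefield()].
#' @return energy in kcal/mol.
#' @export
nonbondedEnergy <- function(mol, forcefield = defaultForcefield()) {
  n <- nAtoms(mol)
  if (n < 2L) return(0)
  xyz <- coords(mol)
  q <- charges(mol)
  lj <- .lj_params(elements(mol), forcefield)
  topo <- .topo_dist3(n, bonds(mol))
  e <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (topo[i, j] <= 2) next
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r == 0) stop("zero interatomic distance between atoms ", i,
                       " and ", j)
      epsij <- sqrt(lj$eps[i] * lj$eps[j])
      rmin <- lj$rminHalf[i] + lj$rminHalf[j]
      s6 <- (rmin / r)^6
      term <- epsij * (s6^2 - 2 * s6) +
        forcefield$coulombK * q[i] * q[j] / r
      if (topo[i, j] == 3) term <- term * forcefield$scale14
      e <- e + term
    }
  }
  e
}

#' Angle-bend potential energy
#'
#' Sum over all bond-angle triplets of k_theta * (theta - theta0)^2, with
#' k_theta and theta0 looked up by the central atom's element (harmonic,
#' theta in radians).
#'
#' @param mol a [Molecule-class] with bonds populated.
#' @param forcefield parameter list, see [defaultForcefield()].
#' @return energy in kcal/mol.
#' @export
angleBendEnergy <- function(mol, forcefield = defaultForcefield()) {
  ang <- enumerateAngles(mol)
  if (!nrow(ang)) return(0)
  xyz <- coords(mol)
  el <- elements(mol)
  e <- 0
  for (r in seq_len(nrow(ang))) {
    i <- ang[r, 1L]; j <- ang[r, 2L]; k <- ang[r, 3L]
    v1 <- xyz[i, ] - xyz[j, ]
    v2 <- xyz[k, ] - xyz[j, ]
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 == 0 || n2 == 0)
      stop("degenerate angle (coincident atoms) at triplet ", r)
    ct <- min(1, max(-1, sum(v1 * v2) / (n1 * n2)))
    theta <- acos(ct)
    theta0 <- .angle_param(el[j], forcefield$angle$theta0) * pi / 180
    kth <- .angle_param(el[j], forcefield$angle$k)
    e <- e + kth * (theta - theta0)^2
  }
  unname(e)
}

# Hydrogen-bond donor/acceptor classification (data-driven rule):
#   donor    = O or N carrying at least one bonded hydrogen
#   acceptor = any O; N unless pi-deficient (amide-like: bonded to a
#              carbon that is double-bonded to O; nitro-like: bonded to
#              two or more oxygens)
.donor_acceptor <- function(mol) {
  el <- elements(mol)
  n <- nAtoms(mol)
  b <- bonds(mol)
  nbrs <- lapply(seq_len(n), function(i) integer())
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      nbrs[[b[k, 1L]]] <- c(nbrs[[b[k, 1L]]], b[k, 2L])
      nbrs[[b[k, 2L]]] <- c(nbrs[[b[k, 2L]]], b[k, 1L])
    }
  }
  hasDoubleO <- function(c_idx) {
    if (!nrow(b)) return(FALSE)
    hit <- (b[, 1L] == c_idx & el[b[, 2L]] == "O" & mol@bondOrders >= 2) |
           (b[, 2L] == c_idx & el[b[, 1L]] == "O" & mol@bondOrders >= 2)
    any(hit)
  }
  donor <- acceptor <- logical(n)
  for (i in seq_len(n)) {
    if (!el[i] %in% c("N", "O")) next
    donor[i] <- any(el[nbrs[[i]]] == "H")
    if (el[i] == "O") {
      acceptor[i] <- TRUE
    } else {
      nO <- sum(el[nbrs[[i]]] == "O")
      amideLike <- any(vapply(nbrs[[i]][el[nbrs[[i]]] == "C"],
                              hasDoubleO, logical(1L)))
      acceptor[i] <- nO < 2L && !amideLike
    }
  }
  list(donor = donor, acceptor = acceptor)
}

#' Polar van der Waals surface area (vsa_pol)
#'
#' Sum of approximated van der Waals surface areas of polar atoms, i.e.
#' atoms that are simultaneously hydrogen-bond donors and acceptors.  The
#' per-atom vdW area is computed with the same sphere-sampling engine at
#' probe radius 0.
#'
#' @param mol a [Molecule-class] with elements and bonds populated.
#' @param nSpherePoints sampling points per atom.
#' @return area in Angstrom^2 (0 when no atom is both donor and acceptor).
#' @export
vsaPol <- function(mol, nSpherePoints = 960L) {
  da <- .donor_acceptor(mol)
  flag <- da$donor & da$acceptor
  if (!any(flag)) return(0)
  surf <- accessibleSurfaceArea(mol, probeRadius = 0, nSpherePoints)
  sum(perAtomArea(surf)[flag])
}

#' Compute the six-descriptor vector for one molecule
#'
#' Assembles E_nb, E_ang, ASA_neg, CASA_pos, CASA_neg and vsa_pol under one
#' shared configuration.  Deterministic: identical input and configuration
#' give bit-identical values.
#'
#' @param mol a [Molecule-class] with coordinates, charges and bonds.
#' @param config configuration from [descriptorConfig()].
#' @return named numeric vector of length 6 in canonical order.
#' @examples
#' m <- molecule("C", matrix(0, 1, 3))
#' computeDescriptors(m)
#' @export
computeDescriptors <- function(mol, config = descriptorConfig()) {
  surf <- accessibleSurfaceArea(mol, config$probeRadius, config$nSpherePoints)
  cs <- casaTerms(surf, charges(mol), config$casaNegMode)
  out <- c(
    E_nb = nonbondedEnergy(mol, config$forcefield),
    E_ang = angleBendEnergy(mol, config$forcefield),
    ASA_neg = cs$ASA_neg,
    CASA_pos = cs$CASA_pos,
    CASA_neg = cs$CASA_neg,
    vsa_pol = vsaPol(mol, config$nSpherePoints)
  )
  if (any(!is.finite(out))) stop("non-finite descriptor value")
  out
}

#' Descriptor table for a list of molecules
#'
#' @param mols list of [Molecule-class] objects.
#' @param config configuration from [descriptorConfig()].
#' @return data.frame with columns id (molecule names), then the six
#'   descriptors.
#' @export
descriptorTable <- function(mols, config = descriptorConfig()) {
  rows <- t(vapply(mols, computeDescriptors, numeric(6L), config = config))
  ids <- vapply(mols, function(m) m@name, "")
  if (anyDuplicated(ids) || !all(nzchar(ids)))
    ids <- as.character(seq_along(mols))
  data.frame(id = ids, rows, stringsAsFactors = FALSE)
}
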