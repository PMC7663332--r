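# Molecule construction, element tables and charge assignment.

# Bondi van der Waals radii (Angstrom); overridable via radiusTable=.
.bondi_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98,
                  Si = 2.10, B = 1.92)

# Single-bond covalent radii (Angstrom), used only for bond inference.
.covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                     P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39,
                     Si = 1.11, B = 0.84)

#' Default van der Waals radius table (Bondi)
#'
#' @return named numeric vector, Angstrom per element symbol.
#' @export
defaultRadiusTable <- function() .bondi_radii

.lookup_radii <- function(elements, radiusTable) {
  r <- radiusTable[elements]
  if (anyNA(r))
    stop("unknown element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  unname(r)
}

#' Construct a Molecule
#'
#' @param elements character vector of element symbols.
#' @param coords numeric n x 3 matrix, Angstrom.
#' @param charges partial charges (e); default all zero.
#' @param bonds integer m x 2 matrix of atom-index pairs, or NULL for none.
#' @param bondOrders numeric bond orders, default all 1.
#' @param radii explicit van der Waals radii, or NULL to look them up.
#' @param radiusTable named radius table used when `radii` is NULL.
#' @param name molecule title.
#' @return a [Molecule-class] object.
#' @examples
#' m <- molecule("C", matrix(0, 1, 3))
#' nAtoms(m)
#' @export
molecule <- function(elements, coords, charges = NULL, bonds = NULL,
                     bondOrders = NULL, radii = NULL,
                     radiusTable = defaultRadiusTable(), name = "molecule") {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  n <- length(elements)
  if (is.null(charges)) charges <- numeric(n)
  if (is.null(radii)) radii <- .lookup_radii(elements, radiusTable)
  if (is.null(bonds)) bonds <- matrix(integer(), 0L, 2L)
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (nrow(bonds)) {
    o <- bonds[, 1L] > bonds[, 2L]
    bonds[o, ] <- bonds[o, 2:1]
  }
  if (is.null(bondOrders)) bondOrders <- rep(1, nrow(bonds))
  new("Molecule", name = as.character(name), elements = as.character(elements),
      coords = coords, charges = as.numeric(charges),
      radii = as.numeric(radii), bonds = bonds,
      bondOrders = as.numeric(bondOrders))
}

#' Infer covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their separation is below `tol` times the sum
#' of their single-bond covalent radii (default tolerance 1.2).  Used for
#' XYZ input, which carries no connectivity; SDF connectivity is always
#' taken from the bond block verbatim.
#'
#' @param mol a [Molecule-class].
#' @param tol multiplicative tolerance on the covalent-radius sum.
#' @return the molecule with bonds (order 1) replaced by the inferred set.
#' @export
inferBonds <- function(mol, tol = 1.2) {
  n <- nAtoms(mol)
  rc <- .covalent_radii[elements(mol)]
  if (anyNA(rc))
    stop("no covalent radius for element(s): ",
         paste(unique(elements(mol)[is.na(rc)]), collapse = ", "))
  prs <- if (n >= 2L) utils::combn(n, 2L) else matrix(integer(), 2L, 0L)
  keep <- logical(ncol(prs))
  xyz <- coords(mol)
  for (k in seq_len(ncol(prs))) {
    i <- prs[1L, k]; j <- prs[2L, k]
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    keep[k] <- d <= tol * (rc[i] + rc[j])
  }
  mol@bonds <- t(prs[, keep, drop = FALSE])
  mol@bondOrders <- rep(1, sum(keep))
  validObject(mol)
  mol
}

#' Enumerate bond-angle triplets
#'
#' All and only triplets (i, j, k) with i < k where j is bonded to both i
#' and k; the angle is at the central atom j.
#'
#' @param mol a [Molecule-class] with bonds populated.
#' @return integer matrix with columns `i`, `j`, `k` (possibly 0 rows).
#' @export
enumerateAngles <- function(mol) {
  b <- bonds(mol)
  out <- matrix(integer(), 0L, 3L, dimnames = list(NULL, c("i", "j", "k")))
  if (!nrow(b)) return(out)
  nb <- split(c(b[, 2L], b[, 1L]), c(b[, 1L], b[, 2L]))
  res <- list()
  for (j in as.integer(names(nb))) {
    nbr <- sort(unique(nb[[as.character(j)]]))
    if (length(nbr) < 2L) next
    prs <- utils::combn(nbr, 2L)
    res[[length(res) + 1L]] <- cbind(prs[1L, ], j, prs[2L, ])
  }
  if (!length(res)) return(out)
  m <- do.call(rbind, res)
  m <- m[order(m[, 2L], m[, 1L], m[, 3L]), , drop = FALSE]
  storage.mode(m) <- "integer"
  dimnames(m) <- list(NULL, c("i", "j", "k"))
  m
}

# Gasteiger-Marsili PEOE parameters (a, b, c) by element and bond class.
# chi(q) = a + b q + c q^2; cation electronegativity a + b + c caps the
# transfer denominator (20.02 for H, by convention).
.peoe_params <- function(element, maxOrder) {
  tab <- switch(element,
    H = c(7.17, 6.24, -0.56),
    C = if (maxOrder >= 3) c(10.39, 9.45, 0.73)
        else if (maxOrder >= 2) c(8.79, 9.32, 1.51) else c(7.98, 9.18, 1.88),
    N = if (maxOrder >= 3) c(15.68, 11.70, -0.27)
        else if (maxOrder >= 2) c(12.87, 11.15, 0.85) else c(11.54, 10.82, 1.36),
    O = if (maxOrder >= 2) c(17.07, 13.79, 0.47) else c(14.18, 12.92, 1.39),
    S = c(10.14, 9.13, 1.38),
    F = c(14.66, 13.85, 2.31),
    Cl = c(11.00, 9.69, 1.35),
    Br = c(10.08, 8.47, 1.16),
    I = c(9.90, 7.96, 0.96),
    stop("no electronegativity parameters for element: ", element)
  )
  tab
}

#' Assign partial charges by iterative electronegativity equalization
#'
#' Gasteiger-Marsili partial equalization of orbital electronegativities
#' (PEOE): starting from zero charge, charge flows along each bond in
#' proportion to the electronegativity difference, with a geometric damping
#' factor per cycle.  This is a classical empirical scheme; it is not the
#' semi-empirical AM1 population analysis some modelling suites use, so
#' charges (and hence charge-weighted descriptors) are comparable only
#' within one assignment scheme.
#'
#' @param mol a [Molecule-class] with bonds populated.
#' @param nIter number of damping cycles (6 is the classical choice).
#' @param damping per-cycle damping factor.
#' @return the molecule with `charges` replaced.
#' @export
assignCharges <- function(mol, nIter = 6L, damping = 0.5) {
  n <- nAtoms(mol)
  b <- bonds(mol)
  el <- elements(mol)
  maxOrd <- rep(1, n)
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      o <- mol@bondOrders[k]
      maxOrd[b[k, 1L]] <- max(maxOrd[b[k, 1L]], o)
      maxOrd[b[k, 2L]] <- max(maxOrd[b[k, 2L]], o)
    }
  }
  par <- t(vapply(seq_len(n),
                  function(i) .peoe_params(el[i], maxOrd[i]), numeric(3L)))
  chiPlus <- ifelse(el == "H", 20.02, rowSums(par))
  q <- numeric(n)
  if (!nrow(b)) { charges(mol) <- q; return(mol) }
  for (cyc in seq_len(nIter)) {
    chi <- par[, 1L] + par[, 2L] * q + par[, 3L] * q^2
    dq <- numeric(n)
    f <- damping^cyc
    for (k in seq_len(nrow(b))) {
      i <- b[k, 1L]; j <- b[k, 2L]
      if (chi[j] > chi[i]) {
        move <- (chi[j] - chi[i]) / chiPlus[i] * f
        dq[i] <- dq[i] + move; dq[j] <- dq[j] - move
      } else {
        move <- (chi[i] - chi[j]) / chiPlus[j] * f
        dq[j] <- dq[j] + move; dq[i] <- dq[i] - move
      }
    }
    q <- q + dq
  }
  charges(mol) <- q
  mol
}
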