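#' @import methods
NULL

#' Molecule: a minimal 3D small-molecule representation
#'
#' Holds per-atom element symbols, Cartesian coordinates (Angstrom), van der
#' Waals radii (Angstrom) and partial charges (elementary charge units),
#' plus the covalent bond list and bond orders.  This is all the structural
#' information the descriptor engine needs; there is no perception of
#' aromaticity, stereochemistry or protonation beyond what the input file
#' states.
#'
#' @slot name single character, molecule title.
#' @slot elements character vector of element symbols, one per atom.
#' @slot coords numeric n x 3 matrix of coordinates in Angstrom.
#' @slot charges numeric vector of partial atomic charges (e).
#' @slot radii numeric vector of van der Waals radii (Angstrom).
#' @slot bonds integer m x 2 matrix of 1-based atom index pairs (i < j).
#' @slot bondOrders numeric vector of length m (1 = single, 2 = double, ...).
#'
#' @seealso [molecule()], [readStructures()], [computeDescriptors()]
#' @export
setClass("Molecule",
  representation(
    name = "character",
    elements = "character",
    coords = "matrix",
    charges = "numeric",
    radii = "numeric",
    bonds = "matrix",
    bondOrders = "numeric"
  )
)

setValidity("Molecule", function(object) {
  n <- length(object@elements)
  msgs <- character()
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L ||
      nrow(object@coords) != n)
    msgs <- c(msgs, "coords must be a numeric n x 3 matrix matching elements")
  if (any(!is.finite(object@coords)))
    msgs <- c(msgs, "coordinates must be finite")
  if (length(object@charges) != n)
    msgs <- c(msgs, "charges must have one entry per atom")
  if (length(object@radii) != n)
    msgs <- c(msgs, "radii must have one entry per atom")
  if (length(object@radii) && any(!is.finite(object@radii) | object@radii <= 0))
    msgs <- c(msgs, "van der Waals radii must be positive and finite")
  b <- object@bonds
  if (nrow(b)) {
    if (any(b < 1L | b > n)) msgs <- c(msgs, "bond indices out of range")
    if (any(b[, 1L] == b[, 2L])) msgs <- c(msgs, "self-bonds are not allowed")
    key <- paste(pmin(b[, 1L], b[, 2L]), pmax(b[, 1L], b[, 2L]))
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate bonds")
  }
  if (length(object@bondOrders) != nrow(b))
    msgs <- c(msgs, "bondOrders must have one entry per bond")
  if (length(msgs)) msgs else TRUE
})

#' SurfaceResult: per-atom solvent-accessible surface areas
#'
#' Result of the numerical (Shrake-Rupley style) accessible-surface
#' computation: one non-negative area per atom, together with the probe
#' radius and the number of sampling points used.
#'
#' @slot perAtomArea numeric vector of areas, Angstrom^2, one per atom.
#' @slot probeRadius probe radius in Angstrom (1.4 for a water probe).
#' @slot nSpherePoints number of sampling points per atom sphere.
#'
#' @seealso [accessibleSurfaceArea()], [casaTerms()]
#' @export
setClass("SurfaceResult",
  representation(
    perAtomArea = "numeric",
    probeRadius = "numeric",
    nSpherePoints = "integer"
  )
)

setValidity("SurfaceResult", function(object) {
  msgs <- character()
  if (any(!is.finite(object@perAtomArea) | object@perAtomArea < -1e-9))
    msgs <- c(msgs, "per-atom areas must be finite and non-negative")
  if (length(object@probeRadius) != 1L || object@probeRadius < 0)
    msgs <- c(msgs, "probeRadius must be a single non-negative number")
  if (length(msgs)) msgs else TRUE
})

#' PLSModel: a fitted PLS1 regression model
#'
#' Partial least squares regression of a single response on an autoscaled
#' descriptor matrix, with the loadings/weights per latent variable, the
#' back-transformed coefficients on the original descriptor scale, the
#' relative-importance (RI) values and the fit statistics.
#'
#' @slot descriptorNames column names the model was fitted on.
#' @slot xMeans,xSds centring/scaling vectors applied to the descriptors.
#' @slot yMean training-response mean (the response is centred, not scaled).
#' @slot weights,loadings p x a matrices of PLS weights and X-loadings.
#' @slot yLoadings numeric vector of length a (inner regression weights).
#' @slot scores n x a matrix of training scores.
#' @slot nComponents number of latent variables retained.
#' @slot coefScaled regression coefficients on the autoscaled X scale.
#' @slot coefficients coefficients on the original descriptor scale.
#' @slot intercept intercept on the original scale.
#' @slot ri named relative-importance values in (0, 1], max exactly 1.
#' @slot stats named list: r2_ncv, r2_cv (leave-one-out q2, NA until
#'   computed), rmse (training RMSE).
#'
#' @seealso [plsFit()], [looQ2()], [relativeImportance()]
#' @export
setClass("PLSModel",
  representation(
    descriptorNames = "character",
    xMeans = "numeric",
    xSds = "numeric",
    yMean = "numeric",
    weights = "matrix",
    loadings = "matrix",
    yLoadings = "numeric",
    scores = "matrix",
    nComponents = "integer",
    coefScaled = "numeric",
    coefficients = "numeric",
    intercept = "numeric",
    ri = "numeric",
    stats = "list"
  )
)

setValidity("PLSModel", function(object) {
  p <- length(object@descriptorNames)
  msgs <- character()
  if (length(object@coefficients) != p || length(object@coefScaled) != p)
    msgs <- c(msgs, "one coefficient per descriptor required")
  if (length(object@ri) && abs(max(object@ri) - 1) > 1e-12)
    msgs <- c(msgs, "max relative importance must equal 1")
  if (!is.null(object@stats$rmse) && is.finite(object@stats$rmse) &&
      object@stats$rmse < 0)
    msgs <- c(msgs, "rmse must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' ScoringEquation: a fixed linear pEC50 scoring function
#'
#' An intercept plus one coefficient per descriptor, mapping a descriptor
#' vector to predicted pEC50.  Houses the two published corrector potency
#' equations (models A and B) as shipped, inspectable objects; custom
#' equations use the same class.
#'
#' @slot name one of "model_A", "model_B", "custom".
#' @slot intercept intercept in pEC50 units.
#' @slot coefficients named numeric vector over the six descriptor names.
#' @slot descriptorScale "raw" (coefficients apply to descriptors in their
#'   natural units) or "autoscaled" (descriptors must be centred/scaled
#'   first; the scaling is not part of the shipped equation).
#' @slot metadata list of free-form notes (transcription caveats etc.).
#'
#' @seealso [builtinEquation()], [predictEquation()], [sensitivity()]
#' @export
setClass("ScoringEquation",
  representation(
    name = "character",
    intercept = "numeric",
    coefficients = "numeric",
    descriptorScale = "character",
    metadata = "list"
  )
)

setValidity("ScoringEquation", function(object) {
  msgs <- character()
  if (is.null(names(object@coefficients)) ||
      anyDuplicated(names(object@coefficients)))
    msgs <- c(msgs, "coefficients must be uniquely named")
  if (!object@descriptorScale %in% c("raw", "autoscaled"))
    msgs <- c(msgs, "descriptorScale must be 'raw' or 'autoscaled'")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msgs <- c(msgs, "intercept must be a single finite number")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn Molecule-class compact display
#' @param object a `Molecule`
#' @export
setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule '%s': %d atoms, %d bonds\n",
              object@name, length(object@elements), nrow(object@bonds)))
  cat("  elements:", paste(unique(object@elements), collapse = " "), "\n")
  qr <- range(object@charges)
  cat(sprintf("  charges in [%.3f, %.3f] e\n", qr[1], qr[2]))
  invisible(object)
})

#' @describeIn SurfaceResult-class compact display
#' @param object a `SurfaceResult`
#' @export
setMethod("show", "SurfaceResult", function(object) {
  cat(sprintf(
    "SurfaceResult: %d atoms, total %.2f A^2 (probe %.2f A, %d points)\n",
    length(object@perAtomArea), sum(object@perAtomArea),
    object@probeRadius, object@nSpherePoints))
  invisible(object)
})

#' @describeIn PLSModel-class compact display
#' @param object a `PLSModel`
#' @export
setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d descriptors, %d latent variable(s)\n",
              length(object@descriptorNames), object@nComponents))
  cat(sprintf("  r2_ncv = %.4f, rmse = %.4f",
              object@stats$r2_ncv, object@stats$rmse))
  if (!is.null(object@stats$r2_cv) && is.finite(object@stats$r2_cv))
    cat(sprintf(", r2_cv = %.4f", object@stats$r2_cv))
  cat("\n  top RI:", paste(utils::head(names(sort(object@ri,
      decreasing = TRUE)), 3L), collapse = ", "), "\n")
  invisible(object)
})

#' @describeIn ScoringEquation-class compact display
#' @param object a `ScoringEquation`
#' @export
setMethod("show", "ScoringEquation", function(object) {
  cat(sprintf("ScoringEquation '%s' (%s descriptor scale)\n",
              object@name, object@descriptorScale))
  cat(sprintf("  pEC50 = %.5f", object@intercept))
  for (nm in names(object@coefficients)) {
    co <- object@coefficients[[nm]]
    cat(sprintf(" %s %.5f * %s", if (co < 0) "-" else "+", abs(co), nm))
  }
  cat("\n")
  invisible(object)
})
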