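# Accessor generics and methods.  Slot access from user code is discouraged;
# these are the supported surface.

#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @export
setGeneric("charges", function(x) standardGeneric("charges"))
#' @export
setGeneric("charges<-", function(x, value) standardGeneric("charges<-"))
#' @export
setGeneric("vdwRadii", function(x) standardGeneric("vdwRadii"))
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))
#' @export
setGeneric("bondOrders", function(x) standardGeneric("bondOrders"))
#' @export
setGeneric("perAtomArea", function(x) standardGeneric("perAtomArea"))
#' @export
setGeneric("totalArea", function(x) standardGeneric("totalArea"))
#' @export
setGeneric("riValues", function(x) standardGeneric("riValues"))
#' @export
setGeneric("modelStats", function(x) standardGeneric("modelStats"))
#' @export
setGeneric("descriptorNames", function(x) standardGeneric("descriptorNames"))
#' @export
setGeneric("intercept", function(x) standardGeneric("intercept"))

#' Accessors for Molecule objects
#'
#' `nAtoms()`, `elements()`, `coords()`, `charges()`, `vdwRadii()`,
#' `bonds()` and `bondOrders()` read the corresponding components;
#' `charges<-` replaces the partial charges (length-checked).
#'
#' @param x a [Molecule-class] object.
#' @param value numeric replacement charges, one per atom.
#' @return the requested component.
#' @name molecule-accessors
#' @aliases nAtoms elements coords charges charges<- vdwRadii bonds bondOrders
NULL

#' @rdname molecule-accessors
#' @export
setMethod("nAtoms", "Molecule", function(x) length(x@elements))
#' @rdname molecule-accessors
#' @export
setMethod("elements", "Molecule", function(x) x@elements)
#' @rdname molecule-accessors
#' @export
setMethod("coords", "Molecule", function(x) x@coords)
#' @rdname molecule-accessors
#' @export
setMethod("charges", "Molecule", function(x) x@charges)
#' @rdname molecule-accessors
#' @export
setReplaceMethod("charges", "Molecule", function(x, value) {
  stopifnot(length(value) == length(x@elements), all(is.finite(value)))
  x@charges <- as.numeric(value)
  x
})
#' @rdname molecule-accessors
#' @export
setMethod("vdwRadii", "Molecule", function(x) x@radii)
#' @rdname molecule-accessors
#' @export
setMethod("bonds", "Molecule", function(x) x@bonds)
#' @rdname molecule-accessors
#' @export
setMethod("bondOrders", "Molecule", function(x) x@bondOrders)

#' Accessors for SurfaceResult objects
#'
#' @param x a [SurfaceResult-class] object.
#' @return `perAtomArea()` the per-atom areas (Angstrom^2); `totalArea()`
#'   their sum.
#' @name surface-accessors
#' @aliases perAtomArea totalArea
NULL

#' @rdname surface-accessors
#' @export
setMethod("perAtomArea", "SurfaceResult", function(x) x@perAtomArea)
#' @rdname surface-accessors
#' @export
setMethod("totalArea", "SurfaceResult", function(x) sum(x@perAtomArea))

#' Accessors for PLSModel objects
#'
#' `coef()` returns the regression coefficients on the original descriptor
#' scale (attribute `"intercept"` carries the intercept); `riValues()` the
#' relative-importance map; `modelStats()` the named list with `r2_ncv`,
#' `r2_cv` and `rmse`; `descriptorNames()` the fitted column names.
#'
#' @param object,x a [PLSModel-class] object.
#' @param ... unused.
#' @name pls-accessors
#' @aliases riValues modelStats descriptorNames intercept
NULL

#' @rdname pls-accessors
#' @export
setMethod("coef", "PLSModel", function(object, ...) {
  structure(object@coefficients, names = object@descriptorNames,
            intercept = object@intercept)
})
#' @rdname pls-accessors
#' @export
setMethod("riValues", "PLSModel", function(x) x@ri)
#' @rdname pls-accessors
#' @export
setMethod("modelStats", "PLSModel", function(x) x@stats)
#' @rdname pls-accessors
#' @export
setMethod("descriptorNames", "PLSModel", function(x) x@descriptorNames)
#' @rdname pls-accessors
#' @export
setMethod("intercept", "PLSModel", function(x) x@intercept)

#' Accessors for ScoringEquation objects
#'
#' @param object,x a [ScoringEquation-class] object.
#' @param ... unused.
#' @return `coef()` the named coefficient vector; `intercept()` the
#'   intercept; `descriptorNames()` the descriptor names the equation
#'   expects.
#' @name equation-accessors
NULL

#' @rdname equation-accessors
#' @export
setMethod("coef", "ScoringEquation", function(object, ...) object@coefficients)
#' @rdname equation-accessors
#' @export
setMethod("intercept", "ScoringEquation", function(x) x@intercept)
#' @rdname equation-accessors
#' @export
setMethod("descriptorNames", "ScoringEquation",
          function(x) names(x@coefficients))
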