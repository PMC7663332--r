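# The two published corrector-potency scoring equations, shipped as fixed
# inspectable objects.  Model A is on raw descriptor units; model B's
# coefficient magnitudes are only compatible with autoscaled descriptors,
# and the centring/scaling vectors were never published, so predicting
# from raw descriptors with model B requires user-supplied scaling.

.eq_model_a <- c(E_nb = -0.10591, ASA_neg = -0.01931, vsa_pol = -0.04699,
                 CASA_pos = 0.00260, CASA_neg = 0.00658, E_ang = -0.02034)
.eq_model_b <- c(E_nb = -3.70703, ASA_neg = -1.08439, vsa_pol = -0.51885,
                 CASA_pos = 2.77245, CASA_neg = 0.93650, E_ang = -0.152808)

#' Construct a linear scoring equation
#'
#' @param intercept intercept, pEC50 units.
#' @param coefficients named numeric vector over descriptor names.
#' @param name equation label.
#' @param descriptorScale `"raw"` or `"autoscaled"`.
#' @param notes free-form metadata notes.
#' @return a [ScoringEquation-class].
#' @export
scoringEquation <- function(intercept, coefficients, name = "custom",
                            descriptorScale = "raw", notes = character()) {
  new("ScoringEquation", name = name, intercept = as.numeric(intercept),
      coefficients = coefficients, descriptorScale = descriptorScale,
      metadata = list(notes = notes))
}

#' The published scoring equations (models A and B)
#'
#' Returns the fixed linear pEC50 equation of the published model A
#' (manual split; raw descriptor scale) or model B (Kennard-Stone split;
#' autoscaled descriptor scale).  Coefficients are shipped digit-for-digit
#' as printed.  The equation's third term is printed as "ASA"; the
#' retained-descriptor table lists ASA- (and no plain ASA), so it is
#' mapped to `ASA_neg` here, with that reading recorded in
#' `metadata$notes`.
#'
#' @param model `"A"` or `"B"`.
#' @return a [ScoringEquation-class].
#' @examples
#' eqA <- builtinEquation("A")
#' zero <- setNames(numeric(6), descriptorNameSet())
#' predictEquation(eqA, zero)   # the intercept, 12.91882
#' @export
builtinEquation <- function(model = c("A", "B")) {
  model <- match.arg(model)
  if (model == "A") {
    scoringEquation(12.91882, .eq_model_a, name = "model_A",
                    descriptorScale = "raw",
                    notes = paste("printed 'ASA' term mapped to ASA_neg",
                                  "(the retained descriptor set has ASA-,",
                                  "no plain ASA)"))
  } else {
    scoringEquation(12.40705, .eq_model_b, name = "model_B",
                    descriptorScale = "autoscaled",
                    notes = paste("coefficient magnitudes imply autoscaled",
                                  "descriptors; the scaling vectors were",
                                  "not published, so raw-scale prediction",
                                  "requires user-supplied center/scale"))
  }
}

#' Predict pEC50 from a scoring equation
#'
#' Computes intercept + sum(coefficient * descriptor) in double precision.
#' `newdata` may be a named numeric vector (one compound) or a
#' matrix/data.frame with one column per descriptor.  For an equation on
#' the autoscaled descriptor scale, `center` and `scale` vectors (named by
#' descriptor) must be supplied and are applied to `newdata` first.
#'
#' @param equation a [ScoringEquation-class].
#' @param newdata descriptor values; all equation descriptors must be
#'   present and finite.
#' @param center,scale optional named autoscaling vectors (required when
#'   `descriptorScale == "autoscaled"`).
#' @return numeric vector of predicted pEC50 values.
#' @export
predictEquation <- function(equation, newdata, center = NULL, scale = NULL) {
  nms <- names(coef(equation))
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1L,
                      dimnames = list(NULL, names(newdata)))
  }
  newdata <- as.matrix(as.data.frame(newdata))
  missing <- setdiff(nms, colnames(newdata))
  if (length(missing))
    stop("missing descriptor field(s): ", paste(missing, collapse = ", "))
  X <- newdata[, nms, drop = FALSE]
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("non-finite descriptor value(s)")
  if (equation@descriptorScale == "autoscaled") {
    if (is.null(center) || is.null(scale))
      stop("equation '", equation@name, "' expects autoscaled descriptors; ",
           "supply center= and scale= (the published model does not ",
           "include them)")
    X <- sweep(sweep(X, 2L, center[nms]), 2L, scale[nms], `/`)
  }
  as.numeric(intercept(equation) + X %*% coef(equation))
}

#' Coefficient sign and magnitude report
#'
#' @param equation a [ScoringEquation-class].
#' @return data.frame (one row per descriptor, ordered by decreasing
#'   |coefficient|): descriptor, coefficient, sign, magnitudeRank.
#' @export
sensitivity <- function(equation) {
  co <- coef(equation)
  ord <- order(-abs(co))
  data.frame(descriptor = names(co)[ord],
             coefficient = unname(co[ord]),
             sign = ifelse(co[ord] > 0, "positive",
                           ifelse(co[ord] < 0, "negative", "zero")),
             magnitudeRank = seq_along(co),
             stringsAsFactors = FALSE)
}

#' Serialize / deserialize scoring equations as JSON
#'
#' @param equation a [ScoringEquation-class].
#' @param path file path.
#' @return `equationToJSON` the path invisibly; `equationFromJSON` the
#'   reconstructed equation.
#' @export
equationToJSON <- function(equation, path) {
  jsonlite::write_json(list(
    name = equation@name, intercept = equation@intercept,
    coefficients = as.list(coef(equation)),
    descriptorScale = equation@descriptorScale,
    notes = equation@metadata$notes
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname equationToJSON
#' @export
equationFromJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scoringEquation(x$intercept, unlist(x$coefficients), name = x$name,
                  descriptorScale = x$descriptorScale,
                  notes = if (is.null(x$notes)) character() else x$notes)
}
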