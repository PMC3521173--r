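## Accessor generics.  Slots are never reached into from user code.

#' @name accessors
#' @title Accessors for fitted divergence objects
#' @description Read-only accessors for \linkS4class{DivergenceEstimate} and
#'   \linkS4class{TripleEstimate}: the fitted distance (expected
#'   substitutions/site), its standard error, the usable/mismatching site
#'   counts, the fitted model, convergence status and, for three-taxon fits,
#'   the mouse+rat path length used for D/d-style ratios.
#' @param x a fitted estimate object.
#' @return A scalar (or, for \code{fittedModel}, a
#'   \linkS4class{SubstitutionModel}).
NULL

#' @rdname accessors
#' @export
setGeneric("substDistance", function(x) standardGeneric("substDistance"))
#' @rdname accessors
#' @export
setGeneric("distanceSE", function(x) standardGeneric("distanceSE"))
#' @rdname accessors
#' @export
setGeneric("gammaShapeSE", function(x) standardGeneric("gammaShapeSE"))
#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname accessors
#' @export
setGeneric("nDiff", function(x) standardGeneric("nDiff"))
#' @rdname accessors
#' @export
setGeneric("fittedModel", function(x) standardGeneric("fittedModel"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setGeneric("mouseRatDistance", function(x) standardGeneric("mouseRatDistance"))
#' @rdname accessors
#' @export
setGeneric("branchLengths", function(x) standardGeneric("branchLengths"))

#' @rdname accessors
#' @export
setMethod("substDistance", "DivergenceEstimate", function(x) x@distance)
#' @rdname accessors
#' @export
setMethod("distanceSE", "DivergenceEstimate", function(x) x@se)
#' @rdname accessors
#' @export
setMethod("gammaShapeSE", "DivergenceEstimate", function(x) x@alphaSE)
#' @rdname accessors
#' @export
setMethod("nSites", "DivergenceEstimate", function(x) x@nSites)
#' @rdname accessors
#' @export
setMethod("nDiff", "DivergenceEstimate", function(x) x@nDiff)
#' @rdname accessors
#' @export
setMethod("fittedModel", "DivergenceEstimate", function(x) x@model)
#' @rdname accessors
#' @export
setMethod("isConverged", "DivergenceEstimate", function(x) x@converged)
#' @rdname accessors
#' @export
setMethod("logLik", "DivergenceEstimate", function(object, ...) object@logLik)

#' @rdname accessors
#' @export
setMethod("branchLengths", "TripleEstimate", function(x) x@branchLengths)
#' @rdname accessors
#' @export
setMethod("mouseRatDistance", "TripleEstimate", function(x)
  unname(x@branchLengths["mouse"] + x@branchLengths["rat"]))
#' @rdname accessors
#' @export
setMethod("fittedModel", "TripleEstimate", function(x) x@model)
#' @rdname accessors
#' @export
setMethod("nSites", "TripleEstimate", function(x) x@nSites)
#' @rdname accessors
#' @export
setMethod("nDiff", "TripleEstimate", function(x) x@nDiff)
#' @rdname accessors
#' @export
setMethod("isConverged", "TripleEstimate", function(x) x@converged)

#' @rdname accessors
#' @export
setGeneric("alignmentWidth", function(x) standardGeneric("alignmentWidth"))
#' @rdname accessors
#' @export
setMethod("alignmentWidth", "TripleAlignment", function(x)
  nchar(x@seqs[[1L]]))
#' @rdname accessors
#' @export
setGeneric("maskPositions", function(x) standardGeneric("maskPositions"))
#' @rdname accessors
#' @export
setMethod("maskPositions", "SiteMask", function(x) x@positions)
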