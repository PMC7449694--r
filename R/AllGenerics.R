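#' @rdname snpIds
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname estimate
#' @export
setGeneric("estimate", function(x) standardGeneric("estimate"))

#' @rdname estimate
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))

#' @rdname estimate
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname estimate
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname estimate
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))

#' @rdname oddsRatio
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))

#' @rdname selectionLog
#' @export
setGeneric("selectionLog", function(x) standardGeneric("selectionLog"))

#' @rdname snpIds
#' @export
setGeneric("ldRho", function(x) standardGeneric("ldRho"))

#' @rdname estimate
#' @export
setGeneric("heterogeneityQ", function(x) standardGeneric("heterogeneityQ"))

#' @rdname conditionalF
#' @export
setGeneric("conditionalF", function(x, ...) standardGeneric("conditionalF"))
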