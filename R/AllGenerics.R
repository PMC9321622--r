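#' Accessor generics
#'
#' Small accessor generics for the S4 containers and result objects.
#' Each result class also supports `as.list()` for programmatic access
#' to every slot.
#'
#' @param x an object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("axisValues", function(x) standardGeneric("axisValues"))

#' @rdname accessors
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @rdname accessors
#' @export
setGeneric("spectrumKind", function(x) standardGeneric("spectrumKind"))

#' @rdname accessors
#' @export
setGeneric("spectrumLabel", function(x) standardGeneric("spectrumLabel"))

#' @rdname accessors
#' @export
setGeneric("temperature", function(x) standardGeneric("temperature"))

#' @rdname accessors
#' @export
setGeneric("ksv", function(x) standardGeneric("ksv"))

#' @rdname accessors
#' @export
setGeneric("kq", function(x) standardGeneric("kq"))

#' @rdname accessors
#' @export
setGeneric("bindingConstant", function(x) standardGeneric("bindingConstant"))

#' @rdname accessors
#' @export
setGeneric("bindingSites", function(x) standardGeneric("bindingSites"))

#' @rdname accessors
#' @export
setGeneric("deltaH", function(x) standardGeneric("deltaH"))

#' @rdname accessors
#' @export
setGeneric("deltaS", function(x) standardGeneric("deltaS"))

#' @rdname accessors
#' @export
setGeneric("deltaG", function(x) standardGeneric("deltaG"))

#' @rdname accessors
#' @export
setGeneric("forceLabel", function(x) standardGeneric("forceLabel"))

#' @rdname accessors
#' @export
setGeneric("structureFractions", function(x) standardGeneric("structureFractions"))

#' @rdname accessors
#' @export
setGeneric("ic50", function(x) standardGeneric("ic50"))
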