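#' @rdname RamanSet
#' @param x,object a `RamanSet`
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname RamanSet
#' @export
setGeneric("donorIds", function(x) standardGeneric("donorIds"))

#' @rdname RamanSet
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname RamanSet
#' @export
setGeneric("spotIndices", function(x) standardGeneric("spotIndices"))

#' @rdname RamanSet
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname RamanSet
#' @param msg character, provenance line(s) to append
#' @export
setGeneric("addProvenance", function(x, msg) standardGeneric("addProvenance"))
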