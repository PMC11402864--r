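#' @rdname AopSet-class
#' @param x an object
#' @export
setGeneric("aops", function(x) standardGeneric("aops"))

#' @rdname AopSet-class
#' @export
setGeneric("keyEvents", function(x) standardGeneric("keyEvents"))

#' @rdname AopSet-class
#' @export
setGeneric("relationships", function(x) standardGeneric("relationships"))

#' @rdname AopSet-class
#' @export
setGeneric("quarantined", function(x) standardGeneric("quarantined"))

#' @rdname StressorAopNetwork-class
#' @param x an object
#' @export
setGeneric("links", function(x) standardGeneric("links"))

#' @rdname StressorAopNetwork-class
#' @export
setGeneric("chemicalAnnotations",
           function(x) standardGeneric("chemicalAnnotations"))

#' @rdname StressorAopNetwork-class
#' @export
setGeneric("aopAnnotations", function(x) standardGeneric("aopAnnotations"))

#' @rdname SyntheticWorld-class
#' @param x an object
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname SyntheticWorld-class
#' @export
setGeneric("worldPaths", function(x) standardGeneric("worldPaths"))
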