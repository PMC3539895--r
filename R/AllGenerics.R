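#' @rdname DatabaseSnapshot-class
#' @param object,x a \code{DatabaseSnapshot}
#' @export
setGeneric("sourceName", function(object) standardGeneric("sourceName"))

#' @rdname DatabaseSnapshot-class
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' @rdname DatabaseSnapshot-class
#' @export
setGeneric("xrefs", function(object) standardGeneric("xrefs"))

#' @rdname DatabaseSnapshot-class
#' @export
setGeneric("loadLog", function(object) standardGeneric("loadLog"))

#' @rdname fictsLabel
#' @export
setGeneric("fictsLabel", function(object) standardGeneric("fictsLabel"))

#' @rdname ConsistencyReport-class
#' @param object a report object
#' @export
setGeneric("conversionStats", function(object) standardGeneric("conversionStats"))

#' @rdname ConsistencyReport-class
#' @export
setGeneric("cells", function(object) standardGeneric("cells"))

#' @rdname ConsistencyReport-class
#' @export
setGeneric("verdicts", function(object) standardGeneric("verdicts"))

#' @rdname SyntheticStudy-class
#' @param object a \code{SyntheticStudy}
#' @export
setGeneric("dbA", function(object) standardGeneric("dbA"))

#' @rdname SyntheticStudy-class
#' @export
setGeneric("dbB", function(object) standardGeneric("dbB"))

#' @rdname SyntheticStudy-class
#' @export
setGeneric("edges", function(object) standardGeneric("edges"))

#' @rdname SyntheticStudy-class
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname SyntheticStudy-class
#' @export
setGeneric("nameTable", function(object) standardGeneric("nameTable"))

#' @rdname SyntheticStudy-class
#' @export
setGeneric("nameResolver", function(object) standardGeneric("nameResolver"))
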