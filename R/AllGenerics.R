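#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(object, ...) standardGeneric("transitionMatrix"))

#' @rdname accessors
#' @export
setGeneric("stationaryDist", function(object, ...) standardGeneric("stationaryDist"))

#' @rdname accessors
#' @export
setGeneric("affinityMatrix", function(object, ...) standardGeneric("affinityMatrix"))

#' @rdname accessors
#' @export
setGeneric("attractorLabels", function(object, ...) standardGeneric("attractorLabels"))

#' @rdname accessors
#' @export
setGeneric("membershipMatrix", function(object, ...) standardGeneric("membershipMatrix"))

#' @rdname accessors
#' @export
setGeneric("transitionEntropy", function(object, ...) standardGeneric("transitionEntropy"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(object, ...) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("cellIds", function(object, ...) standardGeneric("cellIds"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(object, ...) standardGeneric("geneIds"))

#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers; use these
#' instead of reaching into slots.
#'
#' @param object an S4 object from this package
#' @param ... unused
#' @name accessors
NULL
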