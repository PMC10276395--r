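#' Accessors
#'
#' Accessor generics for the core containers: \code{counts()} returns the
#' dense count matrix with dimnames, \code{geneIds()}/\code{cellIds()} the
#' identifiers, \code{cellTotals()}/\code{geneTotals()} the margin totals,
#' \code{departures()} the dense departure matrix, \code{lambdaTilde()} the
#' rate matrix implied by a two-way fit, and \code{lambdaHat()} the rate
#' matrix implied by a GLM-PCA fit.
#'
#' @param object an object of the matching class.
#' @return See the method descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))

#' @rdname accessors
#' @export
setGeneric("cellTotals", function(object) standardGeneric("cellTotals"))

#' @rdname accessors
#' @export
setGeneric("geneTotals", function(object) standardGeneric("geneTotals"))

#' @rdname accessors
#' @export
setGeneric("departures", function(object) standardGeneric("departures"))

#' @rdname accessors
#' @export
setGeneric("lambdaTilde", function(object) standardGeneric("lambdaTilde"))

#' @rdname accessors
#' @export
setGeneric("lambdaHat", function(object) standardGeneric("lambdaHat"))

#' @rdname clusterTree-accessors
#' @export
setGeneric("leafLabels", function(object) standardGeneric("leafLabels"))

#' @rdname clusterTree-accessors
#' @export
setGeneric("nLeaves", function(object) standardGeneric("nLeaves"))
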