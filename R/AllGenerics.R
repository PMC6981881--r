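#' Accessors for cryptarget classes
#'
#' Slot accessors: duplex pairing strings and site sequences in either
#' orientation, miRNA id/sequence, read sets, free energies, and the node,
#' edge and graph views of a regulatory network.
#'
#' @name accessors
#' @param x an object of the documented class.
#' @return the corresponding slot contents.
NULL

#' @rdname weightedMismatch
#' @export
setGeneric("weightedMismatch",
           function(x, window = NULL, weights = mismatchWeights())
               standardGeneric("weightedMismatch"))

#' @rdname accessors
#' @export
setGeneric("pairingString", function(x) standardGeneric("pairingString"))

#' @rdname accessors
#' @export
setGeneric("siteSeq3to5", function(x) standardGeneric("siteSeq3to5"))

#' @rdname accessors
#' @export
setGeneric("siteSeq5to3", function(x) standardGeneric("siteSeq5to3"))

#' @rdname accessors
#' @export
setGeneric("mirnaId", function(x) standardGeneric("mirnaId"))

#' @rdname accessors
#' @export
setGeneric("mirnaSeq", function(x) standardGeneric("mirnaSeq"))

#' @rdname accessors
#' @export
setGeneric("reads", function(x) standardGeneric("reads"))

#' @rdname accessors
#' @export
setGeneric("deltaG", function(x) standardGeneric("deltaG"))

#' @rdname accessors
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
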