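#' Accessor generics
#'
#' Small accessor family for the core classes: \code{exprValues} returns the
#' numeric matrix, \code{geneIds}/\code{cellIds} its dimnames,
#' \code{geneKind} the gene kind, \code{isTransformed} the log-transform
#' flag, \code{pairFrame} a two-column data.frame of directed pairs,
#' \code{realCells} the identifiers of original (non-pseudo) cells and
#' \code{pseudoOrigin} the pseudo-cell -> real-cell copy map.
#'
#' @param x an object of one of the package's classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname accessors
#' @export
setGeneric("geneKind", function(x) standardGeneric("geneKind"))

#' @rdname accessors
#' @export
setGeneric("isTransformed", function(x) standardGeneric("isTransformed"))

#' @rdname accessors
#' @export
setGeneric("mirMatrix", function(x) standardGeneric("mirMatrix"))

#' @rdname accessors
#' @export
setGeneric("mrnaMatrix", function(x) standardGeneric("mrnaMatrix"))

#' @rdname accessors
#' @export
setGeneric("pairFrame", function(x) standardGeneric("pairFrame"))

#' @rdname accessors
#' @export
setGeneric("pairLabel", function(x) standardGeneric("pairLabel"))

#' @rdname accessors
#' @export
setGeneric("realCells", function(x) standardGeneric("realCells"))

#' @rdname accessors
#' @export
setGeneric("pseudoOrigin", function(x) standardGeneric("pseudoOrigin"))

#' @rdname accessors
#' @export
setGeneric("ensembleRuns", function(x) standardGeneric("ensembleRuns"))

#' Extract per-cell network edges
#'
#' Returns the significance-filtered edges of a \linkS4class{CellNetworkSet}
#' as a long-format data.frame with columns \code{cell}, \code{mirna},
#' \code{mrna}, \code{z}, \code{p}.
#'
#' @param x a \linkS4class{CellNetworkSet}.
#' @param cell optional cell identifier; when given, only that cell's edges
#'   are returned.
#' @export
setGeneric("networkEdges", function(x, cell = NULL)
    standardGeneric("networkEdges"))
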