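#' @import methods
NULL

#' ExpressionMatrix: a genes x cells expression matrix
#'
#' Thin S4 container for a single-cell expression matrix of one gene kind
#' (miRNA or mRNA). Row names are gene identifiers, column names are cell
#' identifiers. The \code{transformed} flag records whether values are on the
#' \code{log2(x + 1)} scale; it prevents the transform from being applied
#' twice during preprocessing.
#'
#' Duplicate gene identifiers are permitted only in untransformed (raw)
#' matrices, where they represent multiple assay rows for one symbol; they are
#' collapsed by \code{\link{preprocessMatched}}. Cell identifiers must always
#' be unique.
#'
#' @slot values numeric matrix, genes x cells, with complete dimnames.
#' @slot geneKind \code{"miRNA"} or \code{"mRNA"}.
#' @slot transformed logical scalar; \code{TRUE} once values are
#'   \code{log2(x + 1)}-transformed.
#'
#' @aliases ExpressionMatrix-class
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
    representation(values = "matrix", geneKind = "character",
                   transformed = "logical"),
    prototype(values = matrix(numeric(0), 0, 0), geneKind = "mRNA",
              transformed = FALSE))

setValidity("ExpressionMatrix", function(object) {
    v <- object@values
    msg <- character(0)
    if (!is.numeric(v))
        msg <- c(msg, "'values' must be a numeric matrix")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "'values' must have gene row names and cell column names")
    if (!is.null(colnames(v)) && anyDuplicated(colnames(v)))
        msg <- c(msg, "duplicate cell identifiers")
    if (length(object@geneKind) != 1L ||
        !object@geneKind %in% c("miRNA", "mRNA"))
        msg <- c(msg, "'geneKind' must be \"miRNA\" or \"mRNA\"")
    if (length(object@transformed) != 1L || is.na(object@transformed))
        msg <- c(msg, "'transformed' must be TRUE or FALSE")
    if (isTRUE(object@transformed)) {
        if (!is.null(rownames(v)) && anyDuplicated(rownames(v)))
            msg <- c(msg, "duplicate gene identifiers in a transformed matrix")
        if (length(v) && any(v < 0))
            msg <- c(msg, "negative values in a log2(x + 1)-transformed matrix")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix (genes x cells) with dimnames.
#' @param geneKind \code{"miRNA"} or \code{"mRNA"}.
#' @param transformed logical; are the values already on the log2(x+1) scale?
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
ExpressionMatrix <- function(values, geneKind = c("mRNA", "miRNA"),
                             transformed = FALSE) {
    geneKind <- match.arg(geneKind)
    new("ExpressionMatrix", values = as.matrix(values), geneKind = geneKind,
        transformed = transformed)
}

#' MatchedCoSeq: matched miRNA and mRNA profiles over one cell panel
#'
#' Holds a miRNA and an mRNA \linkS4class{ExpressionMatrix} that share a
#' single ordered cell panel, the entry point for all network inference.
#' Built by \code{\link{preprocessMatched}} (which also collapses duplicate
#' symbols, drops constant genes and applies the log transform).
#'
#' @slot mir \linkS4class{ExpressionMatrix} of kind miRNA.
#' @slot mrna \linkS4class{ExpressionMatrix} of kind mRNA.
#'
#' @aliases MatchedCoSeq-class
#' @exportClass MatchedCoSeq
setClass("MatchedCoSeq",
    representation(mir = "ExpressionMatrix", mrna = "ExpressionMatrix"))

setValidity("MatchedCoSeq", function(object) {
    msg <- character(0)
    if (object@mir@geneKind != "miRNA")
        msg <- c(msg, "'mir' must have geneKind \"miRNA\"")
    if (object@mrna@geneKind != "mRNA")
        msg <- c(msg, "'mrna' must have geneKind \"mRNA\"")
    if (!identical(colnames(object@mir@values), colnames(object@mrna@values)))
        msg <- c(msg, "miRNA and mRNA matrices must share one ordered cell panel")
    if (object@mir@transformed != object@mrna@transformed)
        msg <- c(msg, "'mir' and 'mrna' disagree on the transformed flag")
    if (length(msg)) msg else TRUE
})

#' Construct a MatchedCoSeq object
#'
#' @param mir,mrna \linkS4class{ExpressionMatrix} objects sharing the same
#'   ordered cell identifiers.
#' @return A \linkS4class{MatchedCoSeq}.
#' @export
MatchedCoSeq <- function(mir, mrna) new("MatchedCoSeq", mir = mir, mrna = mrna)

#' PairSet: a set of directed miRNA -> mRNA pairs
#'
#' Deduplicated directed pairs, used for the binding prior, validated
#' interaction references, disease-associated pairs and inferred edges.
#'
#' @slot mirna,mrna parallel character vectors; pair i is
#'   \code{mirna[i] -> mrna[i]}.
#' @slot label free-text provenance label (e.g. \code{"prior"}).
#'
#' @aliases PairSet-class
#' @exportClass PairSet
setClass("PairSet",
    representation(mirna = "character", mrna = "character",
                   label = "character"),
    prototype(mirna = character(0), mrna = character(0), label = ""))

setValidity("PairSet", function(object) {
    msg <- character(0)
    if (length(object@mirna) != length(object@mrna))
        msg <- c(msg, "'mirna' and 'mrna' must have equal length")
    else if (anyDuplicated(paste(object@mirna, object@mrna, sep = "\r")))
        msg <- c(msg, "duplicate pairs")
    if (length(object@label) != 1L)
        msg <- c(msg, "'label' must be a single string")
    if (length(msg)) msg else TRUE
})

#' Construct a PairSet
#'
#' Duplicate pairs in the input are dropped silently; use
#' \code{\link{readPairSet}} to get a report of dropped duplicates when
#' reading from disk.
#'
#' @param mirna,mrna character vectors of equal length.
#' @param label free-text label.
#' @return A \linkS4class{PairSet}.
#' @export
PairSet <- function(mirna = character(0), mrna = character(0), label = "") {
    mirna <- as.character(mirna); mrna <- as.character(mrna)
    if (length(mirna) != length(mrna))
        stop("'mirna' and 'mrna' must have equal length")
    key <- paste(mirna, mrna, sep = "\r")
    keep <- !duplicated(key)
    new("PairSet", mirna = mirna[keep], mrna = mrna[keep], label = label)
}

#' AugmentedSet: one pseudo-cell-augmented dataset
#'
#' A \linkS4class{MatchedCoSeq} enlarged by pseudo-cells, each an exact copy
#' of one real cell's matched miRNA/mRNA profile drawn uniformly with
#' replacement. Pseudo-cell columns interleave between the adjacent real
#' cells they were inserted between; the insertion slot is bookkeeping only.
#'
#' @slot data \linkS4class{MatchedCoSeq} containing real and pseudo cells.
#' @slot realCellIds ordered identifiers of the original cells.
#' @slot pseudoOrigin named character; for each pseudo-cell id, the real cell
#'   it copies.
#'
#' @aliases AugmentedSet-class
#' @exportClass AugmentedSet
setClass("AugmentedSet",
    representation(data = "MatchedCoSeq", realCellIds = "character",
                   pseudoOrigin = "character"))

setValidity("AugmentedSet", function(object) {
    cells <- colnames(object@data@mir@values)
    msg <- character(0)
    if (!all(object@realCellIds %in% cells))
        msg <- c(msg, "realCellIds missing from the augmented cell panel")
    if (length(object@pseudoOrigin)) {
        if (is.null(names(object@pseudoOrigin)) ||
            !all(names(object@pseudoOrigin) %in% cells))
            msg <- c(msg, "pseudoOrigin names must be augmented cell ids")
        if (!all(object@pseudoOrigin %in% object@realCellIds))
            msg <- c(msg, "pseudoOrigin values must be real cell ids")
    }
    if (length(cells) !=
        length(object@realCellIds) + length(object@pseudoOrigin))
        msg <- c(msg, "cell count must equal real + pseudo cells")
    if (length(msg)) msg else TRUE
})

#' BootstrapEnsemble: B augmented datasets from one seeded stream
#'
#' @slot runs list of \linkS4class{AugmentedSet}, length B.
#' @slot seed integer master seed.
#' @slot q integer, pseudo-cells inserted per adjacent real-cell pair.
#'
#' @aliases BootstrapEnsemble-class
#' @exportClass BootstrapEnsemble
setClass("BootstrapEnsemble",
    representation(runs = "list", seed = "integer", q = "integer"))

setValidity("BootstrapEnsemble", function(object) {
    msg <- character(0)
    if (!length(object@runs))
        msg <- c(msg, "ensemble must contain at least one run")
    if (!all(vapply(object@runs, is, logical(1), "AugmentedSet")))
        msg <- c(msg, "all runs must be AugmentedSet objects")
    else {
        ids <- lapply(object@runs, slot, "realCellIds")
        if (length(unique(ids)) != 1L)
            msg <- c(msg, "all runs must share identical real cell ids")
    }
    if (length(msg)) msg else TRUE
})

#' CellNetworkSet: per-cell bipartite miRNA-mRNA networks
#'
#' Result container of \code{\link{buildCellNetworks}}: for every tested
#' prior pair and every real cell, the bootstrap-median association z and its
#' upper-tail normal p-value, plus the significance-filtered edge list per
#' cell. Per-run z values are retained optionally (needed by
#' \code{\link{familyRegulationProfile}}).
#'
#' @slot pairs data.frame with columns \code{mirna}, \code{mrna}: the tested
#'   prior pairs (genes present in the data).
#' @slot realCellIds ordered real-cell identifiers.
#' @slot zFinal,pFinal numeric matrices, pairs x real cells.
#' @slot perRunZ numeric array pairs x cells x runs, or a 0-length array when
#'   not retained.
#' @slot alpha significance cutoff used for edge retention.
#'
#' @aliases CellNetworkSet-class
#' @exportClass CellNetworkSet
setClass("CellNetworkSet",
    representation(pairs = "data.frame", realCellIds = "character",
                   zFinal = "matrix", pFinal = "matrix", perRunZ = "array",
                   alpha = "numeric"))

setValidity("CellNetworkSet", function(object) {
    msg <- character(0)
    np <- nrow(object@pairs); m <- length(object@realCellIds)
    if (!all(c("mirna", "mrna") %in% colnames(object@pairs)))
        msg <- c(msg, "'pairs' needs columns mirna and mrna")
    if (!identical(dim(object@zFinal), c(np, m)) ||
        !identical(dim(object@pFinal), c(np, m)))
        msg <- c(msg, "zFinal/pFinal must be pairs x real cells")
    if (length(object@perRunZ) &&
        !identical(dim(object@perRunZ)[1:2], c(np, m)))
        msg <- c(msg, "perRunZ must be pairs x real cells x runs")
    if (object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "'alpha' must be in (0, 1)")
    if (length(msg)) msg else TRUE
})
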