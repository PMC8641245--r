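#' @rdname accessors
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @rdname accessors
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))

#' @rdname accessors
setMethod("cellIds", "ExpressionMatrix", function(x) colnames(x@values))

#' @rdname accessors
setMethod("geneKind", "ExpressionMatrix", function(x) x@geneKind)

#' @rdname accessors
setMethod("isTransformed", "ExpressionMatrix", function(x) x@transformed)

#' @rdname accessors
setMethod("mirMatrix", "MatchedCoSeq", function(x) x@mir)

#' @rdname accessors
setMethod("mrnaMatrix", "MatchedCoSeq", function(x) x@mrna)

#' @rdname accessors
setMethod("cellIds", "MatchedCoSeq", function(x) colnames(x@mir@values))

#' @rdname accessors
setMethod("isTransformed", "MatchedCoSeq", function(x) x@mir@transformed)

#' @rdname accessors
setMethod("pairFrame", "PairSet", function(x)
    data.frame(mirna = x@mirna, mrna = x@mrna, stringsAsFactors = FALSE))

#' @rdname accessors
setMethod("pairLabel", "PairSet", function(x) x@label)

#' @rdname accessors
setMethod("cellIds", "AugmentedSet", function(x) cellIds(x@data))

#' @rdname accessors
setMethod("realCells", "AugmentedSet", function(x) x@realCellIds)

#' @rdname accessors
setMethod("pseudoOrigin", "AugmentedSet", function(x) x@pseudoOrigin)

#' @rdname accessors
setMethod("ensembleRuns", "BootstrapEnsemble", function(x) x@runs)

#' @rdname accessors
setMethod("realCells", "BootstrapEnsemble", function(x)
    x@runs[[1L]]@realCellIds)

#' @rdname accessors
setMethod("realCells", "CellNetworkSet", function(x) x@realCellIds)

#' @rdname accessors
setMethod("pairFrame", "CellNetworkSet", function(x) x@pairs)

setMethod("length", "PairSet", function(x) length(x@mirna))

setMethod("length", "BootstrapEnsemble", function(x) length(x@runs))

#' @rdname networkEdges
setMethod("networkEdges", "CellNetworkSet", function(x, cell = NULL) {
    cells <- if (is.null(cell)) x@realCellIds else {
        if (!all(cell %in% x@realCellIds))
            stop("unknown cell id(s): ", paste(setdiff(cell, x@realCellIds),
                                               collapse = ", "))
        cell
    }
    out <- lapply(cells, function(cc) {
        keep <- which(x@pFinal[, cc] < x@alpha)
        if (!length(keep))
            return(data.frame(cell = character(0), mirna = character(0),
                              mrna = character(0), z = numeric(0),
                              p = numeric(0), stringsAsFactors = FALSE))
        data.frame(cell = cc, mirna = x@pairs$mirna[keep],
                   mrna = x@pairs$mrna[keep], z = x@zFinal[keep, cc],
                   p = x@pFinal[keep, cc], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
})

setMethod("show", "ExpressionMatrix", function(object) {
    v <- object@values
    cat(sprintf("ExpressionMatrix (%s): %d genes x %d cells, %s\n",
                object@geneKind, nrow(v), ncol(v),
                if (object@transformed) "log2(x+1) scale" else "raw scale"))
})

setMethod("show", "MatchedCoSeq", function(object) {
    cat(sprintf("MatchedCoSeq: %d miRNAs, %d mRNAs, %d cells (%s)\n",
                nrow(object@mir@values), nrow(object@mrna@values),
                ncol(object@mir@values),
                if (isTransformed(object)) "log2(x+1)" else "raw"))
})

setMethod("show", "PairSet", function(object) {
    cat(sprintf("PairSet '%s': %d miRNA->mRNA pairs\n", object@label,
                length(object@mirna)))
})

setMethod("show", "AugmentedSet", function(object) {
    cat(sprintf("AugmentedSet: %d real + %d pseudo cells\n",
                length(object@realCellIds), length(object@pseudoOrigin)))
})

setMethod("show", "BootstrapEnsemble", function(object) {
    cat(sprintf("BootstrapEnsemble: B = %d runs, q = %d, seed = %d\n",
                length(object@runs), object@q, object@seed))
})

setMethod("show", "CellNetworkSet", function(object) {
    ecount <- colSums(object@pFinal < object@alpha)
    cat(sprintf(
        "CellNetworkSet: %d tested pairs, %d cells, alpha = %g\n",
        nrow(object@pairs), length(object@realCellIds), object@alpha))
    cat(sprintf("  edges per cell: min %d, median %g, max %d\n",
                if (length(ecount)) min(ecount) else 0L,
                if (length(ecount)) stats::median(ecount) else 0,
                if (length(ecount)) max(ecount) else 0L))
    cat(sprintf("  per-run z retained: %s\n",
                if (length(object@perRunZ)) "yes" else "no"))
})
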