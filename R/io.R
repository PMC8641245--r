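#' Read a genes x cells expression table
#'
#' Parses a delimited text table whose first column holds gene symbols and
#' whose header row holds cell identifiers. Values are returned untouched
#' (raw scale); duplicate gene symbols are retained and later collapsed by
#' \code{\link{preprocessMatched}}.
#'
#' @param path path to a TSV/CSV file.
#' @param geneKind \code{"miRNA"} or \code{"mRNA"}.
#' @param sep field separator; default tab.
#' @return An \linkS4class{ExpressionMatrix} with \code{transformed = FALSE}.
#'   Duplicated symbols trigger a message naming them.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tc1\tc2", "miR-a\t1\t2", "miR-b\t0\t3"), f)
#' readExpressionMatrix(f, "miRNA")
#' @export
readExpressionMatrix <- function(path, geneKind = c("mRNA", "miRNA"),
                                 sep = "\t") {
    geneKind <- match.arg(geneKind)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) < 2L)
        stop("empty expression table (need a header and at least one gene): ",
             path)
    fields <- strsplit(lines, sep, fixed = TRUE)
    ncols <- lengths(fields)
    nexp <- ncols[2L]
    bad <- which(ncols[-1L] != nexp) + 1L
    if (length(bad))
        stop(sprintf("ragged table in %s: row %d has %d fields, expected %d",
                     path, bad[1L], ncols[bad[1L]], nexp))
    header <- fields[[1L]]
    # tolerate a header with or without a corner label for the gene column
    cells <- if (length(header) == nexp - 1L) header else if
        (length(header) == nexp) header[-1L] else
        stop(sprintf("ragged table in %s: header has %d fields, expected %d",
                     path, length(header), nexp))
    genes <- vapply(fields[-1L], `[[`, character(1), 1L)
    vals <- matrix(NA_real_, length(genes), length(cells),
                   dimnames = list(genes, cells))
    for (i in seq_along(genes)) {
        row <- fields[[i + 1L]][-1L]
        num <- suppressWarnings(as.numeric(row))
        if (anyNA(num)) {
            j <- which(is.na(num))[1L]
            stop(sprintf(
                "non-numeric value %s in %s at row %d (gene %s), column %d (cell %s)",
                dQuote(row[j]), path, i + 1L, genes[i], j + 1L, cells[j]))
        }
        vals[i, ] <- num
    }
    dup <- unique(genes[duplicated(genes)])
    if (length(dup))
        message(length(dup), " duplicated gene symbol(s) retained (",
                paste(utils::head(dup, 5L), collapse = ", "),
                if (length(dup) > 5L) ", ..." else "",
                "); preprocessMatched() averages them")
    ExpressionMatrix(vals, geneKind = geneKind, transformed = FALSE)
}

#' Write an ExpressionMatrix as TSV
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param path output path.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, sep = "\t") {
    stopifnot(is(x, "ExpressionMatrix"))
    df <- data.frame(gene = rownames(x@values), x@values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a two-column miRNA -> mRNA pair list
#'
#' Reads a delimited two-column file of directed pairs. A header row is
#' auto-detected with a documented dialect rule: if the first row's two
#' tokens occur nowhere else in their respective columns, the row is treated
#' as a header and skipped. Duplicate pairs are dropped with a report.
#'
#' @param path path to the file.
#' @param label free-text label stored on the \linkS4class{PairSet}.
#' @param sep field separator; default tab.
#' @return A \linkS4class{PairSet}. An empty file yields an empty set with a
#'   warning.
#' @export
readPairSet <- function(path, label = basename(path), sep = "\t") {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
        warning("empty pair list: ", path)
        return(PairSet(label = label))
    }
    fields <- strsplit(lines, sep, fixed = TRUE)
    bad <- which(lengths(fields) != 2L)
    if (length(bad))
        stop(sprintf("pair list %s: line %d has %d columns, expected 2",
                     path, bad[1L], lengths(fields)[bad[1L]]))
    a <- vapply(fields, `[[`, character(1), 1L)
    b <- vapply(fields, `[[`, character(1), 2L)
    if (length(a) > 1L && !a[1L] %in% a[-1L] && !b[1L] %in% b[-1L]) {
        a <- a[-1L]; b <- b[-1L]   # header row
    }
    ndup <- sum(duplicated(paste(a, b, sep = "\r")))
    if (ndup) message(ndup, " duplicate pair(s) dropped from ", path)
    PairSet(a, b, label = label)
}

#' Write a PairSet as two-column TSV
#'
#' @param x a \linkS4class{PairSet}.
#' @param path output path.
#' @param header write a header row?
#' @return \code{path}, invisibly.
#' @export
writePairSet <- function(x, path, header = TRUE) {
    stopifnot(is(x, "PairSet"))
    utils::write.table(pairFrame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = header)
    invisible(path)
}

#' Read a one-column gene list
#'
#' @param path path to a one-column text file (optional header ignored via
#'   the same dialect rule as \code{\link{readPairSet}}).
#' @return character vector of unique identifiers.
#' @export
readGeneList <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    ids <- readLines(path)
    ids <- trimws(ids[nzchar(ids)])
    if (length(ids) > 1L && !ids[1L] %in% ids[-1L] &&
        grepl("^(id|gene|mirna|mrna|symbol)s?$", ids[1L], ignore.case = TRUE))
        ids <- ids[-1L]
    unique(ids)
}

#' Preprocess matched raw miRNA/mRNA matrices
#'
#' Applies the standard preprocessing to a pair of raw expression matrices
#' over the same cells: (i) rows sharing a gene symbol are collapsed to the
#' mean of their raw values; (ii) genes whose standard deviation across all
#' cells is exactly zero are removed; (iii) remaining values are transformed
#' with \code{log2(x + 1)}. The miRNA file's column order is canonical; mRNA
#' columns are permuted to match. Averaging precedes the constant filter, so
#' a gene that becomes constant after averaging is removed.
#'
#' Matrices that are already transformed are passed through steps (i)-(ii)
#' without re-applying the log, which makes the operation idempotent.
#'
#' @param mirRaw,mrnaRaw \linkS4class{ExpressionMatrix} objects with the same
#'   cell set (order may differ).
#' @return A \linkS4class{MatchedCoSeq} with both matrices transformed.
#' @examples
#' m1 <- ExpressionMatrix(matrix(c(2, 4, 4, 6), 2, 2, byrow = TRUE,
#'         dimnames = list(c("miR-a", "miR-a"), c("c1", "c2"))), "miRNA")
#' m2 <- ExpressionMatrix(matrix(c(1, 3, 7, 7), 2, 2, byrow = TRUE,
#'         dimnames = list(c("g1", "g2"), c("c1", "c2"))), "mRNA")
#' preprocessMatched(m1, m2)   # miR-a averaged to (3, 5); constant g2 dropped
#' @export
preprocessMatched <- function(mirRaw, mrnaRaw) {
    stopifnot(is(mirRaw, "ExpressionMatrix"), is(mrnaRaw, "ExpressionMatrix"))
    c1 <- cellIds(mirRaw); c2 <- cellIds(mrnaRaw)
    if (!setequal(c1, c2)) {
        miss <- c(setdiff(c1, c2), setdiff(c2, c1))
        stop("miRNA and mRNA cell sets differ; mismatched cells: ",
             paste(miss, collapse = ", "))
    }
    mir <- .preprocessOne(mirRaw, cellOrder = c1)
    mrna <- .preprocessOne(mrnaRaw, cellOrder = c1)
    MatchedCoSeq(mir, mrna)
}

.preprocessOne <- function(x, cellOrder) {
    v <- x@values[, cellOrder, drop = FALSE]
    # collapse duplicate symbols by the mean of their raw rows
    if (anyDuplicated(rownames(v))) {
        g <- factor(rownames(v), levels = unique(rownames(v)))
        v <- rowsum(v, g) / as.vector(table(g))
        rownames(v) <- levels(g)
    }
    # constant-gene filter: exact sd == 0 across all cells
    sds <- apply(v, 1L, stats::sd)
    v <- v[sds != 0, , drop = FALSE]
    if (!nrow(v))
        stop("no variable genes: every ", x@geneKind,
             " is constant across cells")
    if (!x@transformed) v <- log2(v + 1)
    ExpressionMatrix(v, geneKind = x@geneKind, transformed = TRUE)
}
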