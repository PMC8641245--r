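#' Per-run association statistics for all prior pairs at all real cells
#'
#' Evaluates the cell-specific association statistic for every prior
#' miRNA-mRNA pair at every \emph{real} cell of one augmented dataset. The
#' box construction uses all \code{n} cells of the run (real plus pseudo),
#' but statistics are computed only at real focal cells, since only real
#' cells receive networks. Prior pairs referencing genes absent from the
#' matrices are skipped with a warning.
#'
#' @param run an \linkS4class{AugmentedSet}.
#' @param prior a \linkS4class{PairSet} of putative miRNA -> mRNA binding
#'   pairs.
#' @param boxFraction neighborhood occupancy fraction (default 0.1).
#' @return A list with \code{pairs} (data.frame of tested pairs), \code{z}
#'   (matrix pairs x real cells), and \code{nSkipped}.
#' @export
perRunStatistics <- function(run, prior, boxFraction = 0.1) {
    stopifnot(is(run, "AugmentedSet"), is(prior, "PairSet"))
    mirV <- exprValues(mirMatrix(run@data))
    mrnaV <- exprValues(mrnaMatrix(run@data))
    sel <- .matchPairs(prior, rownames(mirV), rownames(mrnaV))
    z <- .runZ(mirV, mrnaV, sel$ri, sel$ti, run@realCellIds, boxFraction)
    rownames(z) <- NULL
    list(pairs = data.frame(mirna = rownames(mirV)[sel$ri],
                            mrna = rownames(mrnaV)[sel$ti],
                            stringsAsFactors = FALSE),
         z = z, nSkipped = sel$nSkipped)
}

.matchPairs <- function(prior, mirIds, mrnaIds) {
    ri <- match(prior@mirna, mirIds)
    ti <- match(prior@mrna, mrnaIds)
    keep <- !is.na(ri) & !is.na(ti)
    nSkipped <- sum(!keep)
    if (nSkipped)
        warning(nSkipped, " prior pair(s) reference genes absent from the ",
                "data and were skipped")
    if (!any(keep))
        stop("no testable pairs: no prior pair matches the gene panels")
    list(ri = ri[keep], ti = ti[keep], nSkipped = nSkipped)
}

# z matrix (pairs x real cells) for one augmented run. Boxes are value
# windows (tie-inclusive), so per-gene occupancies vary; a box covering all
# n cells is locally uninformative and its pairs get z = 0.
.runZ <- function(mirV, mrnaV, ri, ti, realCellIds, boxFraction) {
    n <- ncol(mirV)
    nbox <- max(1L, as.integer(round(boxFraction * n)))
    if (nbox >= n)
        stop("degenerate box covers all cells; lower 'boxFraction'")
    mirUse <- sort(unique(ri)); mrnaUse <- sort(unique(ti))
    riPos <- match(ri, mirUse); tiPos <- match(ti, mrnaUse)
    kcols <- match(realCellIds, colnames(mirV))
    z <- matrix(NA_real_, length(ri), length(realCellIds),
                dimnames = list(NULL, realCellIds))
    for (j in seq_along(kcols)) {
        Mx <- .membershipAt(mirV[mirUse, , drop = FALSE], kcols[j], nbox)
        My <- .membershipAt(mrnaV[mrnaUse, , drop = FALSE], kcols[j], nbox)
        nrt <- crossprod(Mx, My)[cbind(riPos, tiPos)]
        nr <- colSums(Mx)[riPos]
        nt <- colSums(My)[tiPos]
        zj <- .zFromCounts(nrt, n, nr, nt)
        zj[nr == n | nt == n] <- 0
        z[, j] <- zj
    }
    z
}

#' Build cell-specific miRNA-mRNA networks from a bootstrap ensemble
#'
#' Runs the per-cell association test for every prior pair in every run of
#' the ensemble, aggregates each (pair, cell) over runs by the median of the
#' normalized statistic z, recomputes the one-sided p-value from the median
#' (\code{p = 1 - pnorm(median z)}), and retains an edge in a cell's network
#' iff \code{p < alpha} (strictly). Only real cells receive networks.
#'
#' @param ensemble a \linkS4class{BootstrapEnsemble}.
#' @param prior a \linkS4class{PairSet} of putative binding pairs.
#' @param alpha significance cutoff in (0, 1); default 0.01.
#' @param boxFraction neighborhood occupancy fraction; default 0.1.
#' @param keepPerRun retain the per-run z array (pairs x cells x runs)?
#'   Required by \code{\link{familyRegulationProfile}}; default TRUE.
#' @return A \linkS4class{CellNetworkSet}.
#' @examples
#' fx <- fixtureSmall()
#' ens <- bootstrapEnsemble(fx$data, q = 5, B = 5, seed = 7)
#' net <- buildCellNetworks(ens, fx$prior, alpha = 0.01)
#' head(networkEdges(net))
#' @export
buildCellNetworks <- function(ensemble, prior, alpha = 0.01,
                              boxFraction = 0.1, keepPerRun = TRUE) {
    stopifnot(is(ensemble, "BootstrapEnsemble"), is(prior, "PairSet"))
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
        stop("'alpha' must be a number in (0, 1)")
    runs <- ensemble@runs
    B <- length(runs)
    mirV <- exprValues(mirMatrix(runs[[1L]]@data))
    mrnaV <- exprValues(mrnaMatrix(runs[[1L]]@data))
    sel <- .matchPairs(prior, rownames(mirV), rownames(mrnaV))
    realIds <- runs[[1L]]@realCellIds
    zArr <- array(NA_real_, c(length(sel$ri), length(realIds), B))
    for (b in seq_len(B)) {
        d <- runs[[b]]@data
        zArr[, , b] <- .runZ(exprValues(mirMatrix(d)),
                             exprValues(mrnaMatrix(d)),
                             sel$ri, sel$ti, realIds, boxFraction)
    }
    zFinal <- apply(zArr, c(1L, 2L), stats::median)
    dimnames(zFinal) <- list(NULL, realIds)
    pFinal <- stats::pnorm(zFinal, lower.tail = FALSE)
    pairs <- data.frame(mirna = rownames(mirV)[sel$ri],
                        mrna = rownames(mrnaV)[sel$ti],
                        stringsAsFactors = FALSE)
    new("CellNetworkSet", pairs = pairs, realCellIds = realIds,
        zFinal = zFinal, pFinal = pFinal,
        perRunZ = if (keepPerRun) zArr else array(numeric(0), c(0L, 0L, 0L)),
        alpha = alpha)
}

#' Write per-cell network edge lists as TSV
#'
#' Writes one TSV per cell (columns mirna, mrna, z, p) plus a combined
#' long-format table \code{networks.tsv} (cell, mirna, mrna, z, p).
#'
#' @param x a \linkS4class{CellNetworkSet}.
#' @param dir output directory (created if missing).
#' @return the combined file path, invisibly.
#' @export
writeCellNetworks <- function(x, dir) {
    stopifnot(is(x, "CellNetworkSet"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    all <- networkEdges(x)
    for (cc in x@realCellIds) {
        sub <- all[all$cell == cc, c("mirna", "mrna", "z", "p")]
        utils::write.table(sub, file.path(dir, paste0("network_", cc, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    combined <- file.path(dir, "networks.tsv")
    utils::write.table(all, combined, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(combined)
}
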