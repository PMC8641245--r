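#' Hub miRNAs of one cell's network
#'
#' Ranks the miRNAs that have at least one target in the cell's network by
#' out-degree and returns the top \code{ceiling(fraction * count)} of them.
#' Ties at the cut are broken by lexicographic miRNA identifier so the
#' result is deterministic. A miRNA with no targets ("off" in that cell)
#' cannot be a hub.
#'
#' @param edges data.frame with at least a \code{mirna} column (one cell's
#'   retained edges, e.g. from \code{\link{networkEdges}}).
#' @param fraction top fraction of active miRNAs to keep (default 0.2).
#' @return character vector of hub miRNA ids (possibly empty, with a
#'   warning for an empty network).
#' @export
hubMirnas <- function(edges, fraction = 0.2) {
    if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
    if (!nrow(edges)) {
        warning("empty network: no hub miRNAs")
        return(character(0))
    }
    deg <- table(edges$mirna)
    ids <- names(deg)
    ord <- order(-as.vector(deg), ids)
    ids[ord][seq_len(ceiling(fraction * length(ids)))]
}

# per-cell hub sets for a CellNetworkSet
.hubsByCell <- function(net, fraction = 0.2) {
    all <- networkEdges(net)
    stats::setNames(lapply(net@realCellIds, function(cc) {
        sub <- all[all$cell == cc, , drop = FALSE]
        if (!nrow(sub)) character(0)
        else hubMirnas(sub, fraction)
    }), net@realCellIds)
}

# per-cell edge key sets
.edgesByCell <- function(net) {
    all <- networkEdges(net)
    key <- paste(all$mirna, all$mrna, sep = "\r")
    stats::setNames(lapply(net@realCellIds, function(cc) key[all$cell == cc]),
                    net@realCellIds)
}

#' Conserved and rewired miRNA regulation across cells
#'
#' An interaction (or hub miRNA) is "on" in a cell when it appears in that
#' cell's network (or hub set). Items on in at least
#' \code{conservedMinCells} cells are conserved; items on in exactly one
#' cell are rewired; everything in between belongs to neither set. The
#' default threshold is \code{ceiling(0.9 * m)} cells (17 of 19), a high
#' conservation level.
#'
#' @param net a \linkS4class{CellNetworkSet}.
#' @param conservedMinCells integer threshold; default \code{ceiling(0.9*m)}.
#' @param hubFraction fraction for per-cell hub selection (default 0.2).
#' @return A list with \code{conservedEdges}, \code{rewiredEdges}
#'   (\linkS4class{PairSet}s), \code{conservedHubs}, \code{rewiredHubs}
#'   (character vectors), and the presence-count tables \code{edgeCounts},
#'   \code{hubCounts}.
#' @export
conservedAndRewired <- function(net,
                                conservedMinCells =
                                    ceiling(0.9 * length(realCells(net))),
                                hubFraction = 0.2) {
    stopifnot(is(net, "CellNetworkSet"))
    m <- length(net@realCellIds)
    if (conservedMinCells > m)
        stop("'conservedMinCells' cannot exceed the number of cells")
    edgeCounts <- table(unlist(.edgesByCell(net), use.names = FALSE))
    hubCounts <- table(unlist(.hubsByCell(net, hubFraction),
                              use.names = FALSE))
    splitKey <- function(keys) {
        parts <- strsplit(keys, "\r", fixed = TRUE)
        PairSet(vapply(parts, `[[`, character(1), 1L),
                vapply(parts, `[[`, character(1), 2L))
    }
    consE <- names(edgeCounts)[edgeCounts >= conservedMinCells]
    rewE <- names(edgeCounts)[edgeCounts == 1L]
    list(conservedEdges = splitKey(consE),
         rewiredEdges = splitKey(rewE),
         conservedHubs = sort(names(hubCounts)[hubCounts >= conservedMinCells]),
         rewiredHubs = sort(names(hubCounts)[hubCounts == 1L]),
         edgeCounts = edgeCounts, hubCounts = hubCounts)
}

#' Overlap similarity between two term sets
#'
#' \code{|intersect(a, b)| / min(|a|, |b|)}, the overlap coefficient used
#' for both interaction similarity and hub-miRNA similarity between two
#' cells. Returns 0 (with a warning) when either set is empty.
#'
#' @param a,b vectors of items (edge keys or miRNA ids).
#' @return a number in [0, 1].
#' @export
pairwiseSimilarity <- function(a, b) {
    if (!length(a) || !length(b)) {
        warning("empty term set: similarity set to 0")
        return(0)
    }
    length(intersect(a, b)) / min(length(unique(a)), length(unique(b)))
}

#' Cell-cell similarity matrix from per-cell networks
#'
#' Computes the m x m matrix of overlap similarities between the cells'
#' miRNA-mRNA interaction sets (\code{mode = "interaction"}) or hub-miRNA
#' sets (\code{mode = "hub"}).
#'
#' @param net a \linkS4class{CellNetworkSet}.
#' @param mode \code{"interaction"} or \code{"hub"}.
#' @param hubFraction hub selection fraction for \code{mode = "hub"}.
#' @return symmetric numeric matrix with cell ids as dimnames; the diagonal
#'   is 1 for cells with a nonempty term set.
#' @export
similarityMatrix <- function(net, mode = c("interaction", "hub"),
                             hubFraction = 0.2) {
    mode <- match.arg(mode)
    terms <- if (mode == "interaction") .edgesByCell(net)
             else .hubsByCell(net, hubFraction)
    .termSimilarity(terms)
}

.termSimilarity <- function(terms) {
    ids <- names(terms)
    m <- length(ids)
    sim <- matrix(0, m, m, dimnames = list(ids, ids))
    for (i in seq_len(m)) for (j in i:m) {
        s <- if (!length(terms[[i]]) || !length(terms[[j]])) 0
             else length(intersect(terms[[i]], terms[[j]])) /
                  min(length(terms[[i]]), length(terms[[j]]))
        sim[i, j] <- sim[j, i] <- s
    }
    sim
}

#' Normalized Euclidean expression distance between cells
#'
#' Stacks the miRNA and mRNA matrices into one gene dimension, computes the
#' Euclidean distance between every pair of cells over all genes, and
#' min-max-normalizes the distances to [0, 1] using the off-diagonal range
#' (the structural diagonal zeros are excluded so they do not pin the
#' minimum).
#'
#' @param data a \linkS4class{MatchedCoSeq}.
#' @return list with \code{raw} and \code{normalized} symmetric matrices.
#' @export
expressionDistanceMatrix <- function(data) {
    stopifnot(is(data, "MatchedCoSeq"))
    v <- rbind(exprValues(mirMatrix(data)), exprValues(mrnaMatrix(data)))
    if (ncol(v) < 2L) stop("need at least 2 cells")
    raw <- as.matrix(stats::dist(t(v)))
    off <- raw[upper.tri(raw)]
    rng <- range(off)
    if (rng[1L] == rng[2L])
        stop("zero distance range: all off-diagonal distances are equal")
    normalized <- (raw - rng[1L]) / (rng[2L] - rng[1L])
    diag(normalized) <- 0
    list(raw = raw, normalized = normalized)
}

#' Hierarchical clustering of cells
#'
#' Agglomerative clustering of cells from a similarity or distance matrix.
#' Similarity inputs (detected by a unit diagonal, or forced with
#' \code{similarity = TRUE}) are converted to dissimilarity \code{1 - sim}.
#'
#' @param mat symmetric matrix with cell-id dimnames.
#' @param nClusters number of clusters to cut the dendrogram into.
#' @param linkage \code{"average"} (default), \code{"single"} or
#'   \code{"complete"}.
#' @param similarity logical; \code{NULL} (default) auto-detects.
#' @return list with \code{labels} (named integer vector) and \code{tree}
#'   (the \code{hclust} merge record).
#' @export
hierarchicalClustering <- function(mat, nClusters,
                                   linkage = c("average", "single",
                                               "complete"),
                                   similarity = NULL) {
    linkage <- match.arg(linkage)
    m <- nrow(mat)
    if (nClusters < 1L || nClusters > m)
        stop("'nClusters' must be between 1 and the number of cells")
    if (is.null(similarity))
        similarity <- all(abs(diag(mat) - 1) < 1e-12) && all(mat <= 1 + 1e-12)
    d <- if (similarity) 1 - mat else mat
    diag(d) <- 0
    tree <- stats::hclust(stats::as.dist(d), method = linkage)
    labels <- stats::cutree(tree, k = nClusters)
    list(labels = labels, tree = tree)
}

#' Cell-cell crosstalk network from a similarity matrix
#'
#' Two cells have a crosstalk relationship when their similarity is
#' strictly larger than the median of all m(m-1)/2 pairwise (off-diagonal)
#' similarities.
#'
#' @param sim symmetric similarity matrix with cell-id dimnames.
#' @return list with \code{cells}, \code{edges} (data.frame \code{i},
#'   \code{j}), and \code{threshold} (the median).
#' @export
crosstalkNetwork <- function(sim) {
    m <- nrow(sim)
    if (m < 2L) stop("need at least 2 cells")
    ut <- which(upper.tri(sim), arr.ind = TRUE)
    vals <- sim[ut]
    threshold <- stats::median(vals)
    keep <- vals > threshold
    list(cells = rownames(sim),
         edges = data.frame(i = rownames(sim)[ut[keep, 1L]],
                            j = colnames(sim)[ut[keep, 2L]],
                            similarity = vals[keep],
                            stringsAsFactors = FALSE),
         threshold = threshold)
}

#' Hub cells of a crosstalk network
#'
#' Top \code{ceiling(fraction * count)} cells by degree among cells with
#' degree at least 1; ties at the cut are broken lexicographically.
#'
#' @param ct a crosstalk network from \code{\link{crosstalkNetwork}}.
#' @param fraction top fraction (default 0.2).
#' @return character vector of hub cell ids.
#' @export
hubCells <- function(ct, fraction = 0.2) {
    if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
    deg <- table(c(ct$edges$i, ct$edges$j))
    if (!length(deg)) {
        warning("edgeless crosstalk network: no hub cells")
        return(character(0))
    }
    ids <- names(deg)
    ord <- order(-as.vector(deg), ids)
    ids[ord][seq_len(ceiling(fraction * length(ids)))]
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' \code{D} is the supremum distance between the two empirical CDFs and the
#' p-value comes from the asymptotic two-sample KS distribution.
#'
#' @param a,b nonempty numeric samples.
#' @return list with \code{D} and \code{p}.
#' @export
ksTwoSample <- function(a, b) {
    if (!length(a) || !length(b)) stop("both samples must be nonempty")
    kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Per-run regulation profile of a miRNA family
#'
#' For each real cell and each bootstrap run, counts the targets of a miRNA
#' family called at the per-run level (per-run \code{p < alpha}) and the
#' percentage of those targets found in a validated reference and in a
#' disease-associated pair list. The resulting per-cell distributions over
#' runs feed pairwise \code{\link{ksTwoSample}} comparisons. Family members
#' absent from the tested pairs are skipped with a warning.
#'
#' @param net a \linkS4class{CellNetworkSet} built with
#'   \code{keepPerRun = TRUE}.
#' @param family character vector of family miRNA ids.
#' @param validated,diseasePairs optional \linkS4class{PairSet}s.
#' @param alpha per-run call cutoff; defaults to the set's alpha.
#' @return data.frame with columns \code{cell}, \code{run}, \code{nTargets},
#'   \code{pctValidated}, \code{pctDisease} (percentages in [0, 100]; NA
#'   when a cell/run has no called family targets).
#' @export
familyRegulationProfile <- function(net, family, validated = NULL,
                                    diseasePairs = NULL, alpha = net@alpha) {
    stopifnot(is(net, "CellNetworkSet"))
    if (!length(net@perRunZ))
        stop("per-run z values not retained; rerun buildCellNetworks() ",
             "with keepPerRun = TRUE")
    present <- family %in% net@pairs$mirna
    if (!any(present)) {
        warning("no family member present among the tested pairs")
        return(data.frame(cell = character(0), run = integer(0),
                          nTargets = integer(0), pctValidated = numeric(0),
                          pctDisease = numeric(0)))
    }
    if (any(!present))
        warning("family member(s) absent from the tested pairs: ",
                paste(family[!present], collapse = ", "))
    fIdx <- which(net@pairs$mirna %in% family)
    key <- paste(net@pairs$mirna, net@pairs$mrna, sep = "\r")[fIdx]
    inVal <- if (is.null(validated)) rep(FALSE, length(fIdx))
             else key %in% paste(validated@mirna, validated@mrna, sep = "\r")
    inDis <- if (is.null(diseasePairs)) rep(FALSE, length(fIdx))
             else key %in% paste(diseasePairs@mirna, diseasePairs@mrna,
                                 sep = "\r")
    B <- dim(net@perRunZ)[3L]
    cells <- net@realCellIds
    out <- expand.grid(cell = cells, run = seq_len(B),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out$nTargets <- 0L; out$pctValidated <- NA_real_
    out$pctDisease <- NA_real_
    row <- 0L
    for (b in seq_len(B)) for (ci in seq_along(cells)) {
        row <- which(out$cell == cells[ci] & out$run == b)
        p <- stats::pnorm(net@perRunZ[fIdx, ci, b], lower.tail = FALSE)
        called <- p < alpha
        nT <- sum(called)
        out$nTargets[row] <- nT
        if (nT > 0L) {
            out$pctValidated[row] <- 100 * sum(inVal[called]) / nT
            out$pctDisease[row] <- 100 * sum(inDis[called]) / nT
        }
    }
    out
}

#' Evaluate per-cell networks against a reference pair set
#'
#' For each real cell, the percentage of its edges found in a reference set
#' of interactions, alongside a permutation baseline: the mean validated
#' percentage over \code{nRandom} networks of the same size drawn uniformly
#' without replacement from the tested prior pair space.
#'
#' @param net a \linkS4class{CellNetworkSet}.
#' @param reference a \linkS4class{PairSet} of validated interactions.
#' @param nRandom number of random networks per cell (default 100).
#' @param seed integer seed for the random draws.
#' @return data.frame with columns \code{cell}, \code{nEdges},
#'   \code{validatedPct}, \code{randomPct} (NA when a cell has no edges).
#' @export
evaluateAgainstReference <- function(net, reference, nRandom = 100L,
                                     seed = 42L) {
    stopifnot(is(net, "CellNetworkSet"), is(reference, "PairSet"))
    if (nRandom < 1L) stop("'nRandom' must be at least 1")
    refKey <- paste(reference@mirna, reference@mrna, sep = "\r")
    priorKey <- paste(net@pairs$mirna, net@pairs$mrna, sep = "\r")
    priorInRef <- priorKey %in% refKey
    byCell <- .edgesByCell(net)
    withr::with_seed(as.integer(seed), {
        rows <- lapply(net@realCellIds, function(cc) {
            ed <- byCell[[cc]]
            nE <- length(ed)
            if (!nE)
                return(data.frame(cell = cc, nEdges = 0L,
                                  validatedPct = NA_real_,
                                  randomPct = NA_real_))
            vp <- 100 * sum(ed %in% refKey) / nE
            rp <- mean(vapply(seq_len(nRandom), function(i) {
                100 * sum(priorInRef[sample.int(length(priorKey), nE)]) / nE
            }, numeric(1)))
            data.frame(cell = cc, nEdges = nE, validatedPct = vp,
                       randomPct = rp)
        })
        out <- do.call(rbind, rows)
        rownames(out) <- NULL
        out
    })
}
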