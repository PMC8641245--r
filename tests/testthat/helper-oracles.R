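# Independent oracles and small fixture builders shared across test files.
# Each oracle is written as a separate, naive code path from the package
# implementation it checks.

# genes x cells ExpressionMatrix from a plain matrix
em <- function(values, kind = "mRNA", transformed = TRUE,
               genes = NULL, cells = NULL) {
    if (!is.null(genes)) rownames(values) <- genes
    if (!is.null(cells)) colnames(values) <- cells
    if (is.null(rownames(values)))
        rownames(values) <- paste0(ifelse(kind == "miRNA", "miR-", "G"),
                                   seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- paste0("c", seq_len(ncol(values)))
    ExpressionMatrix(values, kind, transformed = transformed)
}

# small matched dataset with given matrices (already log-scale)
matched <- function(mirValues, mrnaValues) {
    cells <- paste0("c", seq_len(ncol(mirValues)))
    MatchedCoSeq(em(mirValues, "miRNA", cells = cells),
                 em(mrnaValues, "mRNA", cells = cells))
}

# brute-force box builder: walk cells in order of |value - value[k]| and
# keep taking cells while fewer than nbox collected or the distance ties
# the last accepted one
oracleBox <- function(vals, k, nbox) {
    d <- abs(vals - vals[k])
    ord <- order(d)
    taken <- ord[1]
    for (i in 2:length(vals)) {
        if (length(taken) < nbox || d[ord[i]] == d[taken[length(taken)]])
            taken <- c(taken, ord[i])
        else break
    }
    sort(taken)
}
# (members in ascending index order, matching neighborhoodCounts)

# exhaustive maximal-biclique enumeration over all miRNA subsets
oracleBicliques <- function(pairs, minMirnas, minMrnas) {
    mirs <- sort(unique(pairs$mirna))
    key <- paste(pairs$mirna, pairs$mrna)
    targetsOf <- function(A) {
        ts <- sort(unique(pairs$mrna))
        ts[vapply(ts, function(t) all(paste(A, t) %in% key), logical(1))]
    }
    out <- list()
    for (bits in seq_len(2^length(mirs) - 1L)) {
        A <- mirs[as.logical(bitwAnd(bits, 2^(seq_along(mirs) - 1L)))]
        B <- targetsOf(A)
        if (!length(B)) next
        # maximal iff no further miRNA targets all of B
        ext <- setdiff(mirs, A)
        closed <- !any(vapply(ext, function(m)
            all(paste(m, B) %in% key), logical(1)))
        if (closed && length(A) >= minMirnas && length(B) >= minMrnas)
            out[[paste(A, collapse = " ")]] <- list(mirnas = A, mrnas = B)
    }
    unname(out[order(names(out))])
}

# independent Markov clustering: explicit stochastic-matrix iteration with
# attractor-row cluster extraction
oracleMcl <- function(adj, inflation = 2, iter = 200) {
    diag(adj) <- 1
    M <- apply(adj, 2, function(col) col / sum(col))
    for (i in seq_len(iter)) {
        M <- M %*% M
        M <- M^inflation
        M <- apply(M, 2, function(col) col / sum(col))
        M[M < 1e-14] <- 0
    }
    attractors <- which(diag(M) > 1e-6)
    clusters <- lapply(attractors, function(a)
        sort(rownames(adj)[which(M[a, ] > 1e-6 | seq_len(ncol(M)) == a)]))
    unique(clusters)
}

# canonical string form of a module list, for set comparison
moduleKey <- function(mods) {
    sort(vapply(mods, function(m)
        paste(paste(sort(m$mirnas), collapse = ","),
              paste(sort(m$mrnas), collapse = ","), sep = "|"),
        character(1)))
}

# mean per-cell AUC of planted pairs over decoys, ranked by zFinal
meanPlantedAuc <- function(net, truth) {
    key <- paste(net@pairs$mirna, net@pairs$mrna)
    isTrue <- key %in% paste(truth@mirna, truth@mrna)
    stopifnot(any(isTrue), any(!isTrue))
    n1 <- sum(isTrue); n0 <- sum(!isTrue)
    mean(vapply(realCells(net), function(cc) {
        r <- rank(net@zFinal[, cc])
        (sum(r[isTrue]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }, numeric(1)))
}
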