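#' Markov clustering of a crosstalk network
#'
#' Standard Markov Cluster algorithm on the unweighted adjacency matrix
#' with self-loops: columns are normalized to a stochastic matrix, then
#' expansion (matrix squaring) and inflation (elementwise power followed by
#' column renormalization) are iterated until the matrix changes by less
#' than \code{tol} (max absolute entry change) or \code{maxIter} iterations.
#' Clusters are read off the steady-state matrix as connected components of
#' its nonzero support; modules smaller than \code{minSize} cells are
#' discarded. Isolated cells form singleton clusters and are removed by any
#' \code{minSize > 1}.
#'
#' @param ct a crosstalk network (list with \code{cells} and \code{edges})
#'   from \code{\link{crosstalkNetwork}}, or a symmetric 0/1 adjacency
#'   matrix with dimnames.
#' @param inflation inflation exponent, > 1 (default 2).
#' @param minSize minimum cells per reported module (default 3).
#' @param maxIter iteration cap (default 100).
#' @param tol convergence tolerance on the max entry change (default 1e-6).
#' @return list with \code{modules} (list of sorted cell-id vectors) and
#'   \code{converged}; a warning is raised when the cap is hit.
#' @export
mclModules <- function(ct, inflation = 2, minSize = 3L, maxIter = 100L,
                       tol = 1e-6) {
    if (inflation <= 1) stop("'inflation' must be > 1")
    if (minSize < 1L) stop("'minSize' must be at least 1")
    if (is.matrix(ct)) {
        adj <- (ct != 0) * 1
        cells <- rownames(adj)
    } else {
        cells <- ct$cells
        adj <- matrix(0, length(cells), length(cells),
                      dimnames = list(cells, cells))
        if (nrow(ct$edges)) {
            adj[cbind(ct$edges$i, ct$edges$j)] <- 1
            adj[cbind(ct$edges$j, ct$edges$i)] <- 1
        }
    }
    diag(adj) <- 1
    M <- sweep(adj, 2L, colSums(adj), "/")
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        Mnew <- M %*% M                       # expansion
        Mnew <- Mnew^inflation                # inflation
        Mnew[Mnew < 1e-12] <- 0               # prune
        Mnew <- sweep(Mnew, 2L, colSums(Mnew), "/")
        if (max(abs(Mnew - M)) < tol) {
            M <- Mnew
            converged <- TRUE
            break
        }
        M <- Mnew
    }
    if (!converged)
        warning("MCL did not converge within ", maxIter,
                " iterations; interpreting the current matrix")
    support <- (M > 1e-6) | t(M > 1e-6)
    comp <- .components(support)
    modules <- split(cells, comp)
    modules <- lapply(modules, sort)
    modules <- modules[vapply(modules, length, integer(1)) >= minSize]
    names(modules) <- NULL
    list(modules = modules[order(vapply(modules, `[`, character(1), 1L))],
         converged = converged)
}

# connected components of a logical adjacency matrix (BFS)
.components <- function(adj) {
    n <- nrow(adj)
    comp <- rep(NA_integer_, n)
    cur <- 0L
    for (s in seq_len(n)) {
        if (!is.na(comp[s])) next
        cur <- cur + 1L
        queue <- s
        comp[s] <- cur
        while (length(queue)) {
            v <- queue[1L]; queue <- queue[-1L]
            nb <- which(adj[v, ] & is.na(comp))
            comp[nb] <- cur
            queue <- c(queue, nb)
        }
    }
    comp
}
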