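#' Enumerate maximal miRNA-mRNA bicliques
#'
#' Finds every maximal complete-bipartite subgraph (biclique) of a bipartite
#' miRNA -> mRNA edge set: a pair of sets (A of miRNAs, B of mRNAs) such
#' that every miRNA in A targets every mRNA in B, and neither side can be
#' extended without breaking completeness. Enumeration uses the Galois
#' (closure) correspondence: each maximal biclique's miRNA side is an
#' intersection of mRNA neighborhoods, so the intersection closure of the
#' neighborhood family is computed and each closed set paired with its
#' common-target set. Output is filtered to modules with at least
#' \code{minMirnas} miRNAs and \code{minMrnas} mRNAs (defaults 2 and 3) and
#' sorted deterministically by miRNA set, then mRNA set.
#'
#' @param pairs a \linkS4class{PairSet} (or data.frame with \code{mirna},
#'   \code{mrna} columns) of edges.
#' @param minMirnas,minMrnas minimum side sizes (defaults 2 and 3).
#' @return list of modules, each a list with sorted character vectors
#'   \code{mirnas} and \code{mrnas}; empty list for an empty edge set.
#' @examples
#' ps <- PairSet(rep(c("m1", "m2"), each = 3), rep(c("g1", "g2", "g3"), 2))
#' maximalBicliques(ps)   # the K_{2,3} itself
#' @export
maximalBicliques <- function(pairs, minMirnas = 2L, minMrnas = 3L) {
    if (is(pairs, "PairSet")) pairs <- pairFrame(pairs)
    if (minMirnas < 1L || minMrnas < 1L)
        stop("minimum side sizes must be at least 1")
    if (!nrow(pairs)) return(list())
    nb <- lapply(split(pairs$mirna, pairs$mrna), unique)   # mRNA -> miRNAs
    base <- unique(lapply(nb, sort))
    closure <- new.env(parent = emptyenv())
    for (s in base) assign(paste(s, collapse = "\r"), s, envir = closure)
    queue <- base
    while (length(queue)) {
        nxt <- list()
        for (a in queue) for (b in base) {
            s <- intersect(a, b)
            if (!length(s)) next
            k <- paste(s, collapse = "\r")
            if (!exists(k, envir = closure, inherits = FALSE)) {
                assign(k, s, envir = closure)
                nxt[[length(nxt) + 1L]] <- s
            }
        }
        queue <- nxt
    }
    mods <- lapply(ls(closure), function(k) {
        A <- get(k, envir = closure)
        B <- sort(names(nb)[vapply(nb, function(x) all(A %in% x),
                                   logical(1))])
        list(mirnas = A, mrnas = B)
    })
    mods <- Filter(function(m) length(m$mirnas) >= minMirnas &&
                                length(m$mrnas) >= minMrnas, mods)
    ord <- order(vapply(mods, function(m) paste(m$mirnas, collapse = "\r"),
                        character(1)),
                 vapply(mods, function(m) paste(m$mrnas, collapse = "\r"),
                        character(1)))
    mods[ord]
}
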