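#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least \code{s} disease genes in a module of
#' \code{M} genes drawn from a background of \code{N} genes of which
#' \code{Q} are disease-associated:
#' \deqn{p = 1 - \sum_{x=0}^{s-1} \binom{Q}{x}\binom{N-Q}{M-x} / \binom{N}{M}.}
#' Computed with the exact hypergeometric distribution function
#' (\code{phyper}), so infeasible terms contribute zero and the evaluation
#' is numerically stable.
#'
#' @param N background gene count (miRNAs + mRNAs expressed in the data).
#' @param Q disease-associated genes in the background.
#' @param M genes in the module.
#' @param s disease-associated genes in the module.
#' @return the p-value; \code{s = 0} gives 1 (empty sum).
#' @examples
#' hypergeomEnrichment(10, 5, 4, 3)   # 55/210
#' @export
hypergeomEnrichment <- function(N, Q, M, s) {
    if (any(c(N, Q, M, s) < 0) || s > M || M > N || Q > N)
        stop("require 0 <= s <= M <= N and 0 <= Q <= N")
    stats::phyper(s - 1, Q, N - Q, M, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, order-preserving and capped at
#' 1. Input values must be probabilities.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
    if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))
        stop("all p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Disease enrichment of biclique modules
#'
#' Tests each miRNA-mRNA module for enrichment in a disease gene set with
#' the upper-tail hypergeometric test against a background of all genes
#' surviving preprocessing, and adjusts across modules with
#' Benjamini-Hochberg.
#'
#' @param modules list of modules from \code{\link{maximalBicliques}}.
#' @param diseaseGenes character vector of disease-associated gene ids
#'   (miRNAs and/or mRNAs).
#' @param background character vector of all background gene ids.
#' @return data.frame with one row per module: \code{nMirnas},
#'   \code{nMrnas}, \code{N}, \code{Q}, \code{M}, \code{s}, \code{p},
#'   \code{pAdjusted}.
#' @export
enrichModules <- function(modules, diseaseGenes, background) {
    background <- unique(background)
    diseaseGenes <- unique(diseaseGenes)
    N <- length(background)
    Q <- sum(diseaseGenes %in% background)
    rows <- lapply(modules, function(mod) {
        genes <- unique(c(mod$mirnas, mod$mrnas))
        M <- length(genes)
        s <- sum(genes %in% diseaseGenes & genes %in% background)
        data.frame(nMirnas = length(mod$mirnas), nMrnas = length(mod$mrnas),
                   N = N, Q = Q, M = M, s = s,
                   p = hypergeomEnrichment(N, Q, M, s))
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(nMirnas = integer(0), nMrnas = integer(0),
                          N = integer(0), Q = integer(0), M = integer(0),
                          s = integer(0), p = numeric(0),
                          pAdjusted = numeric(0)))
    out$pAdjusted <- bhAdjust(out$p)
    rownames(out) <- NULL
    out
}
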