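#' Specification for a synthetic matched co-sequencing dataset
#'
#' Bundles the generator parameters with their defaults, which describe a
#' small half-cell-style study: 19 cells, 50 miRNAs, 300 mRNAs, 20 planted
#' miRNA-mRNA couplings inside a 2,000-pair binding prior, coupling
#' strength 0.9 and 30\% dropout.
#'
#' @param nMirnas,nMrnas,nCells panel sizes.
#' @param nTruePairs number of planted (truly coupled) miRNA-mRNA pairs.
#' @param nPriorPairs total prior size (true pairs plus uniform decoys).
#' @param coupling coupling strength in [0, 1]: the weight of the monotone
#'   miRNA-driven component in each true target's profile.
#' @param dropout fraction in [0, 1) of each gene's measurements lost to
#'   technical dropout, modeled as censoring below the gene's detection
#'   limit (its \code{dropout} expression quantile).
#' @param couplingSign +1 for coactivation-style monotone increasing
#'   coupling (default), -1 for repression-style decreasing coupling.
#' @param nBlocks number of planted cell subpopulations (default 1).
#' @param seed integer seed; the dataset is a deterministic function of the
#'   full spec.
#' @return list of class \code{"syntheticSpec"}.
#' @export
syntheticSpec <- function(nMirnas = 50L, nMrnas = 300L, nCells = 19L,
                          nTruePairs = 20L, nPriorPairs = 2000L,
                          coupling = 0.9, dropout = 0.3, couplingSign = 1,
                          nBlocks = 1L, seed = 42L) {
    spec <- list(nMirnas = as.integer(nMirnas), nMrnas = as.integer(nMrnas),
                 nCells = as.integer(nCells),
                 nTruePairs = as.integer(nTruePairs),
                 nPriorPairs = as.integer(nPriorPairs),
                 coupling = coupling, dropout = dropout,
                 couplingSign = sign(couplingSign), nBlocks = as.integer(nBlocks),
                 seed = as.integer(seed))
    if (spec$nTruePairs > spec$nMirnas * spec$nMrnas)
        stop("more true pairs than miRNA x mRNA combinations")
    if (spec$nPriorPairs < spec$nTruePairs ||
        spec$nPriorPairs > spec$nMirnas * spec$nMrnas)
        stop("'nPriorPairs' must lie between nTruePairs and the number of ",
             "combinations")
    if (spec$coupling < 0 || spec$coupling > 1)
        stop("'coupling' must be in [0, 1]")
    if (spec$dropout < 0 || spec$dropout >= 1)
        stop("'dropout' must be in [0, 1)")
    if (spec$nBlocks < 1L || spec$nBlocks > spec$nCells)
        stop("'nBlocks' must be between 1 and nCells")
    if (spec$couplingSign == 0) stop("'couplingSign' must be +1 or -1")
    structure(spec, class = "syntheticSpec")
}

#' Generate a synthetic matched dataset with planted ground truth
#'
#' Emulates log-scale single-cell co-sequencing data: per block, each gene's
#' log2 expression is normal around a gene-specific (and, with several
#' blocks, block-shifted) mean, truncated at zero. For each planted true
#' pair, the target mRNA profile is rebuilt as a \code{coupling}-weighted
#' mixture of a monotone function of its miRNA's profile and independent
#' noise, rescaled to the gene's original location and spread. Dropout is
#' modeled as detection-limit censoring: per gene, values at or below the
#' gene's \code{dropout} quantile read as zero, mimicking the preferential
#' loss of low-abundance transcripts in real protocols. The binding prior
#' is the union of the true pairs and uniformly drawn decoy pairs.
#'
#' Raw-scale matrices (\code{2^v - 1}) are built and passed through
#' \code{\link{preprocessMatched}}, so the returned data went through the
#' same averaging/filter/log pipeline as real input files.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list of class \code{"syntheticDataset"} with elements
#'   \code{data} (\linkS4class{MatchedCoSeq}), \code{prior}, \code{truth}
#'   (\linkS4class{PairSet}s, truth a subset of prior), \code{blockLabels}
#'   (named integer vector) and \code{spec}.
#' @export
generateSynthetic <- function(spec) {
    stopifnot(inherits(spec, "syntheticSpec"))
    withr::with_seed(spec$seed, .generateSynthetic(spec))
}

.generateSynthetic <- function(spec) {
    mirIds <- sprintf("miR-%03d", seq_len(spec$nMirnas))
    mrnaIds <- sprintf("GENE%04d", seq_len(spec$nMrnas))
    cells <- sprintf("cell_%02d", seq_len(spec$nCells))
    blocks <- stats::setNames(
        rep(seq_len(spec$nBlocks), length.out = spec$nCells), cells)

    simPanel <- function(ids) {
        mu <- stats::rnorm(length(ids), mean = 5, sd = 1.5)
        shift <- if (spec$nBlocks > 1L)
            matrix(stats::rnorm(length(ids) * spec$nBlocks, 0, 1),
                   length(ids), spec$nBlocks)
        else matrix(0, length(ids), 1L)
        v <- matrix(0, length(ids), spec$nCells,
                    dimnames = list(ids, cells))
        for (ci in seq_len(spec$nCells))
            v[, ci] <- mu + shift[, blocks[ci]] +
                stats::rnorm(length(ids), 0, 1)
        pmax(v, 0)
    }
    mirV <- simPanel(mirIds)
    mrnaV <- simPanel(mrnaIds)

    # planted couplings: distinct mRNA targets so profiles are not rebuilt
    # twice; miRNA regulators drawn with replacement
    tMrna <- sample.int(spec$nMrnas, spec$nTruePairs)
    tMir <- sample.int(spec$nMirnas, spec$nTruePairs, replace = TRUE)
    for (i in seq_len(spec$nTruePairs)) {
        r <- mirV[tMir[i], ]
        drive <- spec$couplingSign * r          # monotone driver
        drive <- if (stats::sd(drive) > 0) as.vector(scale(drive))
                 else drive * 0
        mixed <- spec$coupling * drive +
            (1 - spec$coupling) * stats::rnorm(spec$nCells)
        g <- mrnaV[tMrna[i], ]
        sdg <- stats::sd(g)
        if (sdg == 0) sdg <- 1
        if (stats::sd(mixed) > 0) mixed <- as.vector(scale(mixed))
        mrnaV[tMrna[i], ] <- pmax(mean(g) + sdg * mixed, 0)
    }

    if (spec$dropout > 0) {
        mirV <- .applyDropout(mirV, spec$dropout)
        mrnaV <- .applyDropout(mrnaV, spec$dropout)
    }

    truth <- PairSet(mirIds[tMir], mrnaIds[tMrna], label = "truth")
    # decoys drawn uniformly from the non-true combinations
    allIdx <- seq_len(spec$nMirnas * spec$nMrnas)
    trueIdx <- (tMrna - 1L) * spec$nMirnas + tMir
    nDecoy <- spec$nPriorPairs - length(truth)
    decoyIdx <- sample(setdiff(allIdx, trueIdx), nDecoy)
    dMir <- ((decoyIdx - 1L) %% spec$nMirnas) + 1L
    dMrna <- ((decoyIdx - 1L) %/% spec$nMirnas) + 1L
    prior <- PairSet(c(truth@mirna, mirIds[dMir]),
                     c(truth@mrna, mrnaIds[dMrna]), label = "prior")

    data <- preprocessMatched(
        ExpressionMatrix(pmax(2^mirV - 1, 0), "miRNA"),
        ExpressionMatrix(pmax(2^mrnaV - 1, 0), "mRNA"))
    structure(list(data = data, prior = prior, truth = truth,
                   blockLabels = blocks, spec = spec),
              class = "syntheticDataset")
}

# Dropout as detection-limit censoring: per gene, the `rate` quantile of the
# log2 values acts as the detection limit and every measurement at or below
# it reads as zero, so roughly round(rate * n) entries per gene are lost and
# low-abundance measurements are lost preferentially, as in real single-cell
# protocols. Equal values are censored together (a detection limit cannot
# split a tie). See the vignette for what this model does and does not
# emulate.
.applyDropout <- function(v, rate) {
    n <- ncol(v)
    nd <- round(rate * n)
    if (nd < 1L) return(v)
    for (g in seq_len(nrow(v))) {
        limit <- sort(v[g, ], partial = nd)[nd]
        v[g, v[g, ] <= limit] <- 0
    }
    v
}

#' Packaged small synthetic fixture
#'
#' Deterministic dataset sized like a small half-cell study (19 cells, 50
#' miRNAs, 300 mRNAs, 20 planted pairs among a 2,000-pair prior), used by
#' the test suite and documentation examples.
#'
#' @param seed integer seed (default 42).
#' @return a \code{"syntheticDataset"} list; see
#'   \code{\link{generateSynthetic}}.
#' @export
fixtureSmall <- function(seed = 42L) {
    generateSynthetic(syntheticSpec(seed = seed))
}

#' @export
print.syntheticDataset <- function(x, ...) {
    cat(sprintf(
        "syntheticDataset: %d cells, %d planted pairs in a %d-pair prior\n",
        length(cellIds(x$data)), length(x$truth), length(x$prior)))
    invisible(x)
}
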