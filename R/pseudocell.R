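#' Interpolate pseudo-cells into a small matched dataset
#'
#' Enlarges a matched single-cell dataset by inserting \code{q} pseudo-cells
#' between every pair of cells that are adjacent in the canonical cell order.
#' Each pseudo-cell is an exact copy of one real cell's full matched
#' miRNA/mRNA profile, drawn uniformly with replacement from \emph{all} real
#' cells, so the marginal distribution of every gene and the joint
#' distribution of every miRNA-mRNA pair are unchanged. No expression values
#' are interpolated: "interpolation" refers to column insertion only, and
#' the insertion slot is recorded but has no computational effect (the
#' association statistic is order-free).
#'
#' With \code{m} real cells the augmented dataset has
#' \code{m + (m - 1) * q} cells; 19 cells at the default \code{q = 5} give
#' 109.
#'
#' @param data a \linkS4class{MatchedCoSeq}.
#' @param q non-negative integer, pseudo-cells per adjacent pair.
#' @param seed optional integer; when given, sampling runs under this seed
#'   without disturbing the caller's RNG state.
#' @return An \linkS4class{AugmentedSet}.
#' @examples
#' d <- fixtureSmall()$data
#' aug <- interpolatePseudoCells(d, q = 5, seed = 1)
#' length(cellIds(aug))   # 109
#' @export
interpolatePseudoCells <- function(data, q = 5L, seed = NULL) {
    stopifnot(is(data, "MatchedCoSeq"))
    q <- as.integer(q)
    if (is.na(q) || q < 0L) stop("'q' must be a non-negative integer")
    cells <- cellIds(data)
    m <- length(cells)
    if (q > 0L && m < 2L)
        stop("need at least 2 cells to interpolate between adjacent pairs")
    if (q == 0L)
        return(new("AugmentedSet", data = data, realCellIds = cells,
                   pseudoOrigin = stats::setNames(character(0), character(0))))
    draw <- function() sample.int(m, (m - 1L) * q, replace = TRUE)
    origIdx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    .assembleAugmented(data, origIdx, q)
}

# origIdx: ((m-1)*q) indices of real cells copied into the pseudo slots,
# ordered gap by gap
.assembleAugmented <- function(data, origIdx, q) {
    cells <- cellIds(data)
    m <- length(cells)
    # column layout: real_1, gap_1 pseudo (q), real_2, gap_2 pseudo, ..., real_m
    order <- integer(0)        # index into c(real, pseudo-draw) layout
    pseudoIds <- character((m - 1L) * q)
    slot <- 0L
    for (i in seq_len(m - 1L)) {
        order <- c(order, i)
        for (j in seq_len(q)) {
            slot <- slot + 1L
            pseudoIds[slot] <- sprintf("pseudo_%02d_%02d", i, j)
            order <- c(order, m + slot)
        }
    }
    order <- c(order, m)
    origin <- stats::setNames(cells[origIdx], pseudoIds)
    ids <- c(cells, pseudoIds)[order]
    colIdx <- c(seq_len(m), origIdx)[order]
    mirV <- exprValues(mirMatrix(data))[, colIdx, drop = FALSE]
    mrnaV <- exprValues(mrnaMatrix(data))[, colIdx, drop = FALSE]
    colnames(mirV) <- colnames(mrnaV) <- ids
    aug <- MatchedCoSeq(
        ExpressionMatrix(mirV, "miRNA", transformed = isTransformed(data)),
        ExpressionMatrix(mrnaV, "mRNA", transformed = isTransformed(data)))
    new("AugmentedSet", data = aug, realCellIds = cells,
        pseudoOrigin = origin)
}

#' Build a bootstrap ensemble of augmented datasets
#'
#' Produces \code{B} independently resampled \linkS4class{AugmentedSet}s
#' from a single seeded stream. All runs share the same real cells and gene
#' panels; only the pseudo-cell origin draws differ. The whole ensemble is a
#' deterministic function of \code{(data, q, B, seed)}.
#'
#' @param data a \linkS4class{MatchedCoSeq}.
#' @param q pseudo-cells per adjacent pair (default 5).
#' @param B number of bootstrap runs (default 100).
#' @param seed integer master seed (default 42).
#' @return A \linkS4class{BootstrapEnsemble}.
#' @export
bootstrapEnsemble <- function(data, q = 5L, B = 100L, seed = 42L) {
    stopifnot(is(data, "MatchedCoSeq"))
    B <- as.integer(B); q <- as.integer(q); seed <- as.integer(seed)
    if (is.na(B) || B < 1L) stop("'B' must be a positive integer")
    m <- length(cellIds(data))
    if (q > 0L && m < 2L)
        stop("need at least 2 cells to interpolate between adjacent pairs")
    ndraw <- (m - 1L) * q
    draws <- withr::with_seed(seed, {
        if (ndraw > 0L)
            matrix(sample.int(m, ndraw * B, replace = TRUE), ndraw, B)
        else matrix(integer(0), 0L, B)
    })
    runs <- lapply(seq_len(B), function(b) {
        if (q == 0L) interpolatePseudoCells(data, 0L)
        else .assembleAugmented(data, draws[, b], q)
    })
    new("BootstrapEnsemble", runs = runs, seed = seed, q = q)
}
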