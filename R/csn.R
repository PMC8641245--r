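#' Neighborhood box membership and occupancy counts for one cell
#'
#' For a focal cell \code{k} in the scatter of a miRNA's expression \code{x}
#' against an mRNA's expression \code{y}, the cell-specific association
#' statistic counts cells inside three boxes: a box around \code{x[k]} on
#' the miRNA axis (\code{n_r} cells), a box around \code{y[k]} on the mRNA
#' axis (\code{n_t} cells), and their intersection (\code{n_rt} cells).
#'
#' Each box is a value window: it contains the \code{round(boxFraction * n)}
#' cells nearest to the focal value (at least 1), \emph{expanded to include
#' every cell tied with the boundary distance}, so cells with equal
#' expression are in or out together. For continuous (tie-free) data the box
#' holds exactly \code{round(boxFraction * n)} cells; under the heavy ties
#' of dropout zeros and duplicated pseudo-cell profiles it grows to cover
#' whole tie groups, which keeps the marginal box probability \code{n_r/n}
#' honest instead of slicing tie groups by an arbitrary cell order. The
#' focal cell is always a member of all three boxes.
#'
#' @param x,y numeric vectors of equal length n (expression of one miRNA and
#'   one mRNA across all cells of a dataset).
#' @param k focal cell index (1-based).
#' @param boxFraction minimum box occupancy as a fraction of n (default 0.1).
#' @return A list of class \code{"neighborhoodCounts"} with elements
#'   \code{n}, \code{nr}, \code{nt}, \code{nrt} and the box member indices
#'   \code{rBox}, \code{tBox}.
#' @seealso \code{\link{csnStatistic}}
#' @examples
#' x <- c(0, 1, 2, 3, 9); y <- c(9, 3, 2, 1, 0)
#' neighborhoodCounts(x, y, k = 3, boxFraction = 0.6)
#' @export
neighborhoodCounts <- function(x, y, k, boxFraction = 0.1) {
    n <- length(x)
    if (length(y) != n)
        stop("'x' and 'y' must have the same length")
    if (length(k) != 1L || is.na(k) || k < 1L || k > n)
        stop("focal cell index 'k' out of range [1, ", n, "]")
    if (boxFraction <= 0 || boxFraction > 1)
        stop("'boxFraction' must be in (0, 1]")
    nbox <- max(1L, as.integer(round(boxFraction * n)))
    rBox <- .boxMembers(x, k, nbox)
    tBox <- .boxMembers(y, k, nbox)
    structure(list(n = n, nr = length(rBox), nt = length(tBox),
                   nrt = length(intersect(rBox, tBox)),
                   rBox = rBox, tBox = tBox),
              class = "neighborhoodCounts")
}

# cells within the value window around vals[k]: the nbox nearest by
# |difference| plus all cells tied with the boundary distance
.boxMembers <- function(vals, k, nbox) {
    d <- abs(vals - vals[k])
    thr <- sort(d, partial = nbox)[nbox]
    which(d <= thr)
}

#' @export
print.neighborhoodCounts <- function(x, ...) {
    cat(sprintf("neighborhood counts: n = %d, nr = %d, nt = %d, nrt = %d\n",
                x$n, x$nr, x$nt, x$nrt))
    invisible(x)
}

#' Cell-specific association statistic and its significance
#'
#' Computes the neighborhood co-occupancy statistic
#' \deqn{\rho = n_{rt}/n - (n_r/n)(n_t/n)}
#' and its normalized form
#' \deqn{z = \sqrt{n-1}\,(n\,n_{rt} - n_r n_t) /
#'           \sqrt{n_r n_t (n-n_r)(n-n_t)},}
#' which under independence of the two genes approximately follows a
#' standard normal distribution; the one-sided upper-tail p-value is
#' \code{1 - pnorm(z)}. A large positive z means the focal cell's
#' neighborhoods on the two expression axes share more cells than expected
#' under independence, i.e. the miRNA and mRNA co-vary locally around that
#' cell.
#'
#' Note the normal approximation ignores that the focal cell is itself a
#' member of all three boxes, which induces a positive bias of order
#' \code{9/sqrt(n)} in z under the null; see the package vignette for the
#' calibration consequences.
#'
#' @param counts a \code{"neighborhoodCounts"} list from
#'   \code{\link{neighborhoodCounts}}, or \code{NULL} when the four counts
#'   are given directly.
#' @param n,nr,nt,nrt the counts (total cells, miRNA-axis box, mRNA-axis
#'   box, intersection); ignored when \code{counts} is given.
#' @return A list with \code{rho}, \code{z} and \code{p}.
#' @examples
#' csnStatistic(n = 100, nr = 10, nt = 10, nrt = 4)  # rho 0.03, z sqrt(11)
#' @export
csnStatistic <- function(counts = NULL, n, nr, nt, nrt) {
    if (!is.null(counts)) {
        n <- counts$n; nr <- counts$nr; nt <- counts$nt; nrt <- counts$nrt
    }
    if (n < 2L) stop("need at least 2 cells")
    if (nr < 1L || nt < 1L || nr > n || nt > n || nrt < 0L ||
        nrt > min(nr, nt))
        stop("invalid neighborhood counts")
    if (nr == n || nt == n)
        stop("degenerate box covers all cells (sigma undefined)")
    rho <- nrt / n - (nr / n) * (nt / n)
    z <- .zFromCounts(nrt, n, nr, nt)
    list(rho = rho, z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

# vectorized over all arguments
.zFromCounts <- function(nrt, n, nr, nt) {
    sqrt(n - 1) * (n * nrt - nr * nt) / sqrt(nr * nt * (n - nr) * (n - nt))
}

# Box membership for all genes of a matrix at one focal column.
# vals: genes x cells; returns cells x genes logical matrix. A box that
# would cover all n cells (a gene whose values are one big tie group around
# the focal value) carries no local information; it is kept as-is here and
# mapped to z = 0 by the caller.
.membershipAt <- function(vals, k, nbox) {
    n <- ncol(vals)
    out <- matrix(FALSE, n, nrow(vals))
    for (g in seq_len(nrow(vals))) {
        d <- abs(vals[g, ] - vals[g, k])
        thr <- sort(d, partial = nbox)[nbox]
        out[d <= thr, g] <- TRUE
    }
    out
}
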