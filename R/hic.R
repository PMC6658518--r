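## Contact-enrichment calling on binned Hi-C matrices: distance-stratified
## expected counts, observed/expected enrichment, Poisson significance, FDR.

.checkContactMatrix <- function(m) {
    if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 2)
        stop("contact matrix must be square with >= 2 bins")
    if (any(m < 0)) stop("contact counts must be non-negative")
    if (!isTRUE(all.equal(unname(m), unname(t(m)))))
        stop("contact matrix must be symmetric")
    invisible(m)
}

#' Distance-stratified expected contact counts
#'
#' The expected count at bin separation d is the mean observed count over
#' all bin pairs at that separation — the simplest expected model for a
#' small region, standing in for spline-based genome-wide fits.
#'
#' @param m symmetric count matrix (e.g. from [simulateContactMatrix()] or
#'   [readContactTable()]).
#' @return data.frame `distance` (bins, 0 .. n-1), `expected`, `nPairs`.
#' @export
expectedByDistance <- function(m) {
    .checkContactMatrix(m)
    n <- nrow(m)
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    up <- upper.tri(m, diag = TRUE)
    data.frame(distance = 0:(n - 1),
               expected = vapply(0:(n - 1), function(dd)
                   mean(m[up & d == dd]), numeric(1)),
               nPairs = vapply(0:(n - 1), function(dd)
                   sum(up & d == dd), integer(1)))
}

#' Call enriched contact pairs
#'
#' For every bin pair at separation >= `minDistanceBins` (the diagonal is
#' excluded by default; self-ligation dominates it), computes enrichment =
#' observed / expected(distance), an upper-tail Poisson p-value
#' `P(X >= obs | lambda = expected)`, and Benjamini-Hochberg FDR over all
#' tested pairs. When a distance stratum has expected 0, a pseudocount of
#' 0.5 replaces the expected value so scores stay finite (flagged in the
#' output).
#'
#' @param m symmetric count matrix.
#' @param fdrThreshold hotspot threshold on the FDR.
#' @param minDistanceBins minimum bin separation tested.
#' @return List with `records` (data.frame `binI`, `binJ`, `observed`,
#'   `expected`, `enrichment`, `p`, `fdr`, `pseudocount`) and `hotspots`
#'   (the subset with `fdr < fdrThreshold`).
#' @export
callEnrichment <- function(m, fdrThreshold = 0.05, minDistanceBins = 1L) {
    .checkContactMatrix(m)
    n <- nrow(m)
    exp_ <- expectedByDistance(m)
    idx <- which(upper.tri(m), arr.ind = TRUE)
    d <- idx[, 2] - idx[, 1]
    keep <- d >= minDistanceBins
    idx <- idx[keep, , drop = FALSE]; d <- d[keep]
    lambda <- exp_$expected[match(d, exp_$distance)]
    pseudo <- lambda == 0
    lambda[pseudo] <- 0.5
    obs <- m[idx]
    rec <- data.frame(binI = idx[, 1], binJ = idx[, 2], observed = obs,
                      expected = lambda, enrichment = obs / lambda,
                      p = stats::ppois(obs - 1, lambda, lower.tail = FALSE),
                      pseudocount = pseudo)
    rec$fdr <- stats::p.adjust(rec$p, method = "BH")
    rec <- rec[order(rec$p), , drop = FALSE]
    rownames(rec) <- NULL
    list(records = rec,
         hotspots = rec[rec$fdr < fdrThreshold, , drop = FALSE])
}

#' Read / write binned contact tables
#'
#' `readContactTable` turns a TSV of `bin_i, bin_j, count` triples (bin
#' starts in bp or 1-based bin indices) into a dense symmetric matrix;
#' `writeContactTable` is its inverse for the upper triangle.
#'
#' @param path TSV path with columns `bin_i`, `bin_j`, `count`.
#' @param binSize bin size in bp; when bins are given as coordinates they
#'   are converted to indices with this size.
#' @return `readContactTable`: symmetric integer matrix with `binSize` and
#'   `binStarts` attributes. `writeContactTable`: `path`, invisibly.
#' @export
readContactTable <- function(path, binSize = 10000L) {
    tab <- utils::read.delim(path)
    stopifnot(all(c("bin_i", "bin_j", "count") %in% names(tab)))
    coords <- max(tab$bin_i, tab$bin_j) > 1e6 || any(tab$bin_i %% 1 != 0)
    lo <- min(tab$bin_i, tab$bin_j)
    toIdx <- function(b) if (coords) (b - lo) %/% binSize + 1L else as.integer(b)
    i <- toIdx(tab$bin_i); j <- toIdx(tab$bin_j)
    n <- max(i, j)
    m <- matrix(0L, n, n)
    m[cbind(i, j)] <- as.integer(tab$count)
    m[cbind(j, i)] <- as.integer(tab$count)
    structure(m, binSize = as.integer(binSize),
              binStarts = if (coords) lo + (seq_len(n) - 1L) * binSize
                          else seq_len(n))
}

#' @rdname readContactTable
#' @param m symmetric contact matrix.
#' @export
writeContactTable <- function(m, path, binSize = attr(m, "binSize")) {
    .checkContactMatrix(m)
    starts <- attr(m, "binStarts")
    if (is.null(starts)) starts <- seq_len(nrow(m))
    idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
    utils::write.table(
        data.frame(bin_i = starts[idx[, 1]], bin_j = starts[idx[, 2]],
                   count = m[idx]),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
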