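## Preprocessing: log2 transform then full-quantile normalization, in that
## order (transform first, normalize the transformed values).

.get_exprs <- function(x) {
    if (is(x, "SummarizedExperiment")) assay(x, 1L) else x
}

.set_exprs <- function(x, mat) {
    if (is(x, "SummarizedExperiment")) {
        assays(x)[[1L]] <- mat
        x
    } else mat
}

#' Log2-transform an expression matrix
#'
#' Each non-missing value v becomes log2(v + pseudocount); missing values
#' stay missing.  Strictly monotone per cell.
#'
#' @param x numeric matrix (or a \code{SummarizedExperiment}; the first
#'   assay is transformed in place).
#' @param pseudocount non-negative offset added before the log; with the
#'   default 0, any non-positive value is an error.
#' @return Same container as \code{x}, log2 scale.
#' @examples
#' log2Transform(matrix(c(8, 2), 1), pseudocount = 0)
#' @export
log2Transform <- function(x, pseudocount = 0) {
    mat <- .get_exprs(x)
    shifted <- mat + pseudocount
    bad <- which(!is.na(shifted) & shifted <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
        rn <- rownames(mat)[bad[1L, 1L]]
        cn <- colnames(mat)[bad[1L, 2L]]
        stop(sprintf(
            "non-positive value %g at [%s, %s]; use a pseudocount > 0",
            mat[bad[1L, 1L], bad[1L, 2L]],
            if (is.null(rn)) bad[1L, 1L] else rn,
            if (is.null(cn)) bad[1L, 2L] else cn))
    }
    .set_exprs(x, log2(shifted))
}

#' Drop probes with any missing value
#'
#' Quantile normalization requires a complete matrix; this removes
#' incomplete probes and reports how many were dropped.
#'
#' @param x matrix or \code{SummarizedExperiment}.
#' @param quiet suppress the message.
#' @return Filtered object; the number dropped is attached as attribute
#'   \code{"n_dropped"} (metadata field \code{n_dropped_incomplete} for a
#'   \code{SummarizedExperiment}).
#' @export
dropIncompleteProbes <- function(x, quiet = FALSE) {
    mat <- .get_exprs(x)
    keep <- rowSums(is.na(mat)) == 0L
    n_drop <- sum(!keep)
    if (!quiet && n_drop > 0L)
        message(sprintf("dropping %d probe(s) with missing values", n_drop))
    out <- x[keep, , drop = FALSE]
    if (is(out, "SummarizedExperiment"))
        metadata(out)$n_dropped_incomplete <- n_drop
    else attr(out, "n_dropped") <- n_drop
    out
}

#' Full-quantile normalization
#'
#' Forces every sample column to share the identical empirical
#' distribution -- the across-column mean of order statistics -- while
#' preserving within-column ranks.  Ties within a column receive the mean
#' of the tied order-statistic means, which makes the operation
#' deterministic and idempotent.  Delegates to
#' \code{limma::normalizeQuantiles(ties = TRUE)}.
#'
#' @param x complete numeric matrix (or \code{SummarizedExperiment});
#'   missing values are an error -- filter with [dropIncompleteProbes()]
#'   first.
#' @return Same container, quantile-normalized.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(6, 4, 5))
#' quantileNormalize(m)
#' @export
quantileNormalize <- function(x) {
    mat <- .get_exprs(x)
    if (anyNA(mat))
        stop(paste("matrix has missing values; drop or impute first",
                   "(see dropIncompleteProbes)"))
    norm <- limma::normalizeQuantiles(mat, ties = TRUE)
    dimnames(norm) <- dimnames(mat)
    .set_exprs(x, norm)
}

#' Largest Kolmogorov distance between sample columns
#'
#' Diagnostic for normalization: after [quantileNormalize()] every pair of
#' columns has identical sorted values, so the distance is exactly 0.
#'
#' @param x matrix or \code{SummarizedExperiment}.
#' @return Max over column pairs of the sup-distance between empirical
#'   distributions, computed from sorted columns.
#' @export
maxColumnKolmogorov <- function(x) {
    mat <- .get_exprs(x)
    s <- apply(mat, 2L, sort)
    ref <- s[, 1L]
    n <- nrow(s)
    max(vapply(seq_len(ncol(s)), function(j) {
        grid <- sort(unique(c(ref, s[, j])))
        f1 <- findInterval(grid, ref) / n
        f2 <- findInterval(grid, s[, j]) / n
        max(abs(f1 - f2))
    }, numeric(1)))
}
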