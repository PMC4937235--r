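## Step 1: per-probe two-group class comparison with fold-change, t-test
## and presence filters.

#' Per-probe two-group t-test with fold changes
#'
#' Computes, for every probe, group means on the log2 scale, the log2 fold
#' change (group A minus group B), the signed linear fold change, and a
#' two-sided t statistic/p-value under either the pooled-variance
#' (classic two-sample) or Welch model.  Probes with fewer than two
#' non-missing values in either group are flagged untestable rather than
#' dropped; their t and p are \code{NA}.
#'
#' Degenerate variance is resolved deterministically: zero pooled standard
#' error with a zero mean difference gives t = 0, p = 1; with a non-zero
#' difference it gives t = +/-Inf, p = 0.
#'
#' @param x log2 expression matrix (probes x samples) or a cohort
#'   \code{SummarizedExperiment}.
#' @param group_a,group_b disjoint character vectors of sample ids.
#' @param variance_mode \code{"pooled"} (default) or \code{"welch"}.
#' @param map optional probe-to-gene named vector used to annotate
#'   records (taken from \code{rowData} when \code{x} is a
#'   \code{SummarizedExperiment}).
#' @return A [S4Vectors::DataFrame] with one row per probe: columns
#'   \code{probe_id}, \code{gene_symbol}, \code{mean_a}, \code{mean_b},
#'   \code{log2fc}, \code{fold_change}, \code{t_stat}, \code{p_value},
#'   \code{n_a}, \code{n_b}, \code{present_frac}, \code{testable}.
#' @examples
#' m <- rbind(p1 = c(5, 5.1, 4.9, 3, 3.1, 2.9))
#' colnames(m) <- c("a1", "a2", "a3", "b1", "b2", "b3")
#' twoGroupTTest(m, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
#' @export
twoGroupTTest <- function(x, group_a, group_b,
                          variance_mode = c("pooled", "welch"),
                          map = NULL) {
    variance_mode <- match.arg(variance_mode)
    if (is(x, "SummarizedExperiment") && is.null(map))
        map <- setNames(rowData(x)$gene_symbol, rownames(x))
    mat <- .get_exprs(x)
    if (length(intersect(group_a, group_b)))
        stop("groups overlap: ",
             paste(intersect(group_a, group_b), collapse = ", "))
    miss <- setdiff(c(group_a, group_b), colnames(mat))
    if (length(miss))
        stop("sample(s) not in matrix: ", paste(miss, collapse = ", "))
    A <- mat[, group_a, drop = FALSE]
    B <- mat[, group_b, drop = FALSE]

    n_a <- rowSums(!is.na(A))
    n_b <- rowSums(!is.na(B))
    mean_a <- rowMeans(A, na.rm = TRUE)
    mean_b <- rowMeans(B, na.rm = TRUE)
    va <- rowSums((A - mean_a)^2, na.rm = TRUE) / pmax(n_a - 1L, 1L)
    vb <- rowSums((B - mean_b)^2, na.rm = TRUE) / pmax(n_b - 1L, 1L)
    diff <- mean_a - mean_b
    testable <- n_a >= 2L & n_b >= 2L

    if (variance_mode == "pooled") {
        df <- n_a + n_b - 2L
        sp2 <- ((n_a - 1L) * va + (n_b - 1L) * vb) / df
        se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    } else {
        sa <- va / n_a
        sb <- vb / n_b
        se <- sqrt(sa + sb)
        df <- (sa + sb)^2 / (sa^2 / (n_a - 1L) + sb^2 / (n_b - 1L))
    }
    t_stat <- diff / se
    t_stat[se == 0 & diff == 0] <- 0
    p <- 2 * pt(-abs(t_stat), df)
    p[se == 0 & diff == 0] <- 1
    p[se == 0 & diff != 0] <- 0
    t_stat[!testable] <- NA_real_
    p[!testable] <- NA_real_

    probe_ids <- rownames(mat)
    genes <- if (is.null(map)) NA_character_ else unname(map[probe_ids])
    DataFrame(
        probe_id = probe_ids,
        gene_symbol = genes,
        mean_a = unname(mean_a), mean_b = unname(mean_b),
        log2fc = unname(diff),
        fold_change = unname(sign(diff) * 2^abs(diff)),
        t_stat = unname(t_stat), p_value = unname(p),
        n_a = unname(n_a), n_b = unname(n_b),
        present_frac = unname((n_a + n_b) /
                              (length(group_a) + length(group_b))),
        testable = unname(testable),
        row.names = probe_ids)
}

#' Select differentially expressed probes
#'
#' Applies the fold-change, p-value and presence gates to the output of
#' [twoGroupTTest()].  Up: log2fc > log2(fc_min), p <= p_max and
#' present_frac >= present_frac_min; down is symmetric with
#' log2fc < -log2(fc_min).  The two sets are disjoint by construction and
#' raising \code{fc_min} or lowering \code{p_max} can only shrink them.
#'
#' @param records output of [twoGroupTTest()].
#' @param thresholds a [DiffExpThresholds-class] (defaults: FC > 2,
#'   p < 0.001, present in >= 80%).
#' @return List with \code{up_probes}, \code{down_probes} (character
#'   vectors) and \code{records} annotated with logical columns
#'   \code{pass_fc}, \code{pass_p}, \code{pass_present}, \code{pass_up},
#'   \code{pass_down}.
#' @export
selectDE <- function(records, thresholds = diffExpThresholds()) {
    validObject(thresholds)
    lfc_min <- log2(thresholds@fc_min)
    ok <- records$testable & !is.na(records$p_value)
    pass_p <- ok & records$p_value <= thresholds@p_max
    pass_present <- records$present_frac >= thresholds@present_frac_min
    pass_fc_up <- ok & records$log2fc > lfc_min
    pass_fc_down <- ok & records$log2fc < -lfc_min
    up <- pass_fc_up & pass_p & pass_present
    down <- pass_fc_down & pass_p & pass_present
    records$pass_fc <- pass_fc_up | pass_fc_down
    records$pass_p <- pass_p
    records$pass_present <- pass_present
    records$pass_up <- up
    records$pass_down <- down
    list(up_probes = records$probe_id[up],
         down_probes = records$probe_id[down],
         records = records)
}

#' Write differential-expression records as TSV
#'
#' @param records (annotated) records from [twoGroupTTest()]/[selectDE()].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeDiffExp <- function(records, path) {
    df <- as.data.frame(records)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v)
        ifelse(is.na(v), NA, sprintf("%.10g", v)))
    writeTsv(df, path)
}
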