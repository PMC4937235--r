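## Validation of a signature on an independent paired count cohort:
## full-quantile normalization of log2 counts, a paired per-gene
## differential test with BH-FDR, direction-aware confirmation and
## cross-platform fold-change concordance.
##
## The paired test is a one-sample t-test on within-patient tumor-normal
## differences of normalized log2 counts -- a deliberate, documented
## substitute for a paired negative-binomial GLM: it preserves the paired
## structure and the FDR gate while staying free of dispersion shrinkage.

#' Filter genes with low counts
#'
#' Approximate library-size pre-filtering: keep genes whose mean raw count
#' across libraries is at least \code{min_mean} (default 5).
#'
#' @param counts integer gene x library matrix (or count
#'   \code{SummarizedExperiment}).
#' @param min_mean minimum mean count.
#' @return Filtered object of the same type.
#' @export
filterLowCounts <- function(counts, min_mean = 5) {
    mat <- .get_exprs(counts)
    counts[rowMeans(mat) >= min_mean, , drop = FALSE]
}

#' Full-quantile normalization of count libraries
#'
#' log2(count + pseudocount) followed by full-quantile normalization
#' across libraries (identical algorithm to [quantileNormalize()]).
#'
#' @param counts non-negative integer matrix (genes x libraries) or a
#'   count \code{SummarizedExperiment}.
#' @param pseudocount positive offset (default 1) added before the log;
#'   required to be > 0 when zero counts are present.
#' @return Same container with normalized log2 values.
#' @export
normalizeCountsFullQuantile <- function(counts, pseudocount = 1) {
    mat <- .get_exprs(counts)
    if (any(mat < 0)) stop("counts must be non-negative")
    if (pseudocount <= 0 && any(mat == 0))
        stop("zero counts present; use a pseudocount > 0")
    .set_exprs(counts, quantileNormalize(log2(mat + pseudocount)))
}

#' Paired per-gene differential test
#'
#' For each gene, within-patient differences d_i = tumor_i - normal_i on
#' the normalized log2 scale; \code{log2fc_seq} is mean(d) and the
#' p-value comes from a two-sided one-sample t-test of d against 0 with
#' n_pairs - 1 degrees of freedom.  A gene with identical differences
#' across patients (zero variance) gets the limiting p of 0 when the mean
#' difference is non-zero and p = 1 when it is zero; such genes are
#' flagged in \code{zero_variance}.
#'
#' @param norm normalized log2 matrix (genes x libraries) or
#'   \code{SummarizedExperiment}.
#' @param design paired design \code{data.frame} with columns
#'   \code{patient_id}, \code{tumor}, \code{normal} (sample/library ids);
#'   taken from \code{metadata()$design} when \code{norm} is a simulated
#'   count cohort.
#' @return A [S4Vectors::DataFrame]: \code{gene}, \code{log2fc_seq},
#'   \code{t_stat}, \code{p_value}, \code{n_pairs}, \code{zero_variance}.
#' @export
pairedDE <- function(norm, design = NULL) {
    if (is.null(design) && is(norm, "SummarizedExperiment"))
        design <- metadata(norm)$design
    if (is.null(design)) stop("a paired design is required")
    need <- c("patient_id", "tumor", "normal")
    if (!all(need %in% colnames(design)))
        stop("design must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(c(design$tumor, design$normal)))
        stop("each sample may appear in exactly one pair")
    mat <- .get_exprs(norm)
    miss <- setdiff(c(design$tumor, design$normal), colnames(mat))
    if (length(miss))
        stop("pair member(s) absent from matrix: ",
             paste(miss, collapse = ", "))
    n <- nrow(design)
    if (n < 2L) stop("need >= 2 complete pairs for the paired test")
    d <- mat[, design$tumor, drop = FALSE] -
         mat[, design$normal, drop = FALSE]
    m <- rowMeans(d)
    s <- sqrt(rowSums((d - m)^2) / (n - 1L))
    se <- s / sqrt(n)
    t_stat <- m / se
    p <- 2 * pt(-abs(t_stat), df = n - 1L)
    zero_var <- se == 0
    t_stat[zero_var] <- sign(m[zero_var]) * Inf
    t_stat[zero_var & m == 0] <- 0
    p[zero_var] <- ifelse(m[zero_var] == 0, 1, 0)
    DataFrame(gene = rownames(mat), log2fc_seq = unname(m),
              t_stat = unname(t_stat), p_value = unname(p),
              n_pairs = n, zero_variance = unname(zero_var),
              row.names = rownames(mat))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q_(i) = min over j >= i of m * p_(j) / j, clipped at 1 and mapped back
#' to the input order (delegates to \code{stats::p.adjust}).
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))
#' @export
bhAdjust <- function(p_values) {
    if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p_values, method = "BH")
}

#' Cross-platform confirmation and fold-change concordance
#'
#' Annotates paired-test records with BH q-values, the array fold change
#' and a direction-aware confirmation flag (q < \code{fdr_max} AND
#' sign(log2fc_seq) == sign(log2fc_array)), then summarizes a signature:
#' confirmed up/down counts and the concordance between platforms
#' (squared Pearson correlation and regression slope of sequencing on
#' array fold changes).  R-squared is direction-blind, which is why the
#' confirmation flag gates on sign separately.
#'
#' @param records output of [pairedDE()].
#' @param log2fc_array named numeric vector of array log2 fold changes
#'   (gene-level).
#' @param signature gene set to summarize.
#' @param fdr_max FDR gate (default 0.05).
#' @return List with \code{records} (annotated \code{DataFrame}:
#'   \code{q_value}, \code{log2fc_array}, \code{confirmed}) and
#'   \code{summary} (\code{n_signature}, \code{n_tested},
#'   \code{n_confirmed_up}, \code{n_confirmed_down}, \code{r_squared},
#'   \code{slope}; the regression fields are \code{NA} with fewer than 3
#'   genes carrying both fold changes).
#' @export
concordance <- function(records, log2fc_array, signature,
                        fdr_max = 0.05) {
    records$q_value <- bhAdjust(records$p_value)
    records$log2fc_array <- unname(log2fc_array[records$gene])
    records$confirmed <- !is.na(records$log2fc_array) &
        records$q_value < fdr_max &
        sign(records$log2fc_seq) == sign(records$log2fc_array)
    sig_rec <- records[records$gene %in% signature, , drop = FALSE]
    both <- !is.na(sig_rec$log2fc_array)
    r2 <- slope <- NA_real_
    if (sum(both) >= 3L) {
        xa <- sig_rec$log2fc_array[both]
        xs <- sig_rec$log2fc_seq[both]
        if (sd(xa) > 0 && sd(xs) > 0) {
            r2 <- cor(xa, xs)^2
            slope <- unname(coef(lm(xs ~ xa))[2L])
        }
    }
    conf <- sig_rec$confirmed
    list(records = records,
         summary = list(
             n_signature = length(unique(signature)),
             n_tested = nrow(sig_rec),
             n_confirmed_up = sum(conf & sig_rec$log2fc_array > 0),
             n_confirmed_down = sum(conf & sig_rec$log2fc_array < 0),
             r_squared = r2, slope = slope))
}

#' Write validation records and summary
#'
#' @param result output of [concordance()].
#' @param path TSV path for the per-gene records; a JSON summary is
#'   written next to it (same name, \code{.json} extension).
#' @return Invisibly, the paths written.
#' @export
writeValidation <- function(result, path) {
    df <- as.data.frame(result$records)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v)
        ifelse(is.na(v), NA, sprintf("%.10g", v)))
    writeTsv(df, path)
    json_path <- sub("\\.tsv$", ".json", path)
    jsonlite::write_json(result$summary, json_path, auto_unbox = TRUE,
                         digits = NA, na = "null")
    invisible(c(records = path, summary = json_path))
}
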