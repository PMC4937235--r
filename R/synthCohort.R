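#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   'assays<-' rowData colData
#' @importFrom S4Vectors DataFrame metadata 'metadata<-'
NULL

# Evaluate expr with a local, restored RNG state so simulation calls do not
# perturb the caller's random stream.
.with_seed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

#' Simulate a probe-level expression cohort with planted signature genes
#'
#' Generates a log2-scale probe x sample intensity matrix emulating a
#' merged tumor / normal-liver / multi-tissue-panel study, with redundant
#' probes per gene and genes planted in four classes:
#' \describe{
#'   \item{tumor_specific}{+\code{delta} in tumor samples only.}
#'   \item{tumor_associated}{+\code{delta} in tumor samples and
#'     +\code{delta}/4 in a random 20% of tissue types (partial leakage
#'     that the tissue screen must catch).}
#'   \item{liver_specific}{+\code{delta} in tumor and normal-liver
#'     samples (organ identity, not tumor biology).}
#'   \item{down_in_tumor}{-\code{delta} in tumor samples.}
#' }
#' Every probe of a gene carries the gene's signal; probes differ only by
#' independent Gaussian noise.  The result is bit-reproducible for a given
#' configuration (the seed lives in the config).
#'
#' @param config a [CohortConfig-class].
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{"exprs"} (probes x samples, log2 scale), \code{rowData} columns
#'   \code{gene_symbol} and \code{truth_class}, \code{colData} columns
#'   \code{group}, \code{etiology}, \code{tissue_type}, and the config plus
#'   gene-level truth table in \code{metadata()}.
#' @examples
#' se <- simulateExpressionCohort(cohortConfig(n_genes = 100, seed = 3))
#' se
#' table(truthLabels(se))
#' @seealso [truthLabels()], [simulateCountCohort()], [writeCohort()]
#' @export
simulateExpressionCohort <- function(config) {
    stopifnot(is(config, "CohortConfig"))
    validObject(config)
    .with_seed(config@seed, .simulate_expression_impl(config))
}

.planted_classes <- function(config) {
    classes <- rep("background", config@n_genes)
    idx <- 1L
    for (cl in .SIGNATURE_CLASSES) {
        k <- config@n_planted[cl]
        if (is.na(k) || k == 0L) next
        classes[idx:(idx + k - 1L)] <- cl
        idx <- idx + k
    }
    classes
}

.simulate_expression_impl <- function(config) {
    n_genes <- config@n_genes
    genes <- sprintf("GENE%04d", seq_len(n_genes))
    classes <- .planted_classes(config)

    ## sample layout
    tum_ids <- sprintf("TUM%03d", seq_len(config@n_tumor))
    liv_ids <- sprintf("LIV%03d", seq_len(config@n_normal_liver))
    tissues <- sprintf("TISSUE%02d", seq_len(config@n_tissue_types))
    tis_ids <- as.vector(t(outer(tissues, seq_len(config@samples_per_tissue),
                                 function(a, b) sprintf("%s_S%d", a, b))))
    sample_ids <- c(tum_ids, liv_ids, tis_ids)
    group <- c(rep("tumor", length(tum_ids)),
               rep("normal_liver", length(liv_ids)),
               rep("normal_tissue", length(tis_ids)))
    etiology <- c(rep(c("HBV", "HCV"), c(config@n_hbv, config@n_hcv)),
                  rep(NA_character_, length(liv_ids) + length(tis_ids)))
    tissue_type <- c(rep(NA_character_, length(tum_ids) + length(liv_ids)),
                     rep(tissues, each = config@samples_per_tissue))

    ## probe layout (redundant probes per gene)
    r <- config@probes_per_gene_range
    ppg <- if (r[1L] == r[2L]) rep(r[1L], n_genes) else
        sample(seq(r[1L], r[2L]), n_genes, replace = TRUE)
    gene_of_probe <- rep(seq_len(n_genes), ppg)
    probe_ids <- sprintf("PR%05d_at", seq_along(gene_of_probe))

    ## gene-level signal matrix (genes x samples), log2-additive.
    ## Planted-class offsets are clamped to [-baseline_sd, 0]: candidate
    ## signature genes are modeled as at-or-below-average baseline in
    ## normal tissue (the premise of a tumor-antigen screen), which also
    ## keeps their planted effects out of the saturated top of the
    ## intensity range where rank-based normalization cannot preserve
    ## fold changes.  Background genes keep unclamped offsets so
    ## normalization stays non-trivial.
    offset <- rnorm(n_genes, 0, config@baseline_sd)
    planted <- classes != "background"
    offset[planted] <- pmin(pmax(offset[planted], -config@baseline_sd), 0)
    signal <- matrix(config@baseline_mu + offset,
                     nrow = n_genes, ncol = length(sample_ids))
    is_tum <- group == "tumor"
    is_liv <- group == "normal_liver"
    d <- config@delta
    signal[classes == "tumor_specific", is_tum] <-
        signal[classes == "tumor_specific", is_tum] + d
    signal[classes == "liver_specific", is_tum | is_liv] <-
        signal[classes == "liver_specific", is_tum | is_liv] + d
    signal[classes == "down_in_tumor", is_tum] <-
        signal[classes == "down_in_tumor", is_tum] - d
    ta_genes <- which(classes == "tumor_associated")
    if (length(ta_genes)) {
        signal[ta_genes, is_tum] <- signal[ta_genes, is_tum] + d
        n_leak <- max(1L, round(0.20 * config@n_tissue_types))
        for (g in ta_genes) {
            leak <- sample(tissues, n_leak)
            cols <- which(tissue_type %in% leak)
            signal[g, cols] <- signal[g, cols] + d / 4
        }
    }

    mat <- signal[gene_of_probe, , drop = FALSE]
    if (config@noise_sd > 0)
        mat <- mat + matrix(rnorm(length(mat), 0, config@noise_sd),
                            nrow = nrow(mat))
    dimnames(mat) <- list(probe_ids, sample_ids)

    truth <- data.frame(gene_id = genes, class = classes,
                        stringsAsFactors = FALSE)
    se <- SummarizedExperiment(
        assays = list(exprs = mat),
        rowData = DataFrame(probe_id = probe_ids,
                            gene_symbol = genes[gene_of_probe],
                            truth_class = classes[gene_of_probe],
                            row.names = probe_ids),
        colData = DataFrame(sample_id = sample_ids, group = group,
                            etiology = etiology, tissue_type = tissue_type,
                            row.names = sample_ids))
    metadata(se)$config <- config
    metadata(se)$truth <- truth
    se
}

#' Planted per-gene class labels of a synthetic cohort
#'
#' @param x a cohort [SummarizedExperiment::SummarizedExperiment] produced
#'   by [simulateExpressionCohort()], or its \code{metadata()$truth} table.
#' @return Named character vector, gene symbol to class (one of
#'   \code{tumor_specific}, \code{tumor_associated}, \code{liver_specific},
#'   \code{down_in_tumor}, \code{background}).
#' @export
truthLabels <- function(x) {
    truth <- if (is.data.frame(x)) x else metadata(x)$truth
    if (is.null(truth))
        stop("no planted truth labels found; was this object simulated?")
    setNames(truth$class, truth$gene_id)
}

#' Simulate a paired tumor/normal count cohort
#'
#' Generates gene-level integer counts for \code{n_patients} patients, one
#' tumor and one adjacent-normal library each, sharing a per-patient
#' log-normal baseline, with per-library size factors and
#' negative-binomial sampling (variance = mu + dispersion * mu^2;
#' \code{dispersion = 0} gives Poisson counts).  Gene means derive from the
#' same log2-additive signal model as [simulateExpressionCohort()]:
#' planted tumor-specific/tumor-associated genes are shifted +\code{delta}
#' in the tumor library, \code{down_in_tumor} genes -\code{delta}, and
#' liver-specific genes are elevated in both members of the pair (so their
#' paired log-ratio is null).
#'
#' @param config a [CohortConfig-class]; supplies \code{delta},
#'   \code{baseline_mu}, \code{baseline_sd}.
#' @param truth named character vector of per-gene classes (see
#'   [truthLabels()]); defines the gene universe.
#' @param n_patients number of tumor/normal pairs (>= 2).
#' @param dispersion negative-binomial dispersion (>= 0).
#' @param patient_sdlog,library_sdlog log-normal SDs of the shared
#'   per-patient baseline and the per-library size factor (set both to 0
#'   for libraries with identical expected depth).
#' @param seed RNG seed (defaults to the config seed).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{"counts"} (genes x libraries), \code{colData} columns
#'   \code{patient} and \code{condition} in {tumor, normal}, and the
#'   paired design table (patient_id, tumor, normal) in
#'   \code{metadata()$design}.
#' @examples
#' cfg <- cohortConfig(n_genes = 50, seed = 2)
#' truth <- truthLabels(simulateExpressionCohort(cfg))
#' cse <- simulateCountCohort(cfg, truth, n_patients = 4)
#' head(SummarizedExperiment::assay(cse))
#' @export
simulateCountCohort <- function(config, truth, n_patients = 9L,
                                dispersion = 0.1, patient_sdlog = 0.3,
                                library_sdlog = 0.15,
                                seed = config@seed) {
    stopifnot(is(config, "CohortConfig"))
    if (n_patients < 2L)
        stop("'n_patients' must be >= 2 (a paired test needs >= 2 pairs)")
    if (dispersion < 0) stop("'dispersion' must be >= 0")
    genes <- names(truth)
    if (is.null(genes)) stop("'truth' must be a named class vector")
    .with_seed(seed, {
        n_g <- length(genes)
        offset <- rnorm(n_g, 0, config@baseline_sd)
        d <- config@delta
        shift_tum <- numeric(n_g)
        shift_tum[truth %in% c("tumor_specific", "tumor_associated")] <- d
        shift_tum[truth == "down_in_tumor"] <- -d
        shift_both <- numeric(n_g)
        shift_both[truth == "liver_specific"] <- d

        pats <- sprintf("PT%02d", seq_len(n_patients))
        tum_ids <- paste0(pats, "_T")
        nor_ids <- paste0(pats, "_N")
        base_log2 <- config@baseline_mu + offset
        counts <- matrix(0L, nrow = n_g, ncol = 2L * n_patients,
                         dimnames = list(genes, c(rbind(tum_ids, nor_ids))))
        for (i in seq_len(n_patients)) {
            patient_baseline <- rlnorm(1, 0, patient_sdlog)
            sf <- rlnorm(2, 0, library_sdlog)   # per-library size factors
            mu_t <- sf[1L] * patient_baseline *
                2^(base_log2 + shift_tum + shift_both)
            mu_n <- sf[2L] * patient_baseline * 2^(base_log2 + shift_both)
            draw <- function(mu) {
                if (dispersion == 0) rpois(n_g, mu)
                else rnbinom(n_g, mu = mu, size = 1 / dispersion)
            }
            counts[, tum_ids[i]] <- draw(mu_t)
            counts[, nor_ids[i]] <- draw(mu_n)
        }
        storage.mode(counts) <- "integer"
        design <- data.frame(patient_id = pats, tumor = tum_ids,
                             normal = nor_ids, stringsAsFactors = FALSE)
        lib_ids <- colnames(counts)
        se <- SummarizedExperiment(
            assays = list(counts = counts),
            colData = DataFrame(
                sample_id = lib_ids,
                patient = rep(pats, each = 2L),
                condition = rep(c("tumor", "normal"), n_patients),
                row.names = lib_ids))
        metadata(se)$design <- design
        metadata(se)$dispersion <- dispersion
        se
    })
}

#' Write a simulated cohort to plain tab-separated files
#'
#' Serializes the expression matrix, sample sheet, probe-to-gene map and
#' planted truth labels (and optionally a paired count cohort) into a
#' directory, using the same formats [readExpressionMatrix()] and friends
#' read back.
#'
#' @param se expression cohort from [simulateExpressionCohort()].
#' @param dir output directory (created if absent).
#' @param counts_se optional count cohort from [simulateCountCohort()].
#' @return Invisibly, a named character vector of the files written.
#' @export
writeCohort <- function(se, dir, counts_se = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
        expression = file.path(dir, "expression.tsv"),
        sample_sheet = file.path(dir, "sample_sheet.tsv"),
        probe_map = file.path(dir, "probe_map.tsv"),
        truth = file.path(dir, "truth_labels.tsv"))
    writeExpressionMatrix(assay(se, "exprs"), paths["expression"])
    sheet <- as.data.frame(colData(se))
    writeTsv(sheet[, c("sample_id", "group", "etiology", "tissue_type")],
             paths["sample_sheet"])
    map <- data.frame(probe_id = rowData(se)$probe_id,
                      gene_symbol = rowData(se)$gene_symbol)
    writeTsv(map, paths["probe_map"])
    writeTsv(metadata(se)$truth, paths["truth"])
    if (!is.null(counts_se)) {
        paths <- c(paths, counts = file.path(dir, "counts.tsv"),
                   design = file.path(dir, "paired_design.tsv"))
        writeCountMatrix(assay(counts_se, "counts"), paths["counts"])
        writeTsv(metadata(counts_se)$design, paths["design"])
    }
    invisible(paths)
}
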