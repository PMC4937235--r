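## End-to-end orchestration: config -> preprocess -> step-1 DE -> step-2
## classification (per setting) -> overlap -> optional count validation,
## with a JSON manifest and a plain-text report.

.default_run_config <- function() {
    list(
        seed = 1L,
        output_dir = "tumorspec_run",
        input_scale = "log2",
        stratify_etiologies = TRUE,
        validate = TRUE,
        n_patients = 9L,
        dispersion = 0.1,
        fdr_max = 0.05,
        synthetic = NULL,
        inputs = NULL,
        diffexp = list(fc_min = 2, p_max = 0.001, present_frac_min = 0.80),
        signature = list(log2fc_up = 1, tumor_frac_min = 0.80,
                         tissue_frac_max = 0.10, majority_frac = 0.50))
}

#' Read and validate a pipeline run configuration
#'
#' YAML with top-level fields \code{seed}, \code{output_dir},
#' \code{input_scale} (\code{log2} or \code{natural}),
#' \code{stratify_etiologies}, \code{validate}, \code{n_patients},
#' \code{dispersion}, \code{fdr_max}, \code{diffexp} /\code{signature}
#' threshold blocks, and either a \code{synthetic} block (arguments of
#' [cohortConfig()]) or an \code{inputs} block with paths
#' \code{expression}, \code{sample_sheet}, \code{probe_map}.  Omitted
#' fields take the package defaults (which mirror the classic gates:
#' FC > 2, p < 0.001, 80% presence, log2FC > 1, >80% of tumors,
#' <10% of tissues, FDR < 0.05).
#'
#' @param path path to a YAML file, or a list with the same structure.
#' @return Validated config list.
#' @export
readRunConfig <- function(path) {
    cfg <- if (is.list(path)) path else yaml::read_yaml(path)
    base <- .default_run_config()
    for (k in names(cfg)) {
        if (!k %in% names(base))
            stop(sprintf("unknown config field '%s'", k))
        base[[k]] <- if (is.list(cfg[[k]]) && is.list(base[[k]]) &&
                         k %in% c("diffexp", "signature"))
            utils::modifyList(base[[k]], cfg[[k]]) else cfg[[k]]
    }
    if (!base$input_scale %in% c("log2", "natural"))
        stop("'input_scale' must be 'log2' or 'natural'")
    if (is.null(base$inputs) && is.null(base$synthetic))
        stop("config needs either an 'inputs' or a 'synthetic' block")
    if (!is.null(base$inputs)) {
        need <- c("expression", "sample_sheet", "probe_map")
        miss <- setdiff(need, names(base$inputs))
        if (length(miss))
            stop("'inputs' lacks path(s): ", paste(miss, collapse = ", "))
        absent <- !vapply(base$inputs[need], file.exists, logical(1))
        if (any(absent))
            stop("input file(s) not found: ",
                 paste(unlist(base$inputs[need])[absent], collapse = ", "))
    }
    ## fail early on invalid thresholds
    do.call(diffExpThresholds, base$diffexp)
    do.call(signatureThresholds, base$signature)
    base
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE))
}

#' Run the full signature-discovery pipeline
#'
#' Executes preprocess -> step-1 differential expression -> step-2
#' classification for each analysis setting (pooled plus HBV/HCV when
#' stratified), the cross-setting overlap, and -- for synthetic cohorts
#' with \code{validate: true} -- a paired count-cohort validation of the
#' pooled tumor-specific signature.  All outputs are plain TSV/JSON under
#' \code{output_dir}, listed in a JSON manifest; identical config and
#' seed give byte-identical outputs.
#'
#' @param config a config list or YAML path (see [readRunConfig()]).
#' @return The manifest, invisibly (also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config) {
    cfg <- readRunConfig(config)
    out_dir <- cfg$output_dir
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log_path <- file.path(out_dir, "run.log")
    log_lines <- character()
    note <- function(fmt, ...) {
        line <- sprintf(fmt, ...)
        message(line)
        log_lines <<- c(log_lines, line)
    }
    outputs <- list()
    partial <- character()

    se <- .stage("input", {
        if (!is.null(cfg$inputs)) {
            note("reading expression cohort from %s",
                 cfg$inputs$expression)
            mat <- readExpressionMatrix(cfg$inputs$expression)
            sheet <- readSampleSheet(cfg$inputs$sample_sheet, mat)
            map <- readProbeGeneMap(cfg$inputs$probe_map, rownames(mat))
            makeCohortExperiment(mat, sheet, map)
        } else {
            syn <- cfg$synthetic
            syn$seed <- cfg$seed
            note("simulating synthetic cohort (seed %d)", cfg$seed)
            simulateExpressionCohort(do.call(cohortConfig, syn))
        }
    })

    se <- .stage("preprocess", {
        if (cfg$input_scale == "natural") se <- log2Transform(se)
        se <- dropIncompleteProbes(se, quiet = TRUE)
        n_drop <- metadata(se)$n_dropped_incomplete
        if (!is.null(n_drop) && n_drop > 0L)
            note("dropped %d probe(s) with missing values", n_drop)
        quantileNormalize(se)
    })

    de_thr <- do.call(diffExpThresholds, cfg$diffexp)
    sig_thr <- do.call(signatureThresholds, cfg$signature)
    results <- .stage("signatures",
        discoverSignatures(se, de_thr, sig_thr,
                           stratify = isTRUE(cfg$stratify_etiologies)))
    funnels <- lapply(results, `[[`, "funnel")
    for (nm in names(results)) {
        res <- results[[nm]]
        de_path <- file.path(out_dir, sprintf("diffexp_%s.tsv", nm))
        writeDiffExp(res$de$records, de_path)
        sig_path <- file.path(out_dir, sprintf("signatures_%s.tsv", nm))
        writeTsv(signatureTable(res$signatures, res$profile, sig_thr),
                 sig_path)
        outputs[[paste0("diffexp_", nm)]] <- de_path
        outputs[[paste0("signatures_", nm)]] <- sig_path
        note("[%s] up probes %d, tumor-associated %d, liver-specific %d, tumor-specific %d",
             nm, res$funnel[["probes_up"]],
             res$funnel[["genes_tumor_associated"]],
             res$funnel[["genes_liver_specific"]],
             res$funnel[["genes_tumor_specific"]])
    }

    if (length(results) >= 2L) {
        venn <- .stage("overlap",
            signatureOverlap(lapply(results, `[[`, "signatures"),
                             category = "tumor_specific"))
        venn_path <- file.path(out_dir, "overlap_tumor_specific.tsv")
        writeTsv(venn, venn_path)
        outputs$overlap <- venn_path
    }

    validation_summary <- NULL
    if (isTRUE(cfg$validate)) {
        if (is.null(cfg$inputs)) {
            val <- .stage("validation", {
                syn <- cfg$synthetic
                syn$seed <- cfg$seed
                ccfg <- do.call(cohortConfig, syn)
                truth <- truthLabels(se)
                counts <- simulateCountCohort(
                    ccfg, truth, n_patients = cfg$n_patients,
                    dispersion = cfg$dispersion,
                    seed = cfg$seed + 1L)
                norm <- normalizeCountsFullQuantile(
                    filterLowCounts(counts))
                rec <- pairedDE(norm)
                hcc <- results[["HCC"]]
                lfc_array <- rowMeans(.by_gene(
                    hcc$profile@tumor_lfc, hcc$profile@gene_symbols))
                concordance(rec, lfc_array,
                            tumorSpecific(hcc$signatures),
                            fdr_max = cfg$fdr_max)
            })
            val_path <- file.path(out_dir, "validation.tsv")
            paths <- writeValidation(val, val_path)
            outputs$validation <- unname(paths["records"])
            outputs$validation_summary <- unname(paths["summary"])
            validation_summary <- val$summary
            note("validation: %d/%d signature genes confirmed up (FDR < %g)",
                 val$summary$n_confirmed_up, val$summary$n_signature,
                 cfg$fdr_max)
        } else {
            partial <- c(partial, "validation")
            note("validation skipped: no paired count cohort configured")
        }
    }

    manifest <- list(
        package = "TumorSpecScreen",
        version = as.character(packageVersion("TumorSpecScreen")),
        seed = cfg$seed,
        parameters = cfg[c("input_scale", "stratify_etiologies",
                           "validate", "n_patients", "dispersion",
                           "fdr_max", "diffexp", "signature")],
        settings = names(results),
        funnels = funnels,
        validation = validation_summary,
        outputs = outputs,
        partial_stages = partial)
    writeLines(log_lines, log_path)
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    manifest$path <- manifest_path
    invisible(manifest)
}

#' Render a human-readable run report
#'
#' Produces a single markdown document from a run manifest: parameter
#' echo, per-setting filter funnels (probe and gene counts at each gate),
#' signature sizes, overlap counts and the concordance summary (marked
#' "not run" when the validation stage was skipped).
#'
#' @param manifest manifest list from [runPipeline()] or a path to a
#'   \code{manifest.json}.
#' @param path output file (default \code{report.md} next to the
#'   manifest).
#' @return Invisibly, the report path.
#' @export
renderReport <- function(manifest, path = NULL) {
    if (is.character(manifest)) {
        mp <- manifest
        manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
        manifest$path <- mp
    }
    need <- c("parameters", "settings", "funnels", "outputs")
    miss <- setdiff(need, names(manifest))
    if (length(miss))
        stop("manifest lacks entries: ", paste(miss, collapse = ", "))
    if (is.null(path))
        path <- file.path(dirname(manifest$path %||% "."), "report.md")
    p <- manifest$parameters
    lines <- c(
        "# Two-step tumor-specificity screen: run report", "",
        sprintf("Seed: %s", manifest$seed),
        sprintf("Thresholds: FC > %g, p < %g, presence >= %g%%; log2FC > %g, tumor fraction > %g, tissue fraction < %g; FDR < %g",
                p$diffexp$fc_min, p$diffexp$p_max,
                100 * p$diffexp$present_frac_min, p$signature$log2fc_up,
                p$signature$tumor_frac_min, p$signature$tissue_frac_max,
                p$fdr_max),
        "", "## Filter funnels", "")
    for (nm in manifest$settings) {
        f <- unlist(manifest$funnels[[nm]])
        lines <- c(lines, sprintf("### %s", nm), "",
            sprintf("- probes in: %d (testable %d)",
                    f[["probes_total"]], f[["probes_testable"]]),
            sprintf("- step 1: %d up / %d down probes; %d unique up genes",
                    f[["probes_up"]], f[["probes_down"]],
                    f[["genes_up"]]),
            sprintf("- step 2: %d tumor-associated, %d liver-specific, %d tumor-specific genes",
                    f[["genes_tumor_associated"]],
                    f[["genes_liver_specific"]],
                    f[["genes_tumor_specific"]]), "")
    }
    lines <- c(lines, "## Validation", "")
    v <- manifest$validation
    if (is.null(v) || (is.list(v) && !length(v))) {
        lines <- c(lines, "Concordance: not run.", "")
    } else {
        r2 <- if (is.null(v$r_squared) || is.na(v$r_squared)) "NA"
              else sprintf("%.4f", v$r_squared)
        sl <- if (is.null(v$slope) || is.na(v$slope)) "NA"
              else sprintf("%.4f", v$slope)
        lines <- c(lines, sprintf(
            "- signature genes: %d (tested %d); confirmed up %d, down %d",
            v$n_signature, v$n_tested, v$n_confirmed_up,
            v$n_confirmed_down),
            sprintf("- fold-change concordance: R^2 = %s, slope = %s",
                    r2, sl), "")
    }
    lines <- c(lines, "## Outputs", "",
               sprintf("- %s: %s", names(manifest$outputs),
                       unlist(manifest$outputs)))
    writeLines(lines, path)
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
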