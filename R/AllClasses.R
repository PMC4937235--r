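#' @import methods
#' @importFrom stats rnorm rnbinom rpois rlnorm pt sd var setNames p.adjust
#'   coef lm cor
#' @importFrom utils read.delim write.table packageVersion
NULL

.SIGNATURE_CLASSES <- c("tumor_specific", "tumor_associated",
                        "liver_specific", "down_in_tumor")

.SAMPLE_GROUPS <- c("tumor", "normal_liver", "normal_tissue")

#' Configuration of a synthetic expression cohort
#'
#' Describes the sample structure, gene/probe layout and signal model of a
#' simulated probe-level expression cohort with planted signature-class
#' genes.  The default shape mirrors the study design the package targets:
#' 55 hepatocellular carcinoma (HCC) samples (13 HBV-related, 42
#' HCV-related), 14 normal liver samples and a panel of 41 normal tissue
#' types with 2 samples each, profiled on a redundant-probe array
#' (several probes per gene).
#'
#' Planted signal is additive on the log2 scale: every probe of a gene
#' carries the gene's class signal of magnitude \code{delta} (log2 units)
#' on top of a per-gene baseline offset and i.i.d. Gaussian noise.
#'
#' @slot n_tumor,n_hbv,n_hcv integer; tumor sample counts
#'   (\code{n_hbv + n_hcv == n_tumor}).
#' @slot n_normal_liver integer; matched normal liver samples.
#' @slot n_tissue_types,samples_per_tissue integer; size of the normal
#'   multi-tissue panel.
#' @slot n_genes integer; total genes simulated (planted + background).
#' @slot probes_per_gene_range integer(2); each gene gets a uniform random
#'   number of probes in this (inclusive) range.
#' @slot n_planted named integer; genes planted per signature class
#'   (names among \code{tumor_specific}, \code{tumor_associated},
#'   \code{liver_specific}, \code{down_in_tumor}).
#' @slot delta numeric; planted effect size in log2 units.
#' @slot baseline_mu,baseline_sd numeric; per-gene baseline log2 level
#'   \code{baseline_mu + N(0, baseline_sd)}.
#' @slot noise_sd numeric; per-cell Gaussian noise SD (log2 units).
#' @slot seed integer; RNG seed making the cohort reproducible.
#' @seealso [cohortConfig()], [simulateExpressionCohort()]
#' @export
setClass("CohortConfig",
    representation(
        n_tumor = "integer", n_hbv = "integer", n_hcv = "integer",
        n_normal_liver = "integer", n_tissue_types = "integer",
        samples_per_tissue = "integer", n_genes = "integer",
        probes_per_gene_range = "integer", n_planted = "integer",
        delta = "numeric", baseline_mu = "numeric", baseline_sd = "numeric",
        noise_sd = "numeric", seed = "integer"))

setValidity("CohortConfig", function(object) {
    msgs <- character()
    count_slots <- c("n_tumor", "n_hbv", "n_hcv", "n_normal_liver",
                     "n_tissue_types", "samples_per_tissue", "n_genes")
    for (s in count_slots) {
        v <- slot(object, s)
        if (length(v) != 1L || is.na(v) ||
            (v < 1L && !s %in% c("n_hbv", "n_hcv")))
            msgs <- c(msgs, sprintf("'%s' must be a single integer >= 1", s))
    }
    if (length(object@n_hbv) == 1L && length(object@n_hcv) == 1L &&
        length(object@n_tumor) == 1L &&
        !anyNA(c(object@n_hbv, object@n_hcv, object@n_tumor)) &&
        object@n_hbv + object@n_hcv != object@n_tumor)
        msgs <- c(msgs, "'n_hbv' + 'n_hcv' must equal 'n_tumor'")
    r <- object@probes_per_gene_range
    if (length(r) != 2L || anyNA(r) || r[1L] < 1L || r[2L] < r[1L])
        msgs <- c(msgs,
            "'probes_per_gene_range' must be [min, max] with min >= 1")
    if (is.null(names(object@n_planted)) ||
        !all(names(object@n_planted) %in% .SIGNATURE_CLASSES) ||
        any(object@n_planted < 0L))
        msgs <- c(msgs, paste0("'n_planted' must be a non-negative integer ",
            "vector named among: ", paste(.SIGNATURE_CLASSES, collapse = ", ")))
    if (length(object@delta) != 1L || is.na(object@delta) ||
        object@delta <= 0)
        msgs <- c(msgs, "'delta' must be a single positive number")
    if (length(object@noise_sd) != 1L || is.na(object@noise_sd) ||
        object@noise_sd < 0)
        msgs <- c(msgs, "'noise_sd' must be a single number >= 0")
    if (length(object@baseline_sd) != 1L || object@baseline_sd < 0)
        msgs <- c(msgs, "'baseline_sd' must be a single number >= 0")
    if (sum(object@n_planted) > object@n_genes)
        msgs <- c(msgs, "'n_planted' total exceeds 'n_genes'")
    if (length(msgs)) msgs else TRUE
})

#' Construct a synthetic-cohort configuration
#'
#' All arguments default to the cohort structure the package is designed
#' around (55/13/42 tumors, 14 normal liver, 41 x 2 normal tissues).
#'
#' @param n_tumor,n_hbv,n_hcv,n_normal_liver,n_tissue_types,samples_per_tissue
#'   cohort shape (see [CohortConfig-class]).
#' @param n_genes number of genes simulated.
#' @param probes_per_gene_range inclusive range of probes per gene.
#' @param n_planted named integer vector of planted genes per class.
#' @param delta planted log2 effect size.
#' @param baseline_mu,baseline_sd per-gene baseline level parameters (log2).
#' @param noise_sd per-cell Gaussian noise SD (log2).
#' @param seed RNG seed.
#' @return A validated [CohortConfig-class] object.
#' @examples
#' cfg <- cohortConfig(n_genes = 200, seed = 7)
#' cfg
#' @export
cohortConfig <- function(n_tumor = 55L, n_hbv = 13L, n_hcv = 42L,
                         n_normal_liver = 14L, n_tissue_types = 41L,
                         samples_per_tissue = 2L, n_genes = 1200L,
                         probes_per_gene_range = c(2L, 4L),
                         n_planted = c(tumor_specific = 30L,
                                       tumor_associated = 30L,
                                       liver_specific = 30L,
                                       down_in_tumor = 20L),
                         delta = 3, baseline_mu = 7, baseline_sd = 1,
                         noise_sd = 0.3, seed = 1L) {
    new("CohortConfig",
        n_tumor = as.integer(n_tumor), n_hbv = as.integer(n_hbv),
        n_hcv = as.integer(n_hcv),
        n_normal_liver = as.integer(n_normal_liver),
        n_tissue_types = as.integer(n_tissue_types),
        samples_per_tissue = as.integer(samples_per_tissue),
        n_genes = as.integer(n_genes),
        probes_per_gene_range = as.integer(probes_per_gene_range),
        n_planted = setNames(as.integer(n_planted), names(n_planted)),
        delta = as.numeric(delta), baseline_mu = as.numeric(baseline_mu),
        baseline_sd = as.numeric(baseline_sd),
        noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
}

setMethod("show", "CohortConfig", function(object) {
    cat("CohortConfig\n")
    cat(sprintf("  tumors: %d (HBV %d / HCV %d); normal liver: %d\n",
        object@n_tumor, object@n_hbv, object@n_hcv, object@n_normal_liver))
    cat(sprintf("  tissue panel: %d types x %d samples\n",
        object@n_tissue_types, object@samples_per_tissue))
    cat(sprintf("  genes: %d (planted: %s); probes/gene in [%d, %d]\n",
        object@n_genes,
        paste(sprintf("%s=%d", names(object@n_planted), object@n_planted),
              collapse = ", "),
        object@probes_per_gene_range[1L], object@probes_per_gene_range[2L]))
    cat(sprintf("  delta = %g, noise_sd = %g, seed = %d\n",
        object@delta, object@noise_sd, object@seed))
})

#' Thresholds for the first-step differential expression filter
#'
#' The defaults reproduce the classic array class-comparison gates: linear
#' fold change > 2, two-sided t-test p < 0.001, probe measured in at least
#' 80% of the samples of the contrast.
#'
#' @slot fc_min numeric > 1; minimum linear fold change.
#' @slot p_max numeric in (0, 1); maximum t-test p-value.
#' @slot present_frac_min numeric in (0, 1]; minimum non-missing fraction.
#' @seealso [diffExpThresholds()], [selectDE()]
#' @export
setClass("DiffExpThresholds",
    representation(fc_min = "numeric", p_max = "numeric",
                   present_frac_min = "numeric"))

setValidity("DiffExpThresholds", function(object) {
    msgs <- character()
    if (length(object@fc_min) != 1L || object@fc_min <= 1)
        msgs <- c(msgs, "'fc_min' must be a single number > 1")
    if (length(object@p_max) != 1L || object@p_max <= 0 || object@p_max >= 1)
        msgs <- c(msgs, "'p_max' must be in (0, 1)")
    if (length(object@present_frac_min) != 1L ||
        object@present_frac_min <= 0 || object@present_frac_min > 1)
        msgs <- c(msgs, "'present_frac_min' must be in (0, 1]")
    if (length(msgs)) msgs else TRUE
})

#' @rdname DiffExpThresholds-class
#' @param fc_min,p_max,present_frac_min see slot documentation.
#' @return A validated \code{DiffExpThresholds} object.
#' @export
diffExpThresholds <- function(fc_min = 2, p_max = 0.001,
                              present_frac_min = 0.80) {
    new("DiffExpThresholds", fc_min = as.numeric(fc_min),
        p_max = as.numeric(p_max),
        present_frac_min = as.numeric(present_frac_min))
}

setMethod("show", "DiffExpThresholds", function(object) {
    cat(sprintf(
        "DiffExpThresholds: FC > %g, p < %g, present in >= %g%% of samples\n",
        object@fc_min, object@p_max, 100 * object@present_frac_min))
})

#' Thresholds for second-step signature classification
#'
#' Defaults follow the tumor-specificity rules the package implements:
#' per-sample/per-tissue elevation means log2 fold change above
#' \code{log2fc_up} (default 1, i.e. 2-fold); a tumor-specific gene must be
#' elevated in strictly more than \code{tumor_frac_min} (80%) of tumor
#' samples and must be expressed in strictly fewer than
#' \code{tissue_frac_max} (10%) of normal tissue types.  A tissue type
#' counts as expressing the gene when its mean exceeds the non-tumor
#' reference by more than \code{tissue_up_log2fc} (default
#' \code{log2fc_up/3}): candidate immunotherapy targets are held to a
#' stricter bar in normal tissues than the 2-fold bar used for tumor
#' elevation, so even modest (about 1.26-fold) elevation in a tissue
#' counts against specificity.
#'
#' @slot log2fc_up numeric; log2 fold-change threshold for "upregulated".
#' @slot tumor_frac_min numeric in (0, 1]; strict minimum fraction of tumor
#'   samples elevated.
#' @slot tissue_frac_max numeric in [0, 1); strict maximum fraction of
#'   tissue types expressing the gene.
#' @slot majority_frac numeric in (0, 1]; fraction of tissue types a
#'   tumor-associated gene must exceed when
#'   \code{classifyTumorAssociated(mode = "majority")} is used.
#' @slot tissue_up_log2fc numeric; log2 margin above the reference at which
#'   a normal tissue type counts as expressing the gene.
#' @seealso [signatureThresholds()], [classifyTumorSpecific()]
#' @export
setClass("SignatureThresholds",
    representation(log2fc_up = "numeric", tumor_frac_min = "numeric",
                   tissue_frac_max = "numeric", majority_frac = "numeric",
                   tissue_up_log2fc = "numeric"))

setValidity("SignatureThresholds", function(object) {
    msgs <- character()
    if (object@tumor_frac_min <= 0 || object@tumor_frac_min > 1)
        msgs <- c(msgs, "'tumor_frac_min' must be in (0, 1]")
    if (object@tissue_frac_max < 0 || object@tissue_frac_max >= 1)
        msgs <- c(msgs, "'tissue_frac_max' must be in [0, 1)")
    if (object@majority_frac <= 0 || object@majority_frac > 1)
        msgs <- c(msgs, "'majority_frac' must be in (0, 1]")
    if (length(object@log2fc_up) != 1L || object@log2fc_up <= 0)
        msgs <- c(msgs, "'log2fc_up' must be a single positive number")
    if (length(msgs)) msgs else TRUE
})

#' @rdname SignatureThresholds-class
#' @param log2fc_up,tumor_frac_min,tissue_frac_max,majority_frac,tissue_up_log2fc
#'   see slot documentation.
#' @return A validated \code{SignatureThresholds} object.
#' @export
signatureThresholds <- function(log2fc_up = 1, tumor_frac_min = 0.80,
                                tissue_frac_max = 0.10,
                                majority_frac = 0.50,
                                tissue_up_log2fc = log2fc_up / 3) {
    new("SignatureThresholds", log2fc_up = as.numeric(log2fc_up),
        tumor_frac_min = as.numeric(tumor_frac_min),
        tissue_frac_max = as.numeric(tissue_frac_max),
        majority_frac = as.numeric(majority_frac),
        tissue_up_log2fc = as.numeric(tissue_up_log2fc))
}

setMethod("show", "SignatureThresholds", function(object) {
    cat(sprintf(paste0(
        "SignatureThresholds: log2FC > %g; tumor fraction > %g; ",
        "tissue fraction < %g (tissue margin %g)\n"),
        object@log2fc_up, object@tumor_frac_min, object@tissue_frac_max,
        object@tissue_up_log2fc))
})

#' Per-probe fold-change profile against a multi-tissue normal panel
#'
#' Holds, for every probe, log2 fold changes of each tumor sample and each
#' normal tissue type against a per-probe reference (by default the mean
#' over all non-tumor samples, i.e. tissue panel plus normal liver), plus
#' the normal-liver contrast against the tissue-only reference.  This is
#' the substrate of the second-step classification rules.
#'
#' @slot probe_ids,gene_symbols character; probe annotation (parallel).
#' @slot tumor_lfc matrix (probes x tumor samples); per-sample log2 fold
#'   change against \code{reference}.
#' @slot tissue_lfc matrix (probes x tissue types); per-tissue-type mean
#'   log2 fold change against \code{reference}.
#' @slot liver_lfc numeric; normal-liver mean minus \code{tissue_reference}.
#' @slot reference numeric; per-probe mean over the reference samples.
#' @slot tissue_reference numeric; per-probe mean over non-liver,
#'   non-tumor samples only.
#' @slot tumor_vs_tissue_lfc numeric; per-probe tumor mean minus
#'   \code{tissue_reference} (used by the liver-specific rule).
#' @seealso [buildTissueProfile()]
#' @export
setClass("TissueProfile",
    representation(probe_ids = "character", gene_symbols = "character",
                   tumor_lfc = "matrix", tissue_lfc = "matrix",
                   liver_lfc = "numeric", reference = "numeric",
                   tissue_reference = "numeric",
                   tumor_vs_tissue_lfc = "numeric"))

setValidity("TissueProfile", function(object) {
    n <- length(object@probe_ids)
    msgs <- character()
    if (length(object@gene_symbols) != n)
        msgs <- c(msgs, "'gene_symbols' must parallel 'probe_ids'")
    if (nrow(object@tumor_lfc) != n || nrow(object@tissue_lfc) != n)
        msgs <- c(msgs, "fold-change matrices must have one row per probe")
    if (length(object@liver_lfc) != n || length(object@reference) != n ||
        length(object@tissue_reference) != n ||
        length(object@tumor_vs_tissue_lfc) != n)
        msgs <- c(msgs, "per-probe vectors must have one entry per probe")
    if (anyNA(object@tissue_lfc))
        msgs <- c(msgs, "tissue fold changes must be finite")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "TissueProfile", function(object) {
    cat(sprintf(paste0("TissueProfile: %d probes (%d genes), ",
                       "%d tumor samples, %d tissue types\n"),
        length(object@probe_ids), length(unique(object@gene_symbols)),
        ncol(object@tumor_lfc), ncol(object@tissue_lfc)))
})

#' A classified expression signature for one analysis setting
#'
#' The deliverable of the two-step screen: three disjoint-by-construction
#' gene sets for one analysis setting (e.g. all tumors, or an
#' etiology-stratified subset).  \code{tumorSpecific} is always a subset of
#' \code{tumorAssociated}; \code{liverSpecific} never overlaps
#' \code{tumorAssociated}.
#'
#' @slot setting character; analysis setting label (e.g. \code{"HCC"},
#'   \code{"HBV-HCC"}, \code{"HCV-HCC"}).
#' @slot liver_specific,tumor_associated,tumor_specific character; unique,
#'   probe-collapsed gene symbols.
#' @seealso [signatureSet()], [discoverSignatures()], [signatureOverlap()]
#' @export
setClass("SignatureSet",
    representation(setting = "character", liver_specific = "character",
                   tumor_associated = "character",
                   tumor_specific = "character"))

setValidity("SignatureSet", function(object) {
    msgs <- character()
    if (length(object@setting) != 1L || is.na(object@setting) ||
        !nzchar(object@setting))
        msgs <- c(msgs, "'setting' must be a single non-empty string")
    for (s in c("liver_specific", "tumor_associated", "tumor_specific"))
        if (anyDuplicated(slot(object, s)))
            msgs <- c(msgs, sprintf("'%s' gene symbols must be unique", s))
    if (!all(object@tumor_specific %in% object@tumor_associated))
        msgs <- c(msgs,
            "'tumor_specific' must be a subset of 'tumor_associated'")
    if (length(intersect(object@liver_specific, object@tumor_associated)))
        msgs <- c(msgs,
            "'liver_specific' and 'tumor_associated' must be disjoint")
    if (length(msgs)) msgs else TRUE
})

#' @rdname SignatureSet-class
#' @param setting analysis setting label.
#' @param liver_specific,tumor_associated,tumor_specific gene symbol
#'   vectors (deduplicated and sorted on construction).
#' @return A validated \code{SignatureSet}.
#' @export
signatureSet <- function(setting, liver_specific = character(),
                         tumor_associated = character(),
                         tumor_specific = character()) {
    new("SignatureSet", setting = as.character(setting),
        liver_specific = sort(unique(as.character(liver_specific))),
        tumor_associated = sort(unique(as.character(tumor_associated))),
        tumor_specific = sort(unique(as.character(tumor_specific))))
}

setMethod("show", "SignatureSet", function(object) {
    cat(sprintf("SignatureSet [%s]\n", object@setting))
    cat(sprintf("  liver-specific:   %d genes\n",
                length(object@liver_specific)))
    cat(sprintf("  tumor-associated: %d genes\n",
                length(object@tumor_associated)))
    cat(sprintf("  tumor-specific:   %d genes\n",
                length(object@tumor_specific)))
})

#' @describeIn SignatureSet-class setting label accessor.
#' @param x a \code{SignatureSet}.
#' @export
setGeneric("setting", function(x) standardGeneric("setting"))

#' @rdname SignatureSet-class
#' @export
setMethod("setting", "SignatureSet", function(x) x@setting)

#' @describeIn SignatureSet-class liver-specific gene set accessor.
#' @export
setGeneric("liverSpecific", function(x) standardGeneric("liverSpecific"))

#' @rdname SignatureSet-class
#' @export
setMethod("liverSpecific", "SignatureSet", function(x) x@liver_specific)

#' @describeIn SignatureSet-class tumor-associated gene set accessor.
#' @export
setGeneric("tumorAssociated", function(x) standardGeneric("tumorAssociated"))

#' @rdname SignatureSet-class
#' @export
setMethod("tumorAssociated", "SignatureSet", function(x) x@tumor_associated)

#' @describeIn SignatureSet-class tumor-specific gene set accessor.
#' @export
setGeneric("tumorSpecific", function(x) standardGeneric("tumorSpecific"))

#' @rdname SignatureSet-class
#' @export
setMethod("tumorSpecific", "SignatureSet", function(x) x@tumor_specific)
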