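## Step 2: screening of step-1 genes against a multi-tissue normal panel
## and rule-based classification into liver-specific, tumor-associated and
## tumor-specific signatures.

#' Build a per-probe fold-change profile against the normal panel
#'
#' For every probe computes a reference (by default the mean over all
#' non-tumor samples: the multi-tissue panel plus normal liver -- a
#' tumor-specific gene must exceed normal liver too, and including liver
#' in the reference enforces that) and log2 fold changes of (i) each tumor
#' sample and (ii) each normal tissue type's mean against it.  The
#' normal-liver contrast is computed against the tissue-only reference,
#' since the liver-specific rule asks whether liver itself is elevated
#' over the other tissues.
#'
#' @param x cohort \code{SummarizedExperiment} (normalized, assay 1 on
#'   log2 scale) with \code{colData} columns \code{group} and
#'   \code{tissue_type}.
#' @param tumor_ids tumor sample ids to profile (a subset, for
#'   etiology-stratified runs); defaults to all tumor samples.
#' @param include_liver_in_reference include normal liver in the shared
#'   reference (default TRUE).
#' @return A [TissueProfile-class].
#' @export
buildTissueProfile <- function(x, tumor_ids = NULL,
                               include_liver_in_reference = TRUE) {
    stopifnot(is(x, "SummarizedExperiment"))
    cd <- colData(x)
    mat <- assay(x, 1L)
    all_tumor <- rownames(cd)[cd$group == "tumor"]
    if (is.null(tumor_ids)) tumor_ids <- all_tumor
    if (!all(tumor_ids %in% all_tumor))
        stop("'tumor_ids' must be tumor samples")
    liver_ids <- rownames(cd)[cd$group == "normal_liver"]
    tissue_samples <- rownames(cd)[cd$group == "normal_tissue"]
    types <- unique(cd$tissue_type[cd$group == "normal_tissue"])
    if (length(types) < 2L)
        stop("need >= 2 normal tissue types for the panel screen")
    per_type <- split(tissue_samples,
                      cd[tissue_samples, "tissue_type"])[types]
    empty <- vapply(per_type, length, integer(1)) == 0L
    if (any(empty))
        stop("tissue type(s) with zero samples: ",
             paste(types[empty], collapse = ", "))

    tissue_ref <- rowMeans(mat[, tissue_samples, drop = FALSE])
    ref_ids <- if (include_liver_in_reference)
        c(tissue_samples, liver_ids) else tissue_samples
    reference <- rowMeans(mat[, ref_ids, drop = FALSE])

    tumor_lfc <- mat[, tumor_ids, drop = FALSE] - reference
    tissue_lfc <- vapply(per_type, function(ids)
        rowMeans(mat[, ids, drop = FALSE]) - reference,
        numeric(nrow(mat)))
    liver_mean <- if (length(liver_ids))
        rowMeans(mat[, liver_ids, drop = FALSE]) else
        rep(NA_real_, nrow(mat))
    new("TissueProfile",
        probe_ids = rownames(mat),
        gene_symbols = as.character(rowData(x)$gene_symbol),
        tumor_lfc = tumor_lfc,
        tissue_lfc = tissue_lfc,
        liver_lfc = unname(liver_mean - tissue_ref),
        reference = unname(reference),
        tissue_reference = unname(tissue_ref),
        tumor_vs_tissue_lfc =
            unname(rowMeans(mat[, tumor_ids, drop = FALSE]) - tissue_ref))
}

## Average probe-level rows of a matrix/vector per gene symbol; returns a
## genes x k matrix with gene rownames.  Redundant probes of one gene
## carry the same signal plus independent noise, so the mean is the
## natural collapse for classification.
.by_gene <- function(v, genes) {
    m <- if (is.matrix(v)) v else matrix(v, ncol = 1L)
    rowsum(m, genes) / as.vector(table(genes)[sort(unique(genes))])
}

#' Classify liver-specific genes
#'
#' A gene is liver-specific when it is elevated over the non-liver tissue
#' reference both in tumors and in normal liver (organ identity rather
#' than tumor biology): gene-level mean tumor log2FC > \code{log2fc_up}
#' AND normal-liver log2FC > \code{log2fc_up}, both against the tissue-only
#' reference.  Evaluated on the full gene universe of the profile, not
#' only step-1 hits (a liver-identity gene is typically flat in the
#' tumor-vs-liver contrast).
#'
#' @param profile a [TissueProfile-class].
#' @param thresholds a [SignatureThresholds-class].
#' @return Character vector of gene symbols.
#' @export
classifyLiverSpecific <- function(profile,
                                  thresholds = signatureThresholds()) {
    validObject(thresholds)
    g <- profile@gene_symbols
    tum <- .by_gene(profile@tumor_vs_tissue_lfc, g)[, 1L]
    liv <- .by_gene(profile@liver_lfc, g)[, 1L]
    sort(names(which(tum > thresholds@log2fc_up &
                     liv > thresholds@log2fc_up)))
}

#' Classify tumor-associated genes
#'
#' Restricted to genes with at least one probe among the step-1
#' upregulated probes.  In the default \code{"average"} mode a gene
#' qualifies when its gene-level mean tumor log2FC against the shared
#' panel reference exceeds \code{log2fc_up}; in \code{"majority"} mode it
#' must exceed \code{log2fc_up} over more than \code{majority_frac} of
#' individual tissue types.
#'
#' @param profile a [TissueProfile-class].
#' @param up_probes step-1 upregulated probe ids (see [selectDE()]).
#' @param thresholds a [SignatureThresholds-class].
#' @param mode \code{"average"} (default) or \code{"majority"}.
#' @return Character vector of gene symbols.
#' @export
classifyTumorAssociated <- function(profile, up_probes,
                                    thresholds = signatureThresholds(),
                                    mode = c("average", "majority")) {
    mode <- match.arg(mode)
    validObject(thresholds)
    if (!length(up_probes)) return(character())
    keep <- profile@probe_ids %in% up_probes
    universe <- unique(profile@gene_symbols[keep])
    g <- profile@gene_symbols
    if (mode == "average") {
        tum <- rowMeans(.by_gene(profile@tumor_lfc, g))
        hits <- names(which(tum > thresholds@log2fc_up))
    } else {
        tum_mean <- rowMeans(.by_gene(profile@tumor_lfc, g))
        tis <- .by_gene(profile@tissue_lfc, g)
        over <- rowMeans(tum_mean - tis > thresholds@log2fc_up)
        hits <- names(which(over > thresholds@majority_frac))
    }
    sort(intersect(hits, universe))
}

#' Classify tumor-specific genes
#'
#' Operates on tumor-associated genes only.  A gene is kept iff
#' \enumerate{
#'   \item it is upregulated (gene-level log2FC > \code{log2fc_up}) in
#'     strictly more than \code{tumor_frac_min} of tumor samples, and
#'   \item strictly fewer than \code{tissue_frac_max} of normal tissue
#'     types express it, where a tissue type counts as expressing the gene
#'     when its mean exceeds the panel reference by more than
#'     \code{tissue_up_log2fc}.
#' }
#' Both inequalities are strict (a gene elevated in exactly 80% of tumors
#' is rejected).
#'
#' @param profile a [TissueProfile-class].
#' @param tumor_associated gene symbols from [classifyTumorAssociated()].
#' @param thresholds a [SignatureThresholds-class].
#' @return Character vector of gene symbols (a subset of
#'   \code{tumor_associated}).
#' @export
classifyTumorSpecific <- function(profile, tumor_associated,
                                  thresholds = signatureThresholds()) {
    validObject(thresholds)
    if (!length(tumor_associated)) return(character())
    g <- profile@gene_symbols
    tum <- .by_gene(profile@tumor_lfc, g)
    tis <- .by_gene(profile@tissue_lfc, g)
    tum <- tum[tumor_associated, , drop = FALSE]
    tis <- tis[tumor_associated, , drop = FALSE]
    tumor_frac <- rowMeans(tum > thresholds@log2fc_up)
    tissue_frac <- rowMeans(tis > thresholds@tissue_up_log2fc)
    sort(tumor_associated[tumor_frac > thresholds@tumor_frac_min &
                          tissue_frac < thresholds@tissue_frac_max])
}

#' Collapse a probe set to unique gene symbols
#'
#' Redundant probes make unique-gene counts smaller than probe counts.
#' With \code{mode = "any"} (default) a gene is included when at least one
#' of its probes is in the set; with \code{mode = "all"} every probe of
#' the gene (within the map) must be in the set.
#'
#' @param probe_set character vector of probe ids.
#' @param map named probe-to-gene vector (see [readProbeGeneMap()]).
#' @param mode \code{"any"} or \code{"all"}.
#' @return Sorted character vector of unique gene symbols.
#' @export
collapseToGenes <- function(probe_set, map, mode = c("any", "all")) {
    mode <- match.arg(mode)
    if (!length(probe_set)) return(character())
    unmapped <- setdiff(probe_set, names(map))
    if (length(unmapped))
        stop("unmapped probe(s): ", paste(unmapped, collapse = ", "))
    if (mode == "any") return(sort(unique(unname(map[probe_set]))))
    genes <- unique(unname(map[probe_set]))
    keep <- vapply(genes, function(gn)
        all(names(map)[map == gn] %in% probe_set), logical(1))
    sort(genes[keep])
}

#' Venn partition of signatures across analysis settings
#'
#' Enumerates every cell of the Venn partition of one signature category
#' across two or more settings.  Cells are disjoint and their union is the
#' union of the input sets.
#'
#' @param sets a list of [SignatureSet-class] objects, or a named list of
#'   gene-symbol vectors.
#' @param category which signature to compare when \code{sets} holds
#'   \code{SignatureSet}s.
#' @return \code{data.frame} with columns \code{cell} (ampersand-joined
#'   setting labels), \code{n_sets} (how many sets the cell belongs to),
#'   \code{n_genes} and \code{genes} (comma-joined members); one row per
#'   non-empty membership pattern, plus attribute \code{"union_size"}.
#' @examples
#' signatureOverlap(list(A = c("X", "Y"), B = c("Y", "Z")))
#' @export
signatureOverlap <- function(sets,
                             category = c("tumor_specific",
                                          "tumor_associated",
                                          "liver_specific")) {
    category <- match.arg(category)
    if (length(sets) < 2L) stop("need >= 2 sets to overlap")
    if (is(sets[[1L]], "SignatureSet")) {
        labels <- vapply(sets, setting, character(1))
        sets <- lapply(sets, slot, category)
        names(sets) <- labels
    }
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        stop("sets must be named")
    universe <- sort(unique(unlist(sets)))
    member <- vapply(sets, function(s) universe %in% s,
                     logical(length(universe)))
    if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
    pattern <- apply(member, 1L, function(row)
        paste(names(sets)[row], collapse = "&"))
    k <- length(sets)
    cells <- unlist(lapply(seq_len(2^k - 1L), function(bits) {
        inc <- as.logical(bitwAnd(bits, 2^(seq_len(k) - 1L)))
        paste(names(sets)[inc], collapse = "&")
    }))
    n_sets_of <- vapply(strsplit(cells, "&", fixed = TRUE), length,
                        integer(1))
    genes_of <- lapply(cells, function(cl) universe[pattern == cl])
    out <- data.frame(
        cell = cells,
        n_sets = n_sets_of,
        n_genes = lengths(genes_of),
        genes = vapply(genes_of, paste, character(1), collapse = ","),
        stringsAsFactors = FALSE)
    attr(out, "union_size") <- length(universe)
    out
}

#' Run the full two-step signature discovery on a cohort
#'
#' Step 1 contrasts tumor samples against normal liver (fold-change,
#' t-test and presence gates); step 2 profiles the cohort against the
#' multi-tissue panel and classifies genes.  With
#' \code{stratify = TRUE}, the two steps are re-run on the HBV- and
#' HCV-etiology tumor subsets (normal panels shared), yielding three
#' \code{SignatureSet}s.  Liver-specific genes are removed from the
#' tumor-associated set before the tumor-specific rule so the three
#' categories are disjoint where required.
#'
#' @param x normalized cohort \code{SummarizedExperiment}.
#' @param de_thresholds a [DiffExpThresholds-class].
#' @param sig_thresholds a [SignatureThresholds-class].
#' @param stratify also run HBV/HCV-stratified settings.
#' @param variance_mode t-test variance model for step 1.
#' @return Named list of results, one per setting (\code{"HCC"}, and if
#'   stratified \code{"HBV-HCC"}, \code{"HCV-HCC"}); each element has
#'   \code{signatures} (a [SignatureSet-class]), \code{de} (the
#'   [selectDE()] output), \code{profile} (the [TissueProfile-class]) and
#'   \code{funnel} (named gate counts).
#' @export
discoverSignatures <- function(x, de_thresholds = diffExpThresholds(),
                               sig_thresholds = signatureThresholds(),
                               stratify = TRUE,
                               variance_mode = "pooled") {
    stopifnot(is(x, "SummarizedExperiment"))
    cd <- colData(x)
    liver_ids <- rownames(cd)[cd$group == "normal_liver"]
    if (length(liver_ids) < 2L)
        stop("need >= 2 normal liver samples for the step-1 contrast")
    settings <- list(HCC = rownames(cd)[cd$group == "tumor"])
    if (stratify) {
        for (et in c("HBV", "HCV")) {
            ids <- rownames(cd)[cd$group == "tumor" &
                                !is.na(cd$etiology) & cd$etiology == et]
            if (length(ids) >= 2L)
                settings[[paste0(et, "-HCC")]] <- ids
        }
    }
    map <- setNames(rowData(x)$gene_symbol, rownames(x))
    lapply(settings, function(tumor_ids) {
        rec <- twoGroupTTest(x, tumor_ids, liver_ids,
                             variance_mode = variance_mode, map = map)
        de <- selectDE(rec, de_thresholds)
        profile <- buildTissueProfile(x, tumor_ids)
        ta <- classifyTumorAssociated(profile, de$up_probes,
                                      sig_thresholds)
        ls <- classifyLiverSpecific(profile, sig_thresholds)
        ta <- setdiff(ta, ls)
        ts <- classifyTumorSpecific(profile, ta, sig_thresholds)
        sig <- signatureSet(
            setting = names(which(vapply(settings, identical,
                                         logical(1), tumor_ids))),
            liver_specific = ls, tumor_associated = ta,
            tumor_specific = ts)
        funnel <- list(
            probes_total = nrow(rec),
            probes_testable = sum(rec$testable),
            probes_up = length(de$up_probes),
            probes_down = length(de$down_probes),
            genes_up = length(collapseToGenes(de$up_probes, map)),
            genes_tumor_associated = length(ta),
            genes_liver_specific = length(ls),
            genes_tumor_specific = length(ts))
        list(signatures = sig, de = de, profile = profile,
             funnel = funnel)
    })
}

#' Per-gene signature summary table
#'
#' One row per classified gene: setting, category, gene-level mean tumor
#' log2FC, fraction of tumor samples elevated and fraction of tissue
#' types expressing the gene (the quantities the classification rules
#' gate on).
#'
#' @param set a [SignatureSet-class].
#' @param profile the matching [TissueProfile-class].
#' @param thresholds the [SignatureThresholds-class] used.
#' @return \code{data.frame} sorted by category then gene.
#' @export
signatureTable <- function(set, profile,
                           thresholds = signatureThresholds()) {
    g <- profile@gene_symbols
    tum <- .by_gene(profile@tumor_lfc, g)
    tis <- .by_gene(profile@tissue_lfc, g)
    rows <- lapply(c("liver_specific", "tumor_associated",
                     "tumor_specific"), function(cat) {
        genes <- slot(set, cat)
        if (!length(genes)) return(NULL)
        data.frame(
            gene = genes, setting = setting(set), category = cat,
            mean_log2fc = round(rowMeans(tum[genes, , drop = FALSE]), 6L),
            tumor_frac = round(rowMeans(
                tum[genes, , drop = FALSE] > thresholds@log2fc_up), 6L),
            tissue_frac = round(rowMeans(
                tis[genes, , drop = FALSE] > thresholds@tissue_up_log2fc),
                6L),
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Curated reference signature gene lists
#'
#' Loads the three curated tumor-specificity signature lists distributed
#' with the package (settings \code{HCC}, \code{HBV-HCC},
#' \code{HCV-HCC}): HCC-specific (52 genes), HBV-HCC-specific (3 genes)
#' and HCV-HCC-specific (31 genes), for use as reference sets in overlap
#' analyses.
#'
#' @return Named list of gene-symbol vectors.
#' @examples
#' lengths(referenceSignatures())
#' @export
referenceSignatures <- function() {
    path <- system.file("extdata", "reference_signatures.tsv",
                        package = "TumorSpecScreen", mustWork = TRUE)
    df <- utils::read.delim(path, comment.char = "#",
                            colClasses = "character")
    split(toupper(df$gene), df$setting)[c("HCC", "HBV-HCC", "HCV-HCC")]
}
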