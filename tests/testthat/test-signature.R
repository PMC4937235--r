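## A hand-built profile: 1 probe per gene, explicit fold-change matrices,
## for boundary cases the simulator cannot hit exactly.
manual_profile <- function(tumor_lfc, tissue_lfc, liver_lfc = NULL,
                           tum_vs_tis = NULL) {
    genes <- rownames(tumor_lfc)
    n <- length(genes)
    new("TissueProfile",
        probe_ids = paste0(genes, "_p"), gene_symbols = genes,
        tumor_lfc = tumor_lfc, tissue_lfc = tissue_lfc,
        liver_lfc = liver_lfc %||% rep(0, n),
        reference = rep(0, n), tissue_reference = rep(0, n),
        tumor_vs_tissue_lfc = tum_vs_tis %||% rowMeans(tumor_lfc))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("constant matrices give all-zero profiles", {
    se <- tiny_cohort(noise_sd = 0, normalize = FALSE)
    SummarizedExperiment::assays(se)[[1]][] <- 5
    prof <- buildTissueProfile(se)
    expect_true(all(prof@tumor_lfc == 0))
    expect_true(all(prof@tissue_lfc == 0))
    expect_true(all(prof@liver_lfc == 0))
    expect_equal(unique(prof@reference), 5)
})

test_that("zero-noise profiles match a direct recomputation from means", {
    se <- simulateExpressionCohort(tiny_config(noise_sd = 0))
    mat <- SummarizedExperiment::assay(se)
    cd <- SummarizedExperiment::colData(se)
    prof <- buildTissueProfile(se)
    tum <- sample_ids_of(se, "tumor")
    non <- setdiff(colnames(mat), tum)
    ref <- rowMeans(mat[, non])
    ## tumor per-sample fold changes against the all-non-tumor reference
    expect_equal(prof@tumor_lfc, mat[, tum] - ref)
    ## liver contrast against the tissue-only reference
    tis <- sample_ids_of(se, "normal_tissue")
    liv <- sample_ids_of(se, "normal_liver")
    expect_equal(prof@liver_lfc,
                 unname(rowMeans(mat[, liv]) - rowMeans(mat[, tis])))
    ## planted tumor-specific gene: tumor lfc = delta minus reference shift
    rd <- SummarizedExperiment::rowData(se)
    g <- planted_genes(se, "tumor_specific")[1]
    pr <- rownames(se)[rd$gene_symbol == g][1]
    expect_equal(unique(round(prof@tumor_lfc[pr, ], 10)), 3)
    ls <- planted_genes(se, "liver_specific")[1]
    prl <- rownames(se)[rd$gene_symbol == ls][1]
    expect_true(prof@liver_lfc[which(rownames(se) == prl)] > 0)
    expect_error(buildTissueProfile(se, tumor_ids = c(tum[1], liv[1])),
                 "tumor")
})

test_that("planted classes are classified correctly on a noisy cohort", {
    se <- tiny_cohort(seed = 4L, noise_sd = 0.3)
    tum <- sample_ids_of(se, "tumor")
    liv <- sample_ids_of(se, "normal_liver")
    sel <- selectDE(twoGroupTTest(se, tum, liv))
    prof <- buildTissueProfile(se)
    thr <- signatureThresholds()
    ls <- classifyLiverSpecific(prof, thr)
    ta <- setdiff(classifyTumorAssociated(prof, sel$up_probes, thr), ls)
    ts <- classifyTumorSpecific(prof, ta, thr)
    truth <- truthLabels(se)
    expect_setequal(ls, names(truth)[truth == "liver_specific"])
    expect_setequal(ta, names(truth)[truth %in%
        c("tumor_specific", "tumor_associated")])
    expect_setequal(ts, names(truth)[truth == "tumor_specific"])
    ## planted tumor-associated genes (elevated in 20% of tissues) are
    ## rejected by the tissue screen, never by the tumor-fraction rule
    expect_length(intersect(ts, names(truth)[truth == "tumor_associated"]),
                  0)
    expect_true(all(ts %in% ta))
    ## empty inputs
    expect_identical(classifyTumorAssociated(prof, character(), thr),
                     character())
    expect_identical(classifyTumorSpecific(prof, character(), thr),
                     character())
})

test_that("tumor-specific thresholds are strict inequalities", {
    ## 10 tumor samples, 10 tissue types; gene A elevated in exactly 80%
    ## of tumors (boundary -> rejected); gene B in 90% (passes); gene C
    ## expressed in exactly 10% of tissues (boundary -> rejected)
    tum <- rbind(A = c(rep(2, 8), 0, 0),
                 B = c(rep(2, 9), 0),
                 C = rep(2, 10))
    tis <- rbind(A = rep(-1, 10),
                 B = rep(-1, 10),
                 C = c(1, rep(-1, 9)))
    prof <- manual_profile(tum, tis)
    ts <- classifyTumorSpecific(prof, c("A", "B", "C"),
                                signatureThresholds())
    expect_identical(ts, "B")
})

test_that("probe-to-gene collapse honors its mode and the pigeonhole bound", {
    map <- c(p1 = "GENE1", p2 = "GENE1", p3 = "GENE2")
    expect_identical(collapseToGenes("p1", map, "any"), "GENE1")
    expect_identical(collapseToGenes("p1", map, "all"), character())
    expect_identical(collapseToGenes(c("p1", "p2"), map, "all"), "GENE1")
    expect_error(collapseToGenes("p9", map), "p9")
    set.seed(8)
    for (i in 1:20) {
        n <- sample(5:30, 1)
        rmap <- setNames(paste0("G", sample(1:10, n, TRUE)),
                         paste0("p", 1:n))
        pick <- sample(names(rmap), sample(1:n, 1))
        expect_lte(length(collapseToGenes(pick, rmap)), length(pick))
    }
})

test_that("signature overlaps match a brute-force bitmask enumeration", {
    ## printed reference lists: sizes and the common three-gene core
    refs <- referenceSignatures()
    ov <- signatureOverlap(refs)
    three <- ov$genes[ov$cell == "HCC&HBV-HCC&HCV-HCC"]
    expect_identical(sort(strsplit(three, ",")[[1]]),
                     c("CDKN2A", "IGF2BP3", "ZNF623"))
    expect_equal(sum(ov$n_genes), attr(ov, "union_size"))

    ## identical sets: everything in the full intersection
    ov2 <- signatureOverlap(list(X = c("A", "B"), Y = c("A", "B")))
    expect_equal(ov2$n_genes[ov2$cell == "X&Y"], 2)
    expect_true(all(ov2$n_genes[ov2$cell != "X&Y"] == 0))

    ## random sets against an independent membership-bitmask oracle
    set.seed(13)
    for (i in 1:10) {
        sets <- lapply(1:3, function(j)
            sample(paste0("G", 1:15), sample(3:10, 1)))
        names(sets) <- c("S1", "S2", "S3")
        ov3 <- signatureOverlap(sets)
        uni <- sort(unique(unlist(sets)))
        mask <- sapply(uni, function(g) sum(2^(0:2) *
            vapply(sets, function(s) g %in% s, logical(1))))
        for (r in seq_len(nrow(ov3))) {
            inc <- names(sets) %in% strsplit(ov3$cell[r], "&")[[1]]
            expect_equal(ov3$n_genes[r], sum(mask == sum(2^(0:2) * inc)))
        }
        expect_equal(sum(ov3$n_genes), length(uni))
    }
})

test_that("signature sets enforce their containment invariants", {
    expect_error(signatureSet("X", tumor_associated = "A",
                              tumor_specific = c("A", "B")), "subset")
    expect_error(signatureSet("X", liver_specific = "A",
                              tumor_associated = c("A", "B")), "disjoint")
    s <- signatureSet("HCC", liver_specific = c("L1", "l1", "L1"),
                      tumor_associated = c("T2", "T1"),
                      tumor_specific = "T1")
    expect_identical(tumorAssociated(s), c("T1", "T2"))
    expect_identical(setting(s), "HCC")
})

test_that("a pan-etiology gene lands in every stratified tumor-specific set", {
    se <- tiny_cohort(seed = 6L)
    res <- discoverSignatures(se)
    expect_named(res, c("HCC", "HBV-HCC", "HCV-HCC"))
    truth <- truthLabels(se)
    ts_truth <- names(truth)[truth == "tumor_specific"]
    for (nm in names(res)) {
        sig <- res[[nm]]$signatures
        expect_true(all(ts_truth %in% tumorSpecific(sig)))
        expect_true(all(tumorSpecific(sig) %in% tumorAssociated(sig)))
    }
    ov <- signatureOverlap(lapply(res, `[[`, "signatures"))
    common <- ov$genes[ov$n_sets == 3 & ov$n_genes > 0]
    expect_true(all(ts_truth %in% strsplit(common, ",")[[1]]))
})

test_that("tumor-specific sensitivity does not increase with noise", {
    sweep_sens <- function(noise) {
        mean(vapply(1:3, function(s) {
            se <- tiny_cohort(seed = s, noise_sd = noise)
            res <- discoverSignatures(se, stratify = FALSE)
            truth <- truthLabels(se)
            ts <- names(truth)[truth == "tumor_specific"]
            mean(ts %in% tumorSpecific(res$HCC$signatures))
        }, numeric(1)))
    }
    sens <- vapply(c(0.3, 1.0, 2.0), sweep_sens, numeric(1))
    expect_true(all(diff(sens) <= 0))
    expect_equal(sens[1], 1)
})
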