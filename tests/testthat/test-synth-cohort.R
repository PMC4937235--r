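test_that("config validation names the offending field", {
    expect_error(cohortConfig(n_tumor = 10, n_hbv = 5, n_hcv = 6),
                 "n_hbv")
    expect_error(cohortConfig(delta = -1), "delta")
    expect_error(cohortConfig(noise_sd = -0.1), "noise_sd")
    expect_error(cohortConfig(probes_per_gene_range = c(0, 2)),
                 "probes_per_gene_range")
    expect_error(cohortConfig(n_genes = 10), "n_planted")
})

test_that("zero-noise planted effects are exact and runs are deterministic", {
    cfg <- tiny_config(noise_sd = 0, delta = 3)
    se <- simulateExpressionCohort(cfg)
    mat <- SummarizedExperiment::assay(se)
    tum <- sample_ids_of(se, "tumor")
    non <- setdiff(colnames(mat), tum)
    rd <- SummarizedExperiment::rowData(se)
    for (gene in planted_genes(se, "tumor_specific")) {
        pr <- rownames(se)[rd$gene_symbol == gene]
        expect_equal(unname(rowMeans(mat[pr, tum, drop = FALSE]) -
                            rowMeans(mat[pr, non, drop = FALSE])),
                     rep(3, length(pr)))
    }
    liv <- sample_ids_of(se, "normal_liver")
    tis <- sample_ids_of(se, "normal_tissue")
    for (gene in planted_genes(se, "liver_specific")) {
        pr <- rownames(se)[rd$gene_symbol == gene]
        expect_equal(unname(rowMeans(mat[pr, c(tum, liv), drop = FALSE]) -
                            rowMeans(mat[pr, tis, drop = FALSE])),
                     rep(3, length(pr)))
    }
    for (gene in planted_genes(se, "down_in_tumor")) {
        pr <- rownames(se)[rd$gene_symbol == gene]
        expect_equal(unname(rowMeans(mat[pr, tum, drop = FALSE]) -
                            rowMeans(mat[pr, liv, drop = FALSE])),
                     rep(-3, length(pr)))
    }
    ## bit-identical on re-simulation
    expect_identical(mat, SummarizedExperiment::assay(
        simulateExpressionCohort(cfg)))
})

test_that("probe redundancy invariants hold", {
    se <- tiny_cohort(normalize = FALSE)
    rd <- SummarizedExperiment::rowData(se)
    expect_gte(nrow(se), length(unique(rd$gene_symbol)))
    expect_false(anyDuplicated(rd$probe_id) > 0)
    ## every probe maps to exactly one gene
    expect_true(all(table(rd$probe_id) == 1L))
    ppg <- table(rd$gene_symbol)
    expect_true(all(ppg >= 2L & ppg <= 4L))
})

test_that("noise level matches a Monte-Carlo moment estimate", {
    cfg <- cohortConfig(n_tumor = 240L, n_hbv = 120L, n_hcv = 120L,
                        n_normal_liver = 4L, n_tissue_types = 2L,
                        samples_per_tissue = 2L, n_genes = 40L,
                        probes_per_gene_range = c(1L, 1L),
                        n_planted = c(tumor_specific = 0L),
                        noise_sd = 0.5, seed = 11L)
    se <- simulateExpressionCohort(cfg)
    mat <- SummarizedExperiment::assay(se)[, sample_ids_of(se, "tumor")]
    sds <- apply(mat, 1L, sd)
    se3 <- 3 * sd(sds) / sqrt(length(sds))
    expect_lt(abs(mean(sds) - 0.5), se3 + 0.01)
})

test_that("class separation holds at delta 3 and low noise", {
    se <- tiny_cohort(seed = 5L, normalize = FALSE, noise_sd = 0.3)
    mat <- SummarizedExperiment::assay(se)
    tum <- sample_ids_of(se, "tumor")
    non <- setdiff(colnames(mat), tum)
    rd <- SummarizedExperiment::rowData(se)
    contrast <- rowMeans(mat[, tum]) - rowMeans(mat[, non])
    gene_contrast <- tapply(contrast, rd$gene_symbol, mean)
    truth <- truthLabels(se)
    bg <- abs(gene_contrast[names(truth)[truth == "background"]])
    for (cl in c("tumor_specific", "tumor_associated", "down_in_tumor")) {
        planted <- abs(gene_contrast[names(truth)[truth == cl]])
        expect_true(all(planted - max(bg) >= 3 / 2))
    }
})

test_that("count simulation: Poisson limit, null genes and planted ratio", {
    cfg <- tiny_config()
    truth <- truthLabels(simulateExpressionCohort(cfg))

    ## dispersion 0 with fixed library depth: variance/mean ratio ~ 1
    cse <- simulateCountCohort(cfg, truth, n_patients = 500L,
                               dispersion = 0, patient_sdlog = 0,
                               library_sdlog = 0, seed = 3L)
    counts <- SummarizedExperiment::assay(cse)
    nor <- S4Vectors::metadata(cse)$design$normal
    bg <- names(truth)[truth == "background"][1:5]
    for (gene in bg) {
        x <- counts[gene, nor]          # 500 i.i.d. draws at fixed mu
        ratio <- var(x) / mean(x)
        expect_lt(abs(ratio - 1), 3 * sqrt(2 / length(x)))
    }

    ## paired mean log2 ratio: ~0 for null genes, ~delta for planted
    cse <- simulateCountCohort(cfg, truth, n_patients = 50L,
                               dispersion = 0.1, seed = 4L)
    counts <- SummarizedExperiment::assay(cse)
    des <- S4Vectors::metadata(cse)$design
    lr <- log2(counts[, des$tumor] + 0.5) - log2(counts[, des$normal] + 0.5)
    m <- rowMeans(lr)
    s3 <- 3 * apply(lr, 1L, sd) / sqrt(ncol(lr))
    bg_all <- names(truth)[truth == "background"]
    expect_true(mean(abs(m[bg_all]) <= s3[bg_all]) > 0.95)
    ts <- names(truth)[truth == "tumor_specific"]
    expect_true(all(abs(m[ts] - 3) <= s3[ts] + 0.1))

    expect_error(simulateCountCohort(cfg, truth, n_patients = 1L),
                 "pair")
    expect_error(simulateCountCohort(cfg, truth, dispersion = -1),
                 "dispersion")
})

test_that("cohort serialization round-trips through the TSV formats", {
    cfg <- tiny_config(seed = 9L)
    se <- simulateExpressionCohort(cfg)
    truth <- truthLabels(se)
    cse <- simulateCountCohort(cfg, truth, n_patients = 3L, seed = 10L)
    dir <- make_tempdir()
    paths <- writeCohort(se, dir, counts_se = cse)
    mat <- readExpressionMatrix(paths[["expression"]])
    expect_equal(mat, SummarizedExperiment::assay(se), tolerance = 1e-10)
    sheet <- readSampleSheet(paths[["sample_sheet"]], mat)
    expect_identical(sheet$group,
                     as.character(SummarizedExperiment::colData(se)$group))
    map <- readProbeGeneMap(paths[["probe_map"]], rownames(mat))
    expect_identical(unname(map[rownames(mat)]),
                     as.character(SummarizedExperiment::rowData(se)$gene_symbol))
    counts <- readCountMatrix(paths[["counts"]])
    expect_identical(counts, SummarizedExperiment::assay(cse))
})
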