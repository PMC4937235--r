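## Shared fixtures: a scaled-down cohort keeping the default structure
## (two etiologies, normal liver, a multi-type tissue panel, redundant
## probes) but small enough to simulate in milliseconds.

tiny_config <- function(seed = 1L, noise_sd = 0.3, delta = 3, ...) {
    cohortConfig(n_tumor = 14L, n_hbv = 6L, n_hcv = 8L,
                 n_normal_liver = 6L, n_tissue_types = 12L,
                 samples_per_tissue = 2L, n_genes = 160L,
                 probes_per_gene_range = c(2L, 4L),
                 n_planted = c(tumor_specific = 6L, tumor_associated = 6L,
                               liver_specific = 6L, down_in_tumor = 4L),
                 delta = delta, noise_sd = noise_sd, seed = seed, ...)
}

tiny_cohort <- function(seed = 1L, normalize = TRUE, ...) {
    se <- simulateExpressionCohort(tiny_config(seed = seed, ...))
    if (normalize) quantileNormalize(se) else se
}

planted_genes <- function(se, class) {
    truth <- truthLabels(se)
    names(truth)[truth == class]
}

sample_ids_of <- function(se, group, etiology = NULL) {
    cd <- SummarizedExperiment::colData(se)
    keep <- cd$group == group
    if (!is.null(etiology))
        keep <- keep & !is.na(cd$etiology) & cd$etiology == etiology
    rownames(cd)[keep]
}

make_tempdir <- function() {
    d <- tempfile("tss")
    dir.create(d)
    d
}
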