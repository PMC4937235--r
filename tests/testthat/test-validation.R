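test_that("full-quantile count normalization satisfies its defining property", {
    ## proportional libraries collapse to identical columns
    m <- cbind(l1 = c(0L, 10L, 20L, 40L), l2 = c(0L, 20L, 40L, 80L))
    rownames(m) <- paste0("g", 1:4)
    qn <- normalizeCountsFullQuantile(m, pseudocount = 1)
    expect_equal(sort(qn[, 1]), sort(qn[, 2]))
    ## all-zero gene sits at the constant minimum across libraries
    expect_equal(qn["g1", 1], qn["g1", 2])
    expect_equal(unname(qn["g1", 1]), min(qn))

    ## 4x3 hand-computed order-statistic oracle
    m3 <- cbind(a = c(1L, 3L, 7L, 15L), b = c(0L, 1L, 3L, 7L),
                c = c(3L, 7L, 15L, 31L))
    rownames(m3) <- paste0("g", 1:4)
    l <- log2(m3 + 1)
    expected <- unname(rowMeans(apply(l, 2, sort)))   # all columns already sorted
    qn3 <- normalizeCountsFullQuantile(m3, 1)
    for (j in 1:3) expect_equal(unname(sort(qn3[, j])), expected)

    expect_error(normalizeCountsFullQuantile(m, pseudocount = 0), "zero")
    expect_error(normalizeCountsFullQuantile(-m), "non-negative")
})

test_that("paired test matches the closed-form one-sample t", {
    mk <- function(d) {
        n <- length(d)
        m <- rbind(g1 = c(5 + d, rep(5, n)))
        colnames(m) <- c(paste0("P", 1:n, "_T"), paste0("P", 1:n, "_N"))
        design <- data.frame(patient_id = paste0("P", 1:n),
                             tumor = paste0("P", 1:n, "_T"),
                             normal = paste0("P", 1:n, "_N"))
        pairedDE(m, design)
    }
    ## d == 0: p = 1, fc = 0
    r0 <- mk(c(0, 0, 0))
    expect_equal(r0$p_value, 1)
    expect_equal(r0$log2fc_seq, 0)
    ## zero-variance non-zero difference: limiting p = 0, flagged
    r1 <- mk(c(1, 1, 1, 1))
    expect_equal(r1$p_value, 0)
    expect_equal(r1$log2fc_seq, 1)
    expect_true(r1$zero_variance)
    ## closed form
    d <- c(2.1, 1.9, 2.0)
    r2 <- mk(d)
    ref <- t.test(d)
    expect_equal(r2$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r2$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(r2$log2fc_seq, mean(d))

    expect_error(mk(1), "pairs")
    m <- rbind(g1 = rep(1, 4))
    colnames(m) <- c("a", "b", "c", "d")
    expect_error(pairedDE(m, data.frame(patient_id = c("p1", "p2"),
                                        tumor = c("a", "a"),
                                        normal = c("b", "c"))),
                 "exactly one pair")
})

test_that("BH adjustment equals an independent step-up oracle", {
    bh_oracle <- function(p) {
        m <- length(p)
        o <- order(p)
        q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
        pmin(q_sorted, 1)[order(o)]
    }
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    set.seed(21)
    for (i in 1:20) {
        p <- runif(sample(1:50, 1))
        q <- bhAdjust(p)
        expect_equal(q, bh_oracle(p))
        ## q monotone in sorted p, and q >= p
        o <- order(p)
        expect_true(all(diff(q[o]) >= -1e-15))
        expect_true(all(q >= p - 1e-15))
    }
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("concordance handles identity, anti-correlation and small n", {
    genes <- paste0("g", 1:10)
    lfc <- seq(-2, 2.5, length.out = 10)
    rec <- S4Vectors::DataFrame(gene = genes, log2fc_seq = lfc,
                                p_value = rep(1e-6, 10))
    arr <- setNames(lfc, genes)
    out <- concordance(rec, arr, genes, fdr_max = 0.05)
    expect_equal(out$summary$r_squared, 1)
    expect_equal(out$summary$slope, 1)
    expect_equal(out$summary$n_confirmed_up, sum(lfc > 0))
    expect_equal(out$summary$n_confirmed_down, sum(lfc < 0))

    ## anti-correlated platforms: R^2 still 1 but nothing confirmed up --
    ## direction gating is deliberately separate from correlation
    out2 <- concordance(rec, setNames(-lfc, genes), genes)
    expect_equal(out2$summary$r_squared, 1)
    expect_equal(out2$summary$slope, -1)
    expect_equal(out2$summary$n_confirmed_up, 0)
    expect_equal(out2$summary$n_confirmed_down, 0)

    ## fewer than 3 usable genes: counts reported, regression empty
    out3 <- concordance(rec, arr[1:2], genes)
    expect_true(is.na(out3$summary$r_squared))
    expect_equal(out3$summary$n_tested, 10)
})

test_that("null count cohorts stay within the BH false-confirmation bound", {
    cfg <- cohortConfig(n_tumor = 4L, n_hbv = 2L, n_hcv = 2L,
                        n_normal_liver = 2L, n_tissue_types = 2L,
                        samples_per_tissue = 2L, n_genes = 2000L,
                        probes_per_gene_range = c(1L, 1L),
                        n_planted = c(tumor_specific = 0L), seed = 17L)
    truth <- setNames(rep("background", cfg@n_genes),
                      sprintf("GENE%04d", seq_len(cfg@n_genes)))
    cse <- simulateCountCohort(cfg, truth, n_patients = 9L,
                               dispersion = 0.1, seed = 18L)
    norm <- normalizeCountsFullQuantile(filterLowCounts(cse))
    rec <- pairedDE(norm)
    arr <- setNames(rep(1, nrow(norm)), rownames(norm))  # claim all up
    out <- concordance(rec, arr, rownames(norm), fdr_max = 0.05)
    rate <- mean(out$records$confirmed)
    n <- nrow(norm)
    expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("planted fold changes are recovered across count simulations", {
    cfg <- tiny_config()
    truth <- truthLabels(simulateExpressionCohort(cfg))
    ts <- names(truth)[truth == "tumor_specific"]
    means <- vapply(1:20, function(s) {
        cse <- simulateCountCohort(cfg, truth, n_patients = 9L,
                                   dispersion = 0.1, seed = 100L + s)
        counts <- SummarizedExperiment::assay(cse)
        des <- S4Vectors::metadata(cse)$design
        lr <- log2(counts[, des$tumor] + 1) - log2(counts[, des$normal] + 1)
        mean(rowMeans(lr)[ts])
    }, numeric(1))
    se3 <- 3 * sd(means) / sqrt(length(means))
    expect_lt(abs(mean(means) - 3), se3)
})
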