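test_that("delta-delta-Ct fold change matches direct evaluation", {
    ct <- data.frame(sample = "x", gene = rep(c("IL8", "GAPDH"), each = 2),
                     condition = rep(c("PMA", "vehicle"), 2), replicate = 1L,
                     ct = c(20, 25, 20, 20))
    fc <- ddctFoldChange(ct, "IL8", "PMA", "vehicle")
    expect_equal(fc$ddct, -5)
    expect_equal(fc$fold, 32)
    # identical delta-Ct in both conditions -> fold 1
    ct$ct <- c(25, 25, 20, 20)
    expect_equal(ddctFoldChange(ct, "IL8", "PMA", "vehicle")$fold, 1)
    # +1 cycle shift -> halving
    ct$ct <- c(26, 25, 20, 20)
    expect_equal(ddctFoldChange(ct, "IL8", "PMA", "vehicle")$fold, 0.5)
    expect_error(ddctFoldChange(ct, "IL8", "PMA", "vehicle",
                                referenceGene = "ACTB"), "no Ct values")
})

test_that("fold change is antisymmetric in the contrast and plate-offset invariant", {
    set.seed(41)
    for (i in 1:20) {
        ct <- data.frame(sample = "x",
                         gene = rep(c("T", "GAPDH"), each = 6),
                         condition = rep(rep(c("PMA", "vehicle"), each = 3), 2),
                         replicate = rep(1:3, 4),
                         ct = runif(12, 18, 30))
        f <- ddctFoldChange(ct, "T", "PMA", "vehicle")$fold
        frev <- ddctFoldChange(ct, "T", "vehicle", "PMA")$fold
        expect_equal(f * frev, 1)
        ctOff <- transform(ct, ct = ct + 2.75)
        expect_equal(ddctFoldChange(ctOff, "T", "PMA", "vehicle")$fold, f)
    }
})

test_that("induction filter is strict and the repression tiers nest", {
    expect_setequal(selectInduced(c(A = 489, B = 2.1, C = 1.9)), c("A", "B"))
    expect_identical(selectInduced(numeric(0)), character(0))
    expect_identical(selectInduced(c(A = 2.0)), character(0))  # "more than"
    expect_equal(repressionRatio(1070, 35), 30.57143, tolerance = 1e-6)
    expect_equal(repressionRatio(26, 8), 3.25)
    expect_error(repressionRatio(10, 0), "positive")
    # nesting invariant on random fold tables
    set.seed(42)
    for (i in 1:25) {
        genes <- paste0("G", 1:12)
        fc <- setNames(2^runif(12, -2, 9), genes)
        fi <- setNames(2^runif(12, -2, 9), genes)
        d <- deriveSignature(fc, fi)
        expect_true(all(d@repressed4 %in% d@repressed2))
        expect_true(all(d@repressed2 %in% d@induced))
    }
})

test_that("the published three-gene folds land in the expected tiers", {
    d <- deriveSignature(c(IL6 = 26, IL8 = 1070, PTGS2 = 212),
                         c(IL6 = 8, IL8 = 35, PTGS2 = 10))
    expect_setequal(d@induced, c("IL6", "IL8", "PTGS2"))
    expect_setequal(d@repressed2, c("IL6", "IL8", "PTGS2"))
    expect_setequal(d@repressed4, c("IL8", "PTGS2"))
    # equal folds -> ratio 1, excluded from both tiers
    d0 <- deriveSignature(c(A = 10), c(A = 10))
    expect_identical(d0@repressed2, character(0))
    # explicit ratios can replace the fold quotient
    dr <- deriveSignature(c(A = 10, B = 10), c(A = 1, B = 1),
                          ratios = c(A = 5, B = 1.2))
    expect_identical(dr@repressed4, "A")
    expect_identical(dr@repressed2, "A")
})

test_that("standard-curve interpolation recovers copy numbers", {
    curve <- fitStandardCurve(c(3, 5), c(30, 23.36))
    expect_equal(copiesFromStandardCurve(26.68, curve), 1e4, tolerance = 1e-9)
    # a fitted point maps back to its own copies on a perfectly linear curve
    expect_equal(copiesFromStandardCurve(30, curve), 1e3, tolerance = 1e-9)
    expect_error(fitStandardCurve(c(4, 4), c(30, 28)), "distinct")
    expect_error(fitStandardCurve(c(3, 5), c(23, 30)), "non-amplifying")
})

test_that("reporter activity normalizes out protein and copy number", {
    expect_equal(foldInduction(reporterActivity(300, 2, 10),
                               reporterActivity(100, 2, 10)), 3)
    expect_equal(reporterActivity(200, 1, 20), reporterActivity(400, 1, 40))
    expect_equal(foldInduction(reporterActivity(5, 1, 1),
                               reporterActivity(5, 1, 1)), 1)
    expect_error(reporterActivity(10, 0, 1), "protein")
    expect_error(reporterActivity(10, 1, -1), "copy number")
})

test_that("noiseless synthetic Ct tables return the programmed folds exactly", {
    ct <- exactCtTable(data.frame(sample = "L", gene = "IL8", fold = 32))
    expect_equal(ddctFoldChange(ct, "IL8", "PMA", "vehicle")$fold, 32)
    # replicate noise: recovered fold is unbiased on the log scale
    set.seed(99)
    errs <- replicate(200, {
        cfg <- simConfig(seed = sample.int(1e6, 1), ctNoise = 0.2,
                         ctReplicates = 3)
        ct <- genCtTable(cfg, data.frame(sample = "L", gene = "T", fold = 8))
        log2(ddctFoldChange(ct, "T", "PMA", "vehicle")$fold / 8)
    })
    expect_lt(abs(mean(errs)), 0.05)
    expect_gte(mean(abs(2^errs - 1) <= 0.25), 0.95)
})
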