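test_that("score model computes within-dataset medians and drops absent genes", {
    co <- toyCohort()
    model <- fitScoreModel(co, c("g1", "g2", "g3"))
    expect_equal(unname(medians(model)), c(2.5, 5, 5))
    expect_warning(m2 <- fitScoreModel(co, c("g1", "C3", "CSF1")),
                   "2 signature gene")
    expect_identical(geneSet(m2), "g1")
    expect_identical(m2@droppedGenes, c("C3", "CSF1"))
    expect_error(suppressWarnings(fitScoreModel(co, "nope")), "no signature gene")
    # case-insensitive symbol matching, cohort spelling preserved
    expect_identical(geneSet(fitScoreModel(co, "G1")), "g1")
})

test_that("hand-enumerated worked example scores (0,1,1,3)", {
    co <- toyCohort()
    res <- scoreSamples(co, fitScoreModel(co, c("g1", "g2", "g3")))
    expect_equal(unname(scores(res)), c(0L, 1L, 1L, 3L))
    # vote detail: medians 2.5/5/5; ties (g2 at 5, g3 at 0 or 10?) score 0
    expect_equal(unname(votes(res)["g2", ]), c(0L, 0L, 0L, 1L))
})

test_that("all-equal expression scores every sample 0 and ties vote 0", {
    m <- matrix(4, 3, 5, dimnames = list(paste0("g", 1:3), paste0("s", 1:5)))
    co <- ExpressionCohort(m)
    res <- scoreSamples(co, fitScoreModel(co, rownames(m)))
    expect_true(all(scores(res) == 0L))
    # one strictly maximal sample hits the upper bound
    m[, 5] <- 9
    co <- ExpressionCohort(m)
    res <- scoreSamples(co, fitScoreModel(co, rownames(m)))
    expect_equal(unname(scores(res)["s5"]), 3L)
})

test_that("scores are invariant under strictly increasing per-gene transforms", {
    set.seed(23)
    for (i in 1:10) {
        m <- matrix(rnorm(6 * 9), 6, 9,
                    dimnames = list(paste0("g", 1:6), paste0("s", 1:9)))
        co <- ExpressionCohort(m)
        base <- scores(scoreSamples(co, fitScoreModel(co, rownames(m))))
        trans <- list(function(x) exp(x), function(x) x^3,
                      function(x) 10 * x + 7, function(x) atan(x))
        m2 <- m
        for (g in seq_len(nrow(m)))
            m2[g, ] <- trans[[1 + (g %% length(trans))]](m[g, ])
        co2 <- ExpressionCohort(m2)
        expect_identical(
            scores(scoreSamples(co2, fitScoreModel(co2, rownames(m2)))), base)
    }
})

test_that("per-gene votes: exactly floor(n/2) with distinct values, fewer with ties", {
    set.seed(31)
    for (n in c(4, 5, 9, 12)) {
        m <- matrix(sample(seq_len(100), 3 * n), 3, n,
                    dimnames = list(paste0("g", 1:3), paste0("s", seq_len(n))))
        co <- ExpressionCohort(m)
        res <- scoreSamples(co, fitScoreModel(co, rownames(m)))
        expect_true(all(rowSums(votes(res)) == floor(n / 2)))
        expect_lte(mean(scores(res)), 3 / 2)
    }
    mTie <- matrix(c(1, 5, 5, 5), 1, 4,
                   dimnames = list("g", paste0("s", 1:4)))
    co <- ExpressionCohort(mTie)
    expect_lte(sum(votes(scoreSamples(co, fitScoreModel(co, "g")))), 2)
})

test_that("marker-gene split follows the at-or-below-cutoff convention", {
    m <- matrix(c(1, 2, 3, 4), 1, 4,
                dimnames = list("ING4", paste0("s", 1:4)))
    co <- ExpressionCohort(m)
    sp <- splitByMarkerGene(co)
    expect_identical(as.character(sp), c("low", "low", "high", "high"))
    expect_identical(splitByMarkerGene(co, cutoff = median(c(1, 2, 3, 4))), sp)
    expect_identical(as.character(splitByMarkerGene(co, cutoff = 3.5)),
                     c("low", "low", "low", "high"))
    mConst <- matrix(2, 1, 4, dimnames = dimnames(m))
    expect_warning(splitByMarkerGene(ExpressionCohort(mConst)), "degenerate")
    expect_error(splitByMarkerGene(co, "TP53"), "not in cohort")
})

test_that("pooled t comparison matches the textbook formula and t.test", {
    v <- c(1, 2, 3, 4, 5, 6)
    g <- factor(rep(c("a", "b"), each = 3))
    cmp <- compareGroupScores(v, g)
    expect_equal(abs(cmp$difference), 3)
    expect_equal(abs(cmp$t), 3.674235, tolerance = 1e-6)
    expect_equal(cmp$df, 4)
    expect_equal(cmp$p, 0.02131164, tolerance = 1e-6)
    tt <- t.test(v ~ g, var.equal = TRUE)
    expect_equal(cmp$t, unname(tt$statistic))
    expect_equal(cmp$p, tt$p.value)
    expect_warning(cmp0 <- compareGroupScores(c(2, 2, 2, 2),
                                              factor(c("a", "a", "b", "b"))),
                   "p undefined")
    expect_equal(cmp0$p, 1)
    expect_error(compareGroupScores(1:3, factor(c("a", "a", "b"))), "n >= 2")
})

test_that("negative ING4-target coupling yields higher scores in ING4-low tumors", {
    g <- genExpressionCohort(simConfig(seed = 17, nSamples = 200, beta = 2))
    model <- fitScoreModel(g$cohort, g$signatureGenes)
    sc <- scores(scoreSamples(g$cohort, model))
    sp <- splitByMarkerGene(g$cohort, "ING4")
    cmp <- compareGroupScores(sc, sp)
    expect_gt(cmp$means[["low"]], cmp$means[["high"]])
    expect_gt(cmp$difference, 0.2 * length(g$signatureGenes))
    # beta = 0 decouples: gap within one gene of zero
    g0 <- genExpressionCohort(simConfig(seed = 17, nSamples = 200, beta = 0))
    sc0 <- scores(scoreSamples(g0$cohort,
                               fitScoreModel(g0$cohort, g0$signatureGenes)))
    cmp0 <- compareGroupScores(sc0, splitByMarkerGene(g0$cohort, "ING4"))
    expect_lt(abs(cmp0$difference), 1)
})
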