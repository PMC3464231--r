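test_that("product-limit estimator handles censoring the standard way", {
    # all events: empirical survival 2/3, 1/3, 0
    k <- survProb(kmCurve(c(1, 2, 3), c(TRUE, TRUE, TRUE)))
    expect_equal(k$surv, c(2 / 3, 1 / 3, 0))
    # censoring at t=2: S drops only at event times, 2/3 then 0
    k <- survProb(kmCurve(c(1, 2, 3), c(TRUE, FALSE, TRUE)))
    expect_equal(k$surv, c(2 / 3, 2 / 3, 0))
    expect_equal(k$nCensor, c(0L, 1L, 0L))
    # all censored: S identically 1
    expect_true(all(survProb(kmCurve(c(1, 2), c(FALSE, FALSE)))$surv == 1))
    expect_error(kmCurve(numeric(0), logical(0)), "empty")
    expect_error(kmCurve(c(0, 1), c(TRUE, TRUE)), "> 0")
})

test_that("KM equals the empirical survival function without censoring, and survfit always", {
    skip_if_not_installed("survival")
    set.seed(5)
    for (i in 1:10) {
        t <- round(rexp(40, 0.2), 2)
        e <- rbinom(40, 1, 0.7) == 1
        k <- survProb(kmCurve(t, e))
        sf <- summary(survival::survfit(survival::Surv(t, e) ~ 1),
                      times = k$time)
        expect_equal(k$surv, sf$surv, tolerance = 1e-12)
        kNoCens <- survProb(kmCurve(t, rep(TRUE, 40)))
        expect_equal(kNoCens$surv,
                     vapply(kNoCens$time, function(x) mean(t > x), 0))
    }
})

test_that("log-rank O/E/V table matches the hand tabulation and survdiff", {
    # group A events at 1,2; group B events at 3,4:
    # O1 = 2, E1 = 1/2 + 1/3, V = 1/4 + 2/9, chisq = 49/17
    lr <- logrankTest(c(1, 2, 3, 4), rep(TRUE, 4),
                      factor(c("A", "A", "B", "B")))
    expect_equal(unname(lr@observed["A"]), 2)
    expect_equal(unname(lr@expected["A"]), 1 / 2 + 1 / 3)
    expect_equal(lr@variance, 1 / 4 + 2 / 9)
    expect_equal(lr@chisq, 49 / 17)
    expect_equal(lr@p, pchisq(49 / 17, 1, lower.tail = FALSE))
    # identical groups (duplicated data): no signal
    lrNull <- logrankTest(rep(c(1, 2, 3), 2), rep(TRUE, 6),
                          factor(rep(c("A", "B"), each = 3)))
    expect_equal(lrNull@chisq, 0)
    expect_equal(lrNull@p, 1)
    expect_error(logrankTest(c(1, 2), c(FALSE, FALSE),
                             factor(c("A", "B"))), "no events")
})

test_that("log-rank agrees with survdiff and is label-swap invariant", {
    skip_if_not_installed("survival")
    set.seed(13)
    for (i in 1:10) {
        d <- simSurvArms(30, hrTrue = sample(c(1, 2), 1))
        lr <- logrankTest(d$time, d$event, d$group)
        sd <- survival::survdiff(survival::Surv(d$time, d$event) ~ d$group)
        expect_equal(lr@chisq, unname(sd$chisq), tolerance = 1e-9)
        swapped <- factor(d$group, levels = rev(levels(d$group)))
        lr2 <- logrankTest(d$time, d$event, swapped)
        expect_equal(lr2@chisq, lr@chisq, tolerance = 1e-12)
        expect_equal(lr2@p, lr@p, tolerance = 1e-12)
    }
})

test_that("hazard ratio: symmetry, label-swap reciprocity and Cox cross-check", {
    skip_if_not_installed("survival")
    # mirror-image groups -> HR exactly 1
    h <- hazardRatio(c(1, 2, 3, 1, 2, 3), rep(TRUE, 6),
                     factor(rep(c("A", "B"), each = 3)))
    expect_equal(h@hr, 1)
    set.seed(29)
    for (i in 1:8) {
        d <- simSurvArms(40, hrTrue = 2)
        h1 <- hazardRatio(d$time, d$event, d$group)
        h2 <- hazardRatio(d$time, d$event,
                          factor(d$group, levels = rev(levels(d$group))))
        expect_equal(h1@hr * h2@hr, 1, tolerance = 1e-10)
        hc <- hazardRatio(d$time, d$event, d$group, method = "cox")
        cph <- survival::coxph(
            survival::Surv(d$time, d$event) ~ I(d$group == "low"),
            ties = "breslow")
        expect_equal(hc@logHr, unname(coef(cph)), tolerance = 1e-6)
        expect_equal(hc@se, sqrt(unname(vcov(cph)[1, 1])),
                     tolerance = 1e-4)
        expect_true(h1@ciLow <= h1@hr && h1@hr <= h1@ciHigh)
    }
    expect_warning(
        hazardRatio(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                    factor(c("A", "A", "B", "B"))), "no events")
})

test_that("ROC cutoff scan maximizes Youden J with deterministic tie-breaks", {
    # perfect separation: events have the two lowest marker values
    r <- rocOptimalCutoff(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(cutoff(r), 2.5)
    expect_equal(youdenJ(r), 1)
    expect_equal(r@sensitivity, 1)
    expect_equal(r@specificity, 1)
    # cutoff is always a midpoint between adjacent observed values
    set.seed(3)
    v <- rnorm(30); lab <- rbinom(30, 1, 0.5)
    if (all(lab == lab[1])) lab[1] <- 1 - lab[1]
    rc <- rocOptimalCutoff(v, lab)
    u <- sort(unique(v))
    expect_true(any(abs((u[-1] + u[-length(u)]) / 2 - cutoff(rc)) < 1e-12))
    # permuted labels give near-zero J on average (null behavior)
    set.seed(9)
    Js <- replicate(200, youdenJ(rocOptimalCutoff(rnorm(40),
                                                  sample(rep(0:1, 20)))))
    expect_lt(mean(Js), 0.45)  # max-over-cutoffs inflates J; stays far from 1
    expect_error(rocOptimalCutoff(c(1, 2), c(TRUE, TRUE)), "both outcome")
    expect_error(rocOptimalCutoff(c(2, 2), c(TRUE, FALSE)), "constant")
})

test_that("end-to-end stratification: policies agree and direction is recovered", {
    g <- genExpressionCohort(simConfig(seed = 21, nSamples = 200, trueHR = 3,
                                       beta = 2))
    med <- stratifyAndCompare(g$cohort, "ING4", cutoffPolicy = "median")
    expl <- stratifyAndCompare(
        g$cohort, "ING4", cutoffPolicy = "explicit",
        cutoff = median(exprsValues(g$cohort)["ING4", ]))
    expect_identical(med$groups, expl$groups)
    expect_equal(med$hazardRatio@hr, expl$hazardRatio@hr)
    # ING4-low group must show worse survival everywhere it is estimated
    expect_gt(med$hazardRatio@hr, 1)
    sLow <- survProb(med$curves$low); sHigh <- survProb(med$curves$high)
    tEval <- median(clinicalData(g$cohort)$time)
    atT <- function(kp, t) c(1, kp$surv)[findInterval(t, c(0, kp$time))]
    expect_lt(atT(sLow, tEval), atT(sHigh, tEval))
    # ROC policy returns the cutoff object it used
    roc <- stratifyAndCompare(g$cohort, "ING4", cutoffPolicy = "roc")
    expect_s4_class(roc$cutoffResult, "CutoffResult")
    expect_equal(roc$cutoff, cutoff(roc$cutoffResult))
    # a high signature score marks the high-risk group (anti-correlated cohort)
    sc <- scores(scoreSamples(g$cohort,
                              fitScoreModel(g$cohort, g$signatureGenes)))
    byScore <- stratifyAndCompare(g$cohort, sc, cutoffPolicy = "median")
    expect_lt(byScore$hazardRatio@hr, 1)  # score-low vs score-high hazard
})
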