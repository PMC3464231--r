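# Shared in-code fixtures and independent oracles for the suite.

# tiny expression cohort with known structure
toyCohort <- function() {
    m <- matrix(c(1, 2, 3, 4,
                  5, 5, 5, 9,
                  0, 10, 0, 10), 3, 4, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
    ExpressionCohort(m)
}

# noiseless Ct table realizing given PMA-vs-vehicle folds per sample/line
exactCtTable <- function(folds) {
    genCtTable(simConfig(seed = 1, ctNoise = 0, ctReplicates = 2), folds)
}

# the three-gene RT-qPCR design with the published induction folds
printedFolds <- function()
    data.frame(sample = rep(c("ctrl", "ing4"), each = 3),
               gene = rep(c("IL6", "IL8", "PTGS2"), 2),
               fold = c(26, 1070, 212, 8, 35, 10))

# independent Fisher oracle: enumerate all tables with the observed margins
# using binomial coefficients directly (no dhyper)
fisherEnumOracle <- function(tab) {
    n <- sum(tab)
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1])
    support <- max(0, r1 + c1 - n):min(r1, c1)
    pt <- choose(r1, support) * choose(n - r1, c1 - support) / choose(n, c1)
    pObs <- pt[match(tab[1, 1], support)]
    sum(pt[pt <= pObs * (1 + 1e-9)])
}

# per-tumor low/high call factors realizing given 2x2 counts
callsFromCounts <- function(aLowbLow, aLowbHigh, aHighbLow, aHighbHigh) {
    n <- aLowbLow + aLowbHigh + aHighbLow + aHighbHigh
    ids <- sprintf("T%04d", seq_len(n))
    a <- factor(rep(c("low", "low", "high", "high"),
                    c(aLowbLow, aLowbHigh, aHighbLow, aHighbHigh)),
                levels = c("low", "high"))
    b <- factor(rep(c("low", "high", "low", "high"),
                    c(aLowbLow, aLowbHigh, aHighbLow, aHighbHigh)),
                levels = c("low", "high"))
    names(a) <- names(b) <- ids
    list(a = a, b = b)
}

# two exponential survival arms with known hazard ratio and ~20% censoring
simSurvArms <- function(nPerArm, hrTrue, baseRate = 0.1, censRate = 0.025) {
    g <- factor(rep(c("low", "high"), each = nPerArm),
                levels = c("low", "high"))
    rate <- ifelse(g == "low", baseRate * hrTrue, baseRate)
    tE <- rexp(2 * nPerArm, rate)
    tC <- rexp(2 * nPerArm, censRate)
    list(time = pmin(tE, tC), event = tE <= tC, group = g)
}

# minimal GDS SOFT text with a duplicated gene symbol on two probes
softFixtureLines <- function() c(
    "^DATABASE = GeoMiame",
    "!Database_name = Gene Expression Omnibus (GEO)",
    "^DATASET = GDS9999",
    "!dataset_sample_count = 3",
    "#GSM1 = sample 1",
    "!dataset_table_begin",
    "ID_REF\tIDENTIFIER\tGSM1\tGSM2\tGSM3",
    "1001_at\tING4\t5.0\t6.0\t7.0",
    "1002_at\tIL8\t2.0\t2.5\t3.0",
    "1003_at\tING4\t1.0\t1.5\t2.0",
    "!dataset_table_end")
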