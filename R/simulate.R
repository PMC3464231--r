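# Seeded generators that emulate every input the pipeline consumes, with
# known ground truth. One global seed drives independent per-stream
# sub-generators (fixed per-generator offsets), so adding a generator never
# perturbs the streams of existing ones.

#' Simulation configuration
#'
#' Validated parameter bundle shared by all generators. Defaults emulate
#' the study conditions the pipeline targets: a 249-tumor tissue microarray
#' with 2-3 punches per tumor, a 60-sample expression cohort with a
#' 25-gene signature, a true marker hazard ratio of 3 with 20\% censoring,
#' and triplicate qPCR with 0.2-cycle replicate noise.
#'
#' @param seed integer RNG seed (< 2^31).
#' @param nTumors TMA size (tumors).
#' @param nSamples expression-cohort size (samples).
#' @param nSignatureGenes,nFillerGenes signature and independent filler
#'   genes.
#' @param beta coupling strength (>= 0): expression units of signature-gene
#'   repression per SD of log ING4.
#' @param exprNoise per-cell expression noise SD.
#' @param punchNoise punch-score noise SD (score units).
#' @param trueHR true hazard ratio of marker-low vs marker-high (> 0).
#' @param censorRate expected censored fraction in the baseline arm,
#'   in \code{[0, 1)}.
#' @param baselineHazard marker-high hazard rate (> 0, events per time
#'   unit).
#' @param ctNoise Ct replicate noise SD (cycles).
#' @param ctReplicates qPCR replicates per well.
#' @param pp65Coupling log-odds of p-p65-high per score unit of ING4
#'   deficit (>= 0; 0 decouples the markers).
#' @param lnOddsMultiplier odds multiplier for lymph-node positivity in
#'   ING4-low/p-p65-high tumors (1 = no effect).
#' @param probTriple probability a tumor gets 3 punches (else 2).
#' @return validated config list (class \code{simConfig}).
#' @export
simConfig <- function(seed = 1L, nTumors = 249L, nSamples = 60L,
                      nSignatureGenes = 25L, nFillerGenes = 50L,
                      beta = 1, exprNoise = 1, punchNoise = 0.3,
                      trueHR = 3, censorRate = 0.2, baselineHazard = 0.1,
                      ctNoise = 0.2, ctReplicates = 3L,
                      pp65Coupling = 1.5, lnOddsMultiplier = 3,
                      probTriple = 0.5) {
    cfg <- list(seed = as.integer(seed), nTumors = as.integer(nTumors),
                nSamples = as.integer(nSamples),
                nSignatureGenes = as.integer(nSignatureGenes),
                nFillerGenes = as.integer(nFillerGenes), beta = beta,
                exprNoise = exprNoise, punchNoise = punchNoise,
                trueHR = trueHR, censorRate = censorRate,
                baselineHazard = baselineHazard, ctNoise = ctNoise,
                ctReplicates = as.integer(ctReplicates),
                pp65Coupling = pp65Coupling,
                lnOddsMultiplier = lnOddsMultiplier, probTriple = probTriple)
    with(cfg, {
        stopifnot(nTumors > 0, nSamples > 1, nSignatureGenes > 0,
                  nFillerGenes >= 0, beta >= 0, exprNoise >= 0,
                  punchNoise >= 0, trueHR > 0, censorRate >= 0,
                  censorRate < 1, baselineHazard > 0, ctNoise >= 0,
                  ctReplicates >= 1, pp65Coupling >= 0,
                  lnOddsMultiplier > 0, probTriple >= 0, probTriple <= 1)
    })
    structure(cfg, class = "simConfig")
}

# per-generator sub-stream seeds derived from the global seed
streamSeed <- function(config, offset) {
    (config$seed + offset) %% .Machine$integer.max
}

#' Simulate a TMA punch-score cohort with pathology annotation
#'
#' Latent per-tumor ING4 on \code{[0, 3]}; punch scores are the rounded
#' latent level plus Gaussian noise, clamped to 0-3, with 2-3 punches per
#' tumor. Latent p-p65 status is negatively coupled to ING4 through a
#' logistic link, and lymph-node positivity odds are multiplied by
#' \code{lnOddsMultiplier} for ING4-low/p-p65-high tumors.
#'
#' @param config a [simConfig()].
#' @return list: \code{punches} (punch table over markers ING4 and pp65),
#'   \code{pathology} (\code{tumor}, \code{lnStatus}), \code{truth}
#'   (latent values and indicators).
#' @export
genTmaCohort <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    set.seed(streamSeed(config, 101L))
    n <- config$nTumors
    tumors <- sprintf("T%03d", seq_len(n))
    ing4Latent <- runif(n, 0, 3)
    pHigh <- plogis(stats::qlogis(0.25) +
                    config$pp65Coupling * (1.5 - ing4Latent))
    pp65High <- rbinom(n, 1, pHigh) == 1
    pp65Latent <- ifelse(pp65High, runif(n, 1.5, 3), runif(n, 0, 1.45))
    pLN <- plogis(stats::qlogis(0.30) +
                  log(config$lnOddsMultiplier) *
                      as.numeric(ing4Latent < 1.5 & pp65High))
    lnPos <- rbinom(n, 1, pLN) == 1
    nPunch <- 2L + rbinom(n, 1, config$probTriple)
    punchRow <- function(latent, tumor, marker, k) {
        sc <- pmin(3, pmax(0, round(latent + rnorm(k, 0, config$punchNoise))))
        data.frame(tumor = tumor, marker = marker, punch = seq_len(k),
                   score = sc, stringsAsFactors = FALSE)
    }
    punches <- do.call(rbind, c(
        lapply(seq_len(n), function(i)
            punchRow(ing4Latent[i], tumors[i], "ING4", nPunch[i])),
        lapply(seq_len(n), function(i)
            punchRow(pp65Latent[i], tumors[i], "pp65", nPunch[i]))))
    rownames(punches) <- NULL
    list(punches = validatePunchTable(punches),
         pathology = data.frame(tumor = tumors,
                                lnStatus = ifelse(lnPos, "LN+", "LN-"),
                                stringsAsFactors = FALSE),
         truth = list(ing4Latent = setNames(ing4Latent, tumors),
                      pp65High = setNames(pp65High, tumors),
                      lnPos = setNames(lnPos, tumors)))
}

#' Simulate an expression cohort with survival annotation
#'
#' ING4 expression is log-normal; each signature gene is its own baseline
#' minus \code{beta} times the standardized log-ING4 level plus Gaussian
#' noise (negative coupling), filler genes are independent. Survival is
#' exponential with hazard \code{baselineHazard * trueHR^I(ING4 <= median)}
#' — the same median split the scoring default uses, so generator truth and
#' pipeline estimate refer to the same contrast — with independent
#' exponential censoring calibrated so the baseline arm's expected censored
#' fraction is \code{censorRate}.
#'
#' @param config a [simConfig()].
#' @return list: \code{cohort} (an [ExpressionCohort-class] with clinical
#'   annotation), \code{signatureGenes}, \code{truth} (group labels, true
#'   HR, latent values).
#' @export
genExpressionCohort <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    set.seed(streamSeed(config, 202L))
    n <- config$nSamples
    samples <- sprintf("S%03d", seq_len(n))
    ing4 <- rlnorm(n, meanlog = 6, sdlog = 0.5)
    z <- as.numeric(scale(log(ing4)))
    sigGenes <- sprintf("NFKBT%02d", seq_len(config$nSignatureGenes))
    base <- rnorm(config$nSignatureGenes, 8, 1)
    sig <- base - config$beta * matrix(z, config$nSignatureGenes, n,
                                       byrow = TRUE) +
        matrix(rnorm(config$nSignatureGenes * n, 0, config$exprNoise),
               config$nSignatureGenes, n)
    fil <- matrix(rnorm(config$nFillerGenes * n, 8, 1.2),
                  config$nFillerGenes, n)
    vals <- rbind(matrix(ing4, 1, n), sig, fil)
    rownames(vals) <- c("ING4", sigGenes,
                        if (config$nFillerGenes)
                            sprintf("FILLER%02d", seq_len(config$nFillerGenes)))
    colnames(vals) <- samples
    low <- ing4 <= median(ing4)
    rate <- config$baselineHazard * config$trueHR^as.numeric(low)
    tEvent <- rexp(n, rate)
    clinical <- if (config$censorRate > 0) {
        cRate <- config$baselineHazard * config$censorRate /
            (1 - config$censorRate)
        tCens <- rexp(n, cRate)
        data.frame(sample = samples, time = pmin(tEvent, tCens),
                   event = tEvent <= tCens)
    } else data.frame(sample = samples, time = tEvent, event = TRUE)
    list(cohort = ExpressionCohort(vals, clinical = clinical),
         signatureGenes = sigGenes,
         truth = list(ing4Low = setNames(low, samples), trueHR = config$trueHR,
                      z = setNames(z, samples)))
}

#' Simulate a Ct table realizing specified fold changes
#'
#' The reference gene (GAPDH) has a constant Ct of 20 in every well; each
#' target gene starts from a baseline Ct of 25 in the \code{"vehicle"}
#' condition and is shifted by \code{-log2(fold)} in the \code{"PMA"}
#' condition, with Gaussian replicate noise of SD \code{ctNoise}.
#'
#' @param config a [simConfig()].
#' @param trueFolds \code{data.frame} with columns \code{sample},
#'   \code{gene}, \code{fold} (> 0): the PMA-vs-vehicle fold to realize for
#'   that gene in that sample/line.
#' @return a validated Ct \code{data.frame}.
#' @export
genCtTable <- function(config, trueFolds) {
    stopifnot(inherits(config, "simConfig"))
    stopifnot(all(c("sample", "gene", "fold") %in% colnames(trueFolds)))
    if (any(trueFolds$fold <= 0)) stop("true folds must be positive")
    set.seed(streamSeed(config, 303L))
    reps <- seq_len(config$ctReplicates)
    rows <- lapply(seq_len(nrow(trueFolds)), function(i) {
        s <- trueFolds$sample[i]; g <- trueFolds$gene[i]
        f <- trueFolds$fold[i]
        rbind(
            data.frame(sample = s, gene = g, condition = "vehicle",
                       replicate = reps,
                       ct = 25 + rnorm(length(reps), 0, config$ctNoise)),
            data.frame(sample = s, gene = g, condition = "PMA",
                       replicate = reps,
                       ct = 25 - log2(f) +
                           rnorm(length(reps), 0, config$ctNoise)))
    })
    refs <- lapply(unique(trueFolds$sample), function(s)
        data.frame(sample = s, gene = "GAPDH",
                   condition = rep(c("vehicle", "PMA"), each = length(reps)),
                   replicate = rep(reps, 2), ct = 20))
    ct <- do.call(rbind, c(rows, refs))
    rownames(ct) <- NULL
    validateCtTable(ct)
}
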