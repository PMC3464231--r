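# End-to-end orchestration: run the simulate / qPCR / TMA / scoring /
# survival stages in dependency order against files under one output
# directory, and record a manifest of config and output hashes. Outputs are
# pure functions of (inputs, config, seed); timestamps live only in logs.

#' Build a pipeline run configuration
#'
#' @param outDir output directory (created if absent).
#' @param seed global seed for the synthetic stages.
#' @param stages subset of \code{c("simulate", "qpcr-folds",
#'   "derive-signature", "tma-assoc", "signature-score", "survive")} in any
#'   order; dependencies are resolved by file presence.
#' @param sim named list of [simConfig()] overrides.
#' @param ihcCutoff IHC low/high cutoff (default 1.5).
#' @param induceThreshold,tier2,tier4 signature-cascade thresholds.
#' @param cutoffPolicy survival dichotomization policy
#'   (\code{"median"}, \code{"roc"}, \code{"explicit"}).
#' @param cutoff explicit survival cutoff (with
#'   \code{cutoffPolicy = "explicit"}).
#' @param controlSample,ing4Sample Ct-table sample labels for the two cell
#'   lines contrasted by the cascade.
#' @param trueFolds optional \code{data.frame(sample, gene, fold)} for the
#'   simulated Ct table; defaults to the three-gene RT-qPCR design
#'   (IL6/IL8/PTGS2 folds 26/1070/212 in the control line, 8/35/10 under
#'   ING4).
#' @return validated config list (class \code{runConfig}).
#' @export
runConfig <- function(outDir = tempfile("ing4run"), seed = 1L,
                      stages = c("simulate", "qpcr-folds",
                                 "derive-signature", "tma-assoc",
                                 "signature-score", "survive"),
                      sim = list(), ihcCutoff = 1.5, induceThreshold = 2,
                      tier2 = 2, tier4 = 4,
                      cutoffPolicy = c("median", "roc", "explicit"),
                      cutoff = NULL,
                      controlSample = "T47D-pMIG", ing4Sample = "T47D-ING4",
                      trueFolds = NULL) {
    all <- c("simulate", "qpcr-folds", "derive-signature", "tma-assoc",
             "signature-score", "survive")
    stages <- all[all %in% match.arg(stages, all, several.ok = TRUE)]
    stopifnot(ihcCutoff > 0, induceThreshold > 1, tier2 > 1, tier4 > 1)
    if (is.null(trueFolds))
        trueFolds <- data.frame(
            sample = rep(c(controlSample, ing4Sample), each = 3),
            gene = rep(c("IL6", "IL8", "PTGS2"), 2),
            fold = c(26, 1070, 212, 8, 35, 10))
    structure(list(outDir = outDir, seed = as.integer(seed), stages = stages,
                   sim = sim, ihcCutoff = ihcCutoff,
                   induceThreshold = induceThreshold, tier2 = tier2,
                   tier4 = tier4, cutoffPolicy = match.arg(cutoffPolicy),
                   cutoff = cutoff, controlSample = controlSample,
                   ing4Sample = ing4Sample, trueFolds = trueFolds),
              class = "runConfig")
}

#' Load a run configuration from a YAML or JSON file
#'
#' File values override [runConfig()] defaults; unknown keys are rejected.
#'
#' @param path config file (\code{.yaml}/\code{.yml} needs the yaml
#'   package; anything else is parsed as JSON).
#' @return a \code{runConfig}.
#' @export
loadRunConfig <- function(path) {
    vals <- if (grepl("\\.ya?ml$", path)) {
        if (!requireNamespace("yaml", quietly = TRUE))
            stop("the yaml package is required for YAML configs")
        yaml::read_yaml(path)
    } else jsonlite::read_json(path, simplifyVector = TRUE)
    known <- names(formals(runConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown config key(s): ", paste(bad, collapse = ", "))
    do.call(runConfig, vals)
}

#' Run the pipeline
#'
#' Executes the requested stages in dependency order, writing every result
#' as TSV/JSON under \code{config$outDir} plus a \code{manifest.json}
#' recording the config, package version and md5 of every output. Reruns
#' with identical config are byte-identical.
#'
#' @param config a [runConfig()] (or a path accepted by [loadRunConfig()]).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = runConfig()) {
    if (is.character(config)) config <- loadRunConfig(config)
    stopifnot(inherits(config, "runConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    pth <- function(f) file.path(config$outDir, f)
    needInput <- function(f) {
        p <- pth(f)
        if (!file.exists(p))
            stop("missing stage input: ", f,
                 " (run the producing stage first)")
        p
    }
    outputs <- character(0)
    emit <- function(obj, file, format = "json") {
        writeResults(obj, pth(file), format = format)
        outputs <<- c(outputs, file)
    }
    simCfg <- do.call(simConfig, c(list(seed = config$seed), config$sim))

    if ("simulate" %in% config$stages) {
        tma <- genTmaCohort(simCfg)
        write.table(tma$punches, pth("punches.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(tma$pathology, pth("pathology.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        expr <- genExpressionCohort(simCfg)
        writeExpressionTable(expr$cohort, pth("expression.tsv"),
                             clinicalPath = pth("clinical.tsv"))
        writeLines(expr$signatureGenes, pth("signature_genes.txt"))
        ct <- genCtTable(simCfg, config$trueFolds)
        write.table(ct, pth("ct.tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        outputs <- c(outputs, "punches.tsv", "pathology.tsv",
                     "expression.tsv", "clinical.tsv", "signature_genes.txt",
                     "ct.tsv")
        emit(list(simConfig = unclass(simCfg),
                  trueHR = simCfg$trueHR,
                  trueFolds = config$trueFolds), "truth.json")
    }

    if ("qpcr-folds" %in% config$stages) {
        ct <- readCtTable(needInput("ct.tsv"))
        genes <- setdiff(unique(ct$gene), "GAPDH")
        folds <- do.call(rbind, lapply(unique(ct$sample), function(s)
            cbind(sample = s,
                  foldChangeTable(ct, genes, "PMA", "vehicle", sample = s))))
        emit(folds, "folds.tsv", "tsv")
    }

    if ("derive-signature" %in% config$stages) {
        folds <- read.delim(needInput("folds.tsv"))
        fc <- function(s) with(folds[folds$sample == s, ],
                               setNames(fold, gene))
        der <- deriveSignature(fc(config$controlSample),
                               fc(config$ing4Sample),
                               induceThreshold = config$induceThreshold,
                               tier2 = config$tier2, tier4 = config$tier4)
        emit(list(induced = der@induced, repressed2 = der@repressed2,
                  repressed4 = der@repressed4,
                  ratios = as.list(der@ratios),
                  thresholds = as.list(der@thresholds)), "signature.json")
    }

    if ("tma-assoc" %in% config$stages) {
        punches <- readPunchTable(needInput("punches.tsv"))
        agg <- lapply(c(ING4 = "ING4", pp65 = "pp65"), function(mk) {
            a <- aggregatePunches(punches, mk)
            setNames(dichotomize(a$meanScore, config$ihcCutoff), a$tumor)
        })
        tab <- crossTab(agg$pp65, agg$ING4, labels = c("pp65", "ING4"))
        emit(list(counts = as.data.frame(as.table(tab)),
                  rowPercents = as.data.frame(as.table(rowPercents(tab))),
                  fisherP = fisherExact2x2(tab),
                  cutoff = config$ihcCutoff), "tma_assoc.json")
    }

    if ("signature-score" %in% config$stages) {
        cohort <- readExpressionTable(needInput("expression.tsv"),
                                      clinicalPath = needInput("clinical.tsv"))
        genes <- readGeneSet(needInput("signature_genes.txt"))
        model <- fitScoreModel(cohort, genes)
        res <- scoreSamples(cohort, model)
        groups <- splitByMarkerGene(cohort, "ING4")
        cmp <- compareGroupScores(scores(res), groups)
        emit(data.frame(sample = names(scores(res)), score = scores(res),
                        ing4Group = as.character(groups)),
             "scores.tsv", "tsv")
        emit(list(nGenes = length(geneSet(res)),
                  droppedGenes = model@droppedGenes,
                  meanScoreLow = unname(cmp$means["low"]),
                  meanScoreHigh = unname(cmp$means["high"]),
                  difference = cmp$difference, t = cmp$t, df = cmp$df,
                  p = cmp$p), "score_comparison.json")
    }

    if ("survive" %in% config$stages) {
        cohort <- readExpressionTable(needInput("expression.tsv"),
                                      clinicalPath = needInput("clinical.tsv"))
        res <- stratifyAndCompare(cohort, "ING4",
                                  cutoffPolicy = config$cutoffPolicy,
                                  cutoff = config$cutoff)
        for (gname in names(res$curves))
            emit(survProb(res$curves[[gname]]),
                 paste0("km_", gname, ".tsv"), "tsv")
        scoresPath <- pth("scores.tsv")
        scoreRes <- if (file.exists(scoresPath)) {
            sc <- read.delim(scoresPath)
            r <- stratifyAndCompare(cohort,
                                    setNames(as.numeric(sc$score), sc$sample),
                                    cutoffPolicy = "median")
            list(scoreHrLowVsHigh = r$hazardRatio@hr,
                 scoreLogrankP = r$logrank@p, scoreCutoff = r$cutoff)
        } else NULL
        emit(c(list(cutoffPolicy = config$cutoffPolicy, cutoff = res$cutoff,
                    chisq = res$logrank@chisq, logrankP = res$logrank@p,
                    hr = res$hazardRatio@hr, ciLow = res$hazardRatio@ciLow,
                    ciHigh = res$hazardRatio@ciHigh,
                    hrMethod = res$hazardRatio@method), scoreRes),
             "survival.json")
    }

    manifest <- list(
        package = "ing4nfkb",
        version = as.character(utils::packageVersion("ing4nfkb")),
        config = unclass(config)[setdiff(names(config), "trueFolds")],
        trueFolds = config$trueFolds,
        outputs = as.list(tools::md5sum(
            file.path(config$outDir, sort(unique(outputs))))))
    names(manifest$outputs) <- basename(names(manifest$outputs))
    jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(manifest)
}
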