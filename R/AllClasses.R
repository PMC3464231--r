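#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats median setNames pchisq pt qnorm rexp rnorm rlnorm runif
#'   rbinom plogis dhyper complete.cases lm coef
#' @importFrom utils read.delim write.table head
NULL

#' ExpressionCohort: an expression matrix with optional survival annotation
#'
#' A thin extension of
#' \link[SummarizedExperiment]{SummarizedExperiment} holding a genes x
#' samples expression matrix (assay \code{"exprs"}) plus optional per-sample
#' clinical annotation in \code{colData}: \code{time} (non-negative
#' follow-up, in the unit the source dataset uses) and \code{event}
#' (logical; \code{TRUE} = recurrence/death).
#'
#' Gene and sample identifiers must be unique; gene symbols are stored
#' case-preserved and matched case-insensitively by the signature-scoring
#' functions.
#'
#' @slot .. see \link[SummarizedExperiment]{SummarizedExperiment}
#' @seealso [ExpressionCohort()], [readExpressionTable()], [readSoftGDS()]
#' @export
setClass("ExpressionCohort", contains = "SummarizedExperiment")

setValidity("ExpressionCohort", function(object) {
    msg <- NULL
    g <- rownames(object); s <- colnames(object)
    if (is.null(g) || is.null(s))
        msg <- c(msg, "gene and sample ids are required as dimnames")
    if (anyDuplicated(g)) msg <- c(msg, "duplicate gene ids")
    if (anyDuplicated(s)) msg <- c(msg, "duplicate sample ids")
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    cd <- SummarizedExperiment::colData(object)
    if ("time" %in% colnames(cd)) {
        tt <- cd$time
        if (any(!is.na(tt) & tt < 0)) msg <- c(msg, "negative follow-up time")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct an ExpressionCohort
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param geneIds,sampleIds unique identifiers; default to the dimnames of
#'   \code{values}.
#' @param clinical optional \code{data.frame} with columns \code{sample},
#'   \code{time} (>= 0) and \code{event} (0/1 or logical). Every clinical
#'   sample must be present in the matrix; samples without clinical rows get
#'   \code{NA}.
#' @return an [ExpressionCohort-class] object.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("ING4", "IL8"), paste0("s", 1:3)))
#' ExpressionCohort(m)
#' @export
ExpressionCohort <- function(values, geneIds = rownames(values),
                             sampleIds = colnames(values), clinical = NULL) {
    values <- as.matrix(values)
    if (!is.numeric(values)) stop("expression values must be numeric")
    if (is.null(geneIds) || is.null(sampleIds))
        stop("gene and sample ids are required")
    geneIds <- as.character(geneIds); sampleIds <- as.character(sampleIds)
    if (length(geneIds) != nrow(values) || length(sampleIds) != ncol(values))
        stop("dimension mismatch between ids and matrix")
    if (anyDuplicated(geneIds))
        stop("duplicate gene ids: ",
             paste(unique(geneIds[duplicated(geneIds)]), collapse = ", "))
    if (anyDuplicated(sampleIds)) stop("duplicate sample ids")
    dimnames(values) <- list(geneIds, sampleIds)
    cd <- S4Vectors::DataFrame(row.names = sampleIds,
                               time = rep(NA_real_, length(sampleIds)),
                               event = rep(NA, length(sampleIds)))
    if (!is.null(clinical)) {
        clinical <- as.data.frame(clinical)
        need <- c("sample", "time", "event")
        if (!all(need %in% colnames(clinical)))
            stop("clinical table needs columns: ", paste(need, collapse = ", "))
        unknown <- setdiff(clinical$sample, sampleIds)
        if (length(unknown))
            stop("clinical sample(s) not in expression matrix: ",
                 paste(unknown, collapse = ", "))
        if (any(clinical$time < 0, na.rm = TRUE))
            stop("negative follow-up time in clinical table")
        idx <- match(clinical$sample, sampleIds)
        cd$time[idx] <- as.numeric(clinical$time)
        cd$event[idx] <- as.logical(clinical$event)
    }
    new("ExpressionCohort",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(exprs = values), colData = cd))
}

#' ScoreModel: per-gene within-dataset medians for signature scoring
#'
#' Fitted by [fitScoreModel()]; holds the signature gene set actually used
#' (genes absent from the cohort are dropped with a warning) and the median
#' expression of each gene computed within the dataset being scored.
#' Medians are never transferred across datasets.
#'
#' @slot geneSet character, signature genes present in the cohort (cohort
#'   spelling).
#' @slot medians named numeric, one per gene.
#' @slot droppedGenes character, requested genes absent from the cohort.
#' @export
setClass("ScoreModel", representation(geneSet = "character",
                                      medians = "numeric",
                                      droppedGenes = "character"))

setValidity("ScoreModel", function(object) {
    if (length(object@geneSet) != length(object@medians))
        return("one median per gene required")
    if (!identical(names(object@medians), object@geneSet))
        return("medians must be named by geneSet")
    TRUE
})

#' ScoreResult: per-sample median-vote signature scores
#'
#' @slot scores named integer, one per sample; each in
#'   \code{[0, length(geneSet)]}.
#' @slot votes 0/1 integer matrix, genes x samples; a vote of 1 means the
#'   sample expresses the gene strictly above its within-dataset median.
#' @slot geneSet character, the genes voted on.
#' @export
setClass("ScoreResult", representation(scores = "integer",
                                       votes = "matrix",
                                       geneSet = "character"))

setValidity("ScoreResult", function(object) {
    msg <- NULL
    if (!all(object@votes %in% c(0L, 1L))) msg <- c(msg, "votes must be 0/1")
    if (!identical(unname(object@scores), unname(as.integer(colSums(object@votes)))))
        msg <- c(msg, "score must equal the vote sum")
    if (any(object@scores < 0L) || any(object@scores > length(object@geneSet)))
        msg <- c(msg, "scores out of [0, |gene set|]")
    if (is.null(msg)) TRUE else msg
})

#' SignatureDerivation: the induced/repressed gene-filter cascade
#'
#' Result of [deriveSignature()]: PMA-induced genes in the control line
#' (fold strictly above the induction threshold) and the nested repressed
#' tiers (repression ratio at or above 2x resp. 4x).
#'
#' @slot induced,repressed2,repressed4 character gene sets,
#'   \code{repressed4} within \code{repressed2} within \code{induced}.
#' @slot ratios named numeric, repression ratio (control fold / ING4 fold)
#'   for every induced gene.
#' @slot thresholds named numeric: \code{induce}, \code{tier2}, \code{tier4}.
#' @export
setClass("SignatureDerivation", representation(induced = "character",
                                               repressed2 = "character",
                                               repressed4 = "character",
                                               ratios = "numeric",
                                               thresholds = "numeric"))

setValidity("SignatureDerivation", function(object) {
    msg <- NULL
    if (!all(object@repressed4 %in% object@repressed2))
        msg <- c(msg, "repressed4 must be a subset of repressed2")
    if (!all(object@repressed2 %in% object@induced))
        msg <- c(msg, "repressed2 must be a subset of induced")
    if (any(object@thresholds <= 1)) msg <- c(msg, "thresholds must exceed 1")
    if (is.null(msg)) TRUE else msg
})

#' KMCurve: a Kaplan-Meier product-limit survival curve
#'
#' @slot time distinct observed times, ascending.
#' @slot nRisk number at risk just before each time (individuals censored at
#'   an event time count as at risk at that time).
#' @slot nEvent,nCensor events and censorings at each time.
#' @slot surv product-limit survival estimate just after each time;
#'   \code{S(0) = 1} implicitly.
#' @export
setClass("KMCurve", representation(time = "numeric", nRisk = "integer",
                                   nEvent = "integer", nCensor = "integer",
                                   surv = "numeric"))

setValidity("KMCurve", function(object) {
    msg <- NULL
    if (is.unsorted(object@time, strictly = TRUE))
        msg <- c(msg, "times must be strictly increasing")
    if (any(diff(object@surv) > 1e-12)) msg <- c(msg, "S must be non-increasing")
    if (any(object@surv < -1e-12 | object@surv > 1 + 1e-12))
        msg <- c(msg, "S must lie in [0,1]")
    if (is.null(msg)) TRUE else msg
})

#' LogrankResult: two-group log-rank (Mantel-Cox) test
#'
#' @slot observed,expected observed and expected event counts per group
#'   (named by group level).
#' @slot variance hypergeometric variance of the group-1 event count.
#' @slot chisq 1-df chi-square statistic.
#' @slot p two-sided p-value.
#' @export
setClass("LogrankResult", representation(observed = "numeric",
                                         expected = "numeric",
                                         variance = "numeric",
                                         chisq = "numeric", p = "numeric"))

#' HazardRatioResult: two-group hazard ratio with 95\% CI
#'
#' @slot hr hazard ratio of the first group level relative to the second.
#' @slot ciLow,ciHigh 95\% confidence bounds.
#' @slot method \code{"mantelhaenszel"} (log-rank O/E estimator) or
#'   \code{"cox"} (one-covariate partial-likelihood Newton fit).
#' @slot logHr,se log hazard ratio and its standard error.
#' @export
setClass("HazardRatioResult", representation(hr = "numeric", ciLow = "numeric",
                                             ciHigh = "numeric",
                                             method = "character",
                                             logHr = "numeric", se = "numeric"))

setValidity("HazardRatioResult", function(object) {
    if (is.finite(object@hr) &&
        (object@ciLow > object@hr + 1e-12 || object@ciHigh < object@hr - 1e-12))
        return("CI must bracket the estimate")
    TRUE
})

#' CutoffResult: ROC-derived optimal dichotomization cutoff
#'
#' The cutoff is the midpoint between adjacent observed marker values that
#' maximizes Youden's J (sensitivity + specificity - 1), where "positive"
#' means marker value below the cutoff (low marker predicts the event).
#'
#' @slot cutoff the selected midpoint.
#' @slot sensitivity,specificity operating characteristics at the cutoff.
#' @slot youdenJ sensitivity + specificity - 1.
#' @export
setClass("CutoffResult", representation(cutoff = "numeric",
                                        sensitivity = "numeric",
                                        specificity = "numeric",
                                        youdenJ = "numeric"))

setMethod("show", "ScoreModel", function(object) {
    cat("ScoreModel:", length(object@geneSet), "signature gene(s)")
    if (length(object@droppedGenes))
        cat(";", length(object@droppedGenes), "requested gene(s) absent")
    cat("\n  median range: [",
        format(min(object@medians), digits = 4), ", ",
        format(max(object@medians), digits = 4), "]\n", sep = "")
})

setMethod("show", "ScoreResult", function(object) {
    cat("ScoreResult:", length(object@scores), "sample(s),",
        length(object@geneSet), "gene(s); score range",
        min(object@scores), "-", max(object@scores), "\n")
})

setMethod("show", "SignatureDerivation", function(object) {
    cat("SignatureDerivation\n",
        " induced (> ", object@thresholds[["induce"]], "x): ",
        length(object@induced), " gene(s)\n",
        " repressed >= ", object@thresholds[["tier2"]], "x: ",
        length(object@repressed2), " gene(s)\n",
        " repressed >= ", object@thresholds[["tier4"]], "x: ",
        length(object@repressed4), " gene(s)\n", sep = "")
})

setMethod("show", "KMCurve", function(object) {
    cat("KMCurve:", sum(object@nEvent), "event(s),", sum(object@nCensor),
        "censored over", length(object@time), "distinct time(s); final S =",
        format(if (length(object@surv)) object@surv[length(object@surv)] else 1,
               digits = 4), "\n")
})

setMethod("show", "LogrankResult", function(object) {
    cat("Log-rank test: chisq =", format(object@chisq, digits = 4),
        "on 1 df, p =", format(object@p, digits = 4), "\n  O:",
        paste(names(object@observed), round(object@observed, 2),
              collapse = ", "),
        " E:", paste(names(object@expected), round(object@expected, 2),
                     collapse = ", "), "\n")
})

setMethod("show", "HazardRatioResult", function(object) {
    cat("HR = ", format(object@hr, digits = 3), " (95% CI ",
        format(object@ciLow, digits = 3), "-",
        format(object@ciHigh, digits = 3), "; ", object@method, ")\n",
        sep = "")
})

setMethod("show", "CutoffResult", function(object) {
    cat("ROC cutoff = ", format(object@cutoff, digits = 4),
        " (sens ", format(object@sensitivity, digits = 3),
        ", spec ", format(object@specificity, digits = 3),
        ", Youden J ", format(object@youdenJ, digits = 3), ")\n", sep = "")
})
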