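#' Accessors for ing4nfkb result objects
#'
#' Small accessor generics so downstream code never touches slots directly:
#' \code{geneSet()} and \code{medians()} for [ScoreModel-class] /
#' [ScoreResult-class] / [SignatureDerivation-class]; \code{scores()} and
#' \code{votes()} for [ScoreResult-class]; \code{survProb()} for
#' [KMCurve-class]; \code{cutoff()} and \code{youdenJ()} for
#' [CutoffResult-class]; \code{hr()} for [HazardRatioResult-class];
#' \code{exprsValues()} and \code{clinicalData()} for
#' [ExpressionCohort-class].
#'
#' @param object a result object of the matching class.
#' @return the slot contents (vectors/matrices/data.frame as documented per
#'   class).
#' @name accessors
#' @aliases geneSet medians scores votes survProb cutoff youdenJ hr
#'   exprsValues clinicalData
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 1, 4,
#'             dimnames = list("g1", paste0("s", 1:4)))
#' model <- fitScoreModel(ExpressionCohort(m), "g1")
#' medians(model)
NULL

#' @rdname accessors
#' @export
setGeneric("geneSet", function(object) standardGeneric("geneSet"))
#' @rdname accessors
#' @export
setGeneric("medians", function(object) standardGeneric("medians"))
#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("votes", function(object) standardGeneric("votes"))
#' @rdname accessors
#' @export
setGeneric("survProb", function(object) standardGeneric("survProb"))
#' @rdname accessors
#' @export
setGeneric("cutoff", function(object) standardGeneric("cutoff"))
#' @rdname accessors
#' @export
setGeneric("youdenJ", function(object) standardGeneric("youdenJ"))
#' @rdname accessors
#' @export
setGeneric("hr", function(object) standardGeneric("hr"))
#' @rdname accessors
#' @export
setGeneric("exprsValues", function(object) standardGeneric("exprsValues"))
#' @rdname accessors
#' @export
setGeneric("clinicalData", function(object) standardGeneric("clinicalData"))

#' @rdname accessors
setMethod("geneSet", "ScoreModel", function(object) object@geneSet)
#' @rdname accessors
setMethod("geneSet", "ScoreResult", function(object) object@geneSet)
#' @rdname accessors
setMethod("geneSet", "SignatureDerivation", function(object)
    list(induced = object@induced, repressed2 = object@repressed2,
         repressed4 = object@repressed4))
#' @rdname accessors
setMethod("medians", "ScoreModel", function(object) object@medians)
#' @rdname accessors
setMethod("scores", "ScoreResult", function(object) object@scores)
#' @rdname accessors
setMethod("votes", "ScoreResult", function(object) object@votes)
#' @rdname accessors
setMethod("survProb", "KMCurve", function(object)
    data.frame(time = object@time, nRisk = object@nRisk,
               nEvent = object@nEvent, nCensor = object@nCensor,
               surv = object@surv))
#' @rdname accessors
setMethod("cutoff", "CutoffResult", function(object) object@cutoff)
#' @rdname accessors
setMethod("youdenJ", "CutoffResult", function(object) object@youdenJ)
#' @rdname accessors
setMethod("hr", "HazardRatioResult", function(object)
    c(hr = object@hr, ciLow = object@ciLow, ciHigh = object@ciHigh))
#' @rdname accessors
setMethod("exprsValues", "ExpressionCohort", function(object)
    SummarizedExperiment::assay(object, "exprs"))
#' @rdname accessors
setMethod("clinicalData", "ExpressionCohort", function(object) {
    cd <- SummarizedExperiment::colData(object)
    out <- data.frame(sample = rownames(cd), time = cd$time, event = cd$event,
                      stringsAsFactors = FALSE)
    out[!is.na(out$time) & !is.na(out$event), , drop = FALSE]
})
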