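# The ING4/NF-kB gene score: each signature gene votes +1 for a tumor if
# its expression is strictly above the gene's median within the dataset
# being scored (ties and below-median values vote 0); the score is the
# vote sum. Medians are always recomputed within the scored dataset.

#' Fit a median-vote score model on a cohort
#'
#' Computes the within-dataset median of every signature gene present in
#' the cohort (midpoint interpolation for even n). Requested genes absent
#' from the cohort are dropped with a warning (the usable score range
#' shrinks accordingly); symbols are matched case-insensitively.
#'
#' @param cohort an [ExpressionCohort-class].
#' @param genes character vector of signature gene symbols.
#' @return a [ScoreModel-class].
#' @export
fitScoreModel <- function(cohort, genes) {
    m <- exprsValues(cohort)
    idx <- match(toupper(genes), toupper(rownames(m)))
    dropped <- genes[is.na(idx)]
    if (length(dropped))
        warning(length(dropped), " signature gene(s) absent from cohort, ",
                "dropped: ", paste(dropped, collapse = ", "))
    idx <- idx[!is.na(idx)]
    if (!length(idx)) stop("no signature gene present in the cohort")
    used <- rownames(m)[idx]
    med <- apply(m[idx, , drop = FALSE], 1, median)
    new("ScoreModel", geneSet = used, medians = setNames(med, used),
        droppedGenes = dropped)
}

#' Score samples with a fitted model
#'
#' Each gene votes 1 for a sample iff the sample's expression is strictly
#' greater than the gene's median (values at or below the median vote 0);
#' the sample's score sums the votes. The model must come from the same
#' cohort — medians are never transferred between datasets.
#'
#' @param cohort the [ExpressionCohort-class] the model was fitted on.
#' @param model a [ScoreModel-class].
#' @return a [ScoreResult-class].
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 5, 5, 9, 0, 10, 0, 10), 3, 4, byrow = TRUE,
#'             dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
#' co <- ExpressionCohort(m)
#' scores(scoreSamples(co, fitScoreModel(co, rownames(m))))  # 0 1 1 3
#' @export
scoreSamples <- function(cohort, model) {
    m <- exprsValues(cohort)
    idx <- match(model@geneSet, rownames(m))
    if (anyNA(idx))
        stop("model gene(s) missing from cohort; fit the model on the ",
             "cohort being scored")
    v <- m[idx, , drop = FALSE] > model@medians
    storage.mode(v) <- "integer"
    new("ScoreResult", scores = setNames(as.integer(colSums(v)), colnames(m)),
        votes = v, geneSet = model@geneSet)
}

#' Split a cohort into marker-low and marker-high groups
#'
#' Default split is at the marker's within-dataset median, values at or
#' below the median going to "low" — the same tie convention as the score's
#' own votes. An explicit cutoff (e.g. ROC-derived, see
#' [rocOptimalCutoff()]) is honored with the same at-or-below rule, so a
#' median cutoff and \code{cutoff = median(value)} are equivalent.
#'
#' @param cohort an [ExpressionCohort-class].
#' @param markerGene marker gene symbol, default \code{"ING4"}.
#' @param cutoff optional explicit cutoff; default within-dataset median.
#' @return factor (levels \code{low}, \code{high}) named by sample.
#' @export
splitByMarkerGene <- function(cohort, markerGene = "ING4", cutoff = NULL) {
    v <- markerValues(cohort, markerGene)
    if (is.null(cutoff)) cutoff <- median(v)
    lab <- factor(ifelse(v <= cutoff, "low", "high"),
                  levels = c("low", "high"))
    if (all(lab == "low"))
        warning("degenerate split: every sample is at or below the cutoff")
    names(lab) <- names(v)
    lab
}

markerValues <- function(cohort, markerGene) {
    m <- exprsValues(cohort)
    i <- match(toupper(markerGene), toupper(rownames(m)))
    if (is.na(i)) stop("marker gene '", markerGene, "' not in cohort")
    setNames(m[i, ], colnames(m))
}

#' Compare mean scores between two groups (pooled t-test)
#'
#' Unpaired two-tailed Student t-test with pooled variance,
#' \code{df = n1 + n2 - 2}. If both groups are constant and equal the
#' difference is 0 and p is reported as 1 with a warning (the statistic is
#' undefined); constant but different groups give p = 0.
#'
#' @param values numeric (e.g. signature scores), named or index-aligned
#'   with \code{labels}.
#' @param labels two-level factor of group membership.
#' @return list: \code{means} (per group), \code{difference} (first level
#'   minus second), \code{t}, \code{df}, \code{p}.
#' @export
compareGroupScores <- function(values, labels) {
    labels <- droplevels(as.factor(labels))
    if (nlevels(labels) != 2) stop("need exactly two groups")
    g <- split(as.numeric(values), labels)
    n <- lengths(g)
    if (any(n < 2)) stop("both groups need n >= 2")
    means <- vapply(g, mean, 0)
    diff <- means[[1]] - means[[2]]
    s2p <- ((n[1] - 1) * stats::var(g[[1]]) + (n[2] - 1) * stats::var(g[[2]])) /
        (sum(n) - 2)
    if (s2p == 0) {
        if (diff == 0) {
            warning("zero pooled variance and zero difference; p undefined, ",
                    "reporting 1")
            t <- 0; p <- 1
        } else {
            t <- sign(diff) * Inf; p <- 0
        }
    } else {
        t <- diff / sqrt(s2p * (1 / n[1] + 1 / n[2]))
        p <- 2 * pt(-abs(t), df = sum(n) - 2)
    }
    list(means = means, difference = unname(diff), t = unname(t),
         df = unname(sum(n) - 2), p = unname(p))
}
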