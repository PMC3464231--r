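# Tissue-microarray IHC scoring: punch aggregation, the 1.5 low/high
# dichotomization, 2x2 contingency analysis with an exact test, and the
# invasion-assay field-count average.

#' Aggregate punch scores to tumor-level IHC scores
#'
#' Each tumor contributes 2-3 punches (cores); its IHC score is the
#' arithmetic mean of the evaluable (non-missing) punch scores. Tumors with
#' no evaluable punch are kept in the output with \code{meanScore = NA} and
#' flagged non-evaluable so each downstream analysis can use its own
#' maximal n.
#'
#' @param punches punch table (see [readPunchTable()]).
#' @param marker marker to aggregate (e.g. \code{"ING4"}, \code{"pp65"}).
#' @return \code{data.frame}: \code{tumor}, \code{meanScore},
#'   \code{nPunches} (evaluable punches), \code{evaluable}.
#' @export
aggregatePunches <- function(punches, marker) {
    punches <- validatePunchTable(punches)
    p <- punches[punches$marker == marker, , drop = FALSE]
    if (!nrow(p)) stop("no punches for marker '", marker, "'")
    sp <- split(p$score, p$tumor)
    out <- data.frame(
        tumor = names(sp),
        meanScore = vapply(sp, function(x)
            if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE), 0),
        nPunches = vapply(sp, function(x) sum(!is.na(x)), 0L),
        stringsAsFactors = FALSE, row.names = NULL)
    out$evaluable <- out$nPunches > 0L
    out
}

#' Dichotomize tumor IHC scores into low/high calls
#'
#' Scores strictly below the cutoff are "low"; scores at or above it are
#' "high" (so the boundary 1.5 is high). \code{NA} scores stay \code{NA}.
#'
#' @param scores numeric scores in \code{[0, 3]} (or any marker scale).
#' @param cutoff dichotomization cutoff, default 1.5.
#' @return factor with levels \code{low}, \code{high}, named like
#'   \code{scores}.
#' @export
dichotomize <- function(scores, cutoff = 1.5) {
    out <- factor(ifelse(is.na(scores), NA,
                         ifelse(scores < cutoff, "low", "high")),
                  levels = c("low", "high"))
    names(out) <- names(scores)
    out
}

#' Cross-tabulate two per-tumor marker calls
#'
#' Tumors present in both call vectors (matched by name) and non-missing in
#' both are tabulated; rows follow \code{callsA}, columns \code{callsB}.
#'
#' @param callsA,callsB factors named by tumor id (any two-level factors,
#'   e.g. low/high marker calls or a pathology annotation).
#' @param labels optional \code{c(rowMarker, colMarker)} names for display.
#' @return integer 2x2 matrix with dimnames.
#' @export
crossTab <- function(callsA, callsB, labels = c("A", "B")) {
    ids <- intersect(names(callsA), names(callsB))
    a <- callsA[ids]; b <- callsB[ids]
    keep <- !is.na(a) & !is.na(b)
    if (!any(keep)) stop("no tumors with both calls available")
    tab <- table(a[keep], b[keep])
    names(dimnames(tab)) <- labels
    m <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
    m
}

#' Within-row percentages, printed-report rounding
#'
#' Nearest-integer percentages; halves round away from zero (so 77/227
#' displays as 34\%).
#'
#' @param tab contingency matrix (counts).
#' @return matrix of integer percentages, same shape.
#' @export
rowPercents <- function(tab) {
    pct <- 100 * sweep(tab, 1, rowSums(tab), "/")
    roundHalfAway(pct)
}

# round half away from zero (display convention for report percentages)
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided point-probability definition: with margins fixed, p is the sum
#' of hypergeometric probabilities of all tables whose point probability
#' does not exceed the observed table's (within relative tolerance 1e-9, to
#' avoid float-ordering artifacts).
#'
#' @param tab 2x2 integer matrix (or a vector \code{c(a, b, c, d)} read
#'   row-wise).
#' @return two-sided p-value.
#' @examples
#' fisherExact2x2(matrix(c(29, 33, 48, 118), 2, byrow = TRUE))  # ~0.018
#' @export
fisherExact2x2 <- function(tab) {
    if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
    if (!all(dim(tab) == 2)) stop("need a 2x2 table")
    if (any(tab < 0) || any(tab != floor(tab)))
        stop("counts must be non-negative integers")
    n <- sum(tab)
    if (n == 0) stop("all-zero table")
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1])
    lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
    support <- lo:hi
    probs <- dhyper(support, c1, n - c1, r1)
    pObs <- dhyper(tab[1, 1], c1, n - c1, r1)
    sum(probs[probs <= pObs * (1 + 1e-9)])
}

#' Mean cell count per microscope field
#'
#' Invasion assays count migrated cells by averaging a minimum number of
#' field images per membrane; the fold difference between two conditions is
#' the ratio of their mean counts.
#'
#' @param counts cell counts, one per field image.
#' @param minFields minimum images required, default 4.
#' @return mean count per field.
#' @export
fieldCountAverage <- function(counts, minFields = 4) {
    if (length(counts) < minFields)
        stop("need >= ", minFields, " field images, got ", length(counts))
    mean(counts)
}
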