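# Relative qPCR quantification (delta-delta-Ct) and the induced/repressed
# gene-filter cascade. Amplification efficiency is fixed at 2 (the
# delta-delta-Ct assumption); replicates are averaged on the Ct scale
# before any differencing.

#' Delta-delta-Ct fold change for one gene and contrast
#'
#' Replicate Ct values are averaged per (gene, condition); then
#' \deqn{\Delta\Delta C_t = (Ct_{g,cond} - Ct_{ref,cond}) -
#'       (Ct_{g,base} - Ct_{ref,base}), \quad fold = 2^{-\Delta\Delta C_t}.}
#'
#' @param ct Ct \code{data.frame} (see [readCtTable()]).
#' @param gene target gene.
#' @param condition,baseline contrast condition labels.
#' @param referenceGene housekeeping gene, default \code{"GAPDH"}.
#' @param sample optional sample/cell-line id to restrict to.
#' @return one-row \code{data.frame}: \code{gene}, \code{condition},
#'   \code{baseline}, \code{ddct}, \code{fold}.
#' @examples
#' ct <- data.frame(sample = "T47D",
#'                  gene = rep(c("IL8", "GAPDH"), each = 2),
#'                  condition = rep(c("PMA", "vehicle"), 2),
#'                  replicate = 1L,
#'                  ct = c(20, 25, 20, 20))
#' ddctFoldChange(ct, "IL8", "PMA", "vehicle")  # fold = 32
#' @export
ddctFoldChange <- function(ct, gene, condition, baseline,
                           referenceGene = "GAPDH", sample = NULL) {
    if (!is.null(sample)) ct <- ct[ct$sample %in% sample, , drop = FALSE]
    meanCt <- function(g, cond) {
        v <- ct$ct[toupper(ct$gene) == toupper(g) & ct$condition == cond]
        if (!length(v)) stop("no Ct values for gene '", g,
                             "' in condition '", cond, "'")
        if (any(!is.finite(v))) stop("non-finite Ct for gene '", g, "'")
        mean(v)
    }
    ddct <- (meanCt(gene, condition) - meanCt(referenceGene, condition)) -
            (meanCt(gene, baseline) - meanCt(referenceGene, baseline))
    data.frame(gene = gene, condition = condition, baseline = baseline,
               ddct = ddct, fold = 2^(-ddct), stringsAsFactors = FALSE)
}

#' Fold changes for many genes at once
#'
#' @inheritParams ddctFoldChange
#' @param genes character vector of target genes.
#' @return \code{data.frame}, one row per gene.
#' @export
foldChangeTable <- function(ct, genes, condition, baseline,
                            referenceGene = "GAPDH", sample = NULL) {
    do.call(rbind, lapply(genes, ddctFoldChange, ct = ct,
                          condition = condition, baseline = baseline,
                          referenceGene = referenceGene, sample = sample))
}

#' Genes induced more than a threshold-fold
#'
#' Strict inequality: a gene induced exactly threshold-fold is excluded.
#'
#' @param folds named numeric vector of fold changes (one per gene).
#' @param threshold induction threshold, default 2.
#' @return character vector of induced genes (input order).
#' @export
selectInduced <- function(folds, threshold = 2) {
    if (!length(folds)) return(character(0))
    stopifnot(!is.null(names(folds)))
    names(folds)[folds > threshold]
}

#' Repression ratio between two PMA-induction folds
#'
#' Ratio of the PMA-induction fold in the control line to that in the
#' ING4-overexpressing line; e.g. IL8 induced 1070-fold in control but only
#' 35-fold under ING4 gives a ratio of about 30.6.
#'
#' @param foldControl,foldIng4 positive induction folds.
#' @return \code{foldControl / foldIng4}.
#' @export
repressionRatio <- function(foldControl, foldIng4) {
    if (any(foldIng4 <= 0)) stop("ING4-line fold must be positive")
    foldControl / foldIng4
}

#' Select repressed genes within the induced set
#'
#' Inclusive inequality (ratio >= threshold), matching the "4-fold or
#' higher" tier wording; the 2-fold tier uses the same rule for
#' consistency.
#'
#' @param induced character vector of induced genes.
#' @param ratios named numeric repression ratios.
#' @param threshold repression threshold (2 or 4).
#' @return character vector of genes in the tier.
#' @export
selectRepressed <- function(induced, ratios, threshold) {
    stopifnot(!is.null(names(ratios)))
    induced[induced %in% names(ratios)[ratios >= threshold]]
}

#' Run the full signature-derivation cascade
#'
#' From per-gene PMA-induction folds in the control and ING4 lines:
#' induced genes (control fold strictly > \code{induceThreshold}), then the
#' nested repressed tiers by repression ratio (>= \code{tier2},
#' >= \code{tier4}).
#'
#' @param foldsControl,foldsIng4 named numeric induction folds per line.
#' @param ratios optional named repression ratios to use instead of
#'   \code{foldsControl / foldsIng4} (e.g. from a direct ING4-vs-control
#'   expression contrast under PMA).
#' @param induceThreshold,tier2,tier4 cascade thresholds (defaults 2, 2, 4).
#' @return a [SignatureDerivation-class].
#' @examples
#' ctrl <- c(IL6 = 26, IL8 = 1070, PTGS2 = 212)
#' ing4 <- c(IL6 = 8, IL8 = 35, PTGS2 = 10)
#' deriveSignature(ctrl, ing4)
#' @export
deriveSignature <- function(foldsControl, foldsIng4, ratios = NULL,
                            induceThreshold = 2, tier2 = 2, tier4 = 4) {
    induced <- selectInduced(foldsControl, induceThreshold)
    if (is.null(ratios)) {
        missing <- setdiff(induced, names(foldsIng4))
        if (length(missing))
            stop("no ING4-line fold for induced gene(s): ",
                 paste(missing, collapse = ", "))
        ratios <- repressionRatio(foldsControl[induced], foldsIng4[induced])
    }
    new("SignatureDerivation",
        induced = induced,
        repressed2 = selectRepressed(induced, ratios, tier2),
        repressed4 = selectRepressed(induced, ratios, tier4),
        ratios = ratios[names(ratios) %in% induced],
        thresholds = c(induce = induceThreshold, tier2 = tier2,
                       tier4 = tier4))
}

#' Fit a qPCR standard curve
#'
#' Least-squares line of Ct on log10 copy number; Ct must decrease with
#' template amount (negative slope), otherwise the curve is non-amplifying.
#'
#' @param log10Copies,ct numeric vectors (>= 2 distinct points).
#' @return list with \code{slope}, \code{intercept}, \code{points}.
#' @export
fitStandardCurve <- function(log10Copies, ct) {
    stopifnot(length(log10Copies) == length(ct))
    if (length(unique(log10Copies)) < 2)
        stop("standard curve needs >= 2 distinct copy-number points")
    fit <- lm(ct ~ log10Copies)
    slope <- unname(coef(fit)[2])
    if (!is.finite(slope) || slope >= 0)
        stop("non-amplifying standard curve (slope >= 0)")
    list(slope = slope, intercept = unname(coef(fit)[1]),
         points = data.frame(log10Copies = log10Copies, ct = ct))
}

#' Copy number from a standard curve
#'
#' @param ct observed Ct.
#' @param curve fitted curve from [fitStandardCurve()].
#' @return estimated copies, \code{10^((ct - intercept)/slope)}.
#' @export
copiesFromStandardCurve <- function(ct, curve) {
    if (curve$slope >= 0) stop("non-amplifying standard curve (slope >= 0)")
    10^((ct - curve$intercept) / curve$slope)
}

#' Normalized reporter activity and fold induction
#'
#' Luciferase activity is expressed as relative light units per microgram
#' of protein, normalized to the integrated \code{luc2} reporter copy
#' number; fold induction is the ratio of normalized activities.
#'
#' @param rlu relative light units.
#' @param proteinUg micrograms of total protein (> 0).
#' @param luc2Copies reporter gene copies (> 0).
#' @return normalized activity (numeric).
#' @export
reporterActivity <- function(rlu, proteinUg, luc2Copies) {
    if (any(proteinUg <= 0)) stop("protein amount must be positive")
    if (any(luc2Copies <= 0)) stop("luc2 copy number must be positive")
    rlu / proteinUg / luc2Copies
}

#' @rdname reporterActivity
#' @param treated,untreated normalized activities from [reporterActivity()].
#' @export
foldInduction <- function(treated, untreated) {
    if (any(untreated <= 0)) stop("untreated activity must be positive")
    treated / untreated
}
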