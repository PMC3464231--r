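# Minimal GEO SOFT (GDS dialect) reader. Local files only: the package
# never touches the network. Only the dataset table between
# !dataset_table_begin / !dataset_table_end is parsed; metadata lines
# (^, !, #) outside it are ignored.

#' Read a local GDS SOFT-format expression file
#'
#' Parses the dataset table of a GDS SOFT file (columns \code{ID_REF},
#' \code{IDENTIFIER}, then one column per GSM sample). Gene symbols are
#' taken from \code{IDENTIFIER}; when several probes map to the same symbol
#' they are collapsed by the stated policy.
#'
#' @param path local SOFT file.
#' @param collapse duplicate-symbol policy: \code{"maxMean"} keeps the probe
#'   with the highest mean expression across samples (the common
#'   signature-scoring convention); \code{"first"} keeps the first probe in
#'   file order.
#' @return an [ExpressionCohort-class] (no clinical annotation; supply that
#'   separately via [ExpressionCohort()] or [readExpressionTable()]).
#' @export
readSoftGDS <- function(path, collapse = c("maxMean", "first")) {
    collapse <- match.arg(collapse)
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    beg <- grep("^!dataset_table_begin", lines, ignore.case = TRUE)
    end <- grep("^!dataset_table_end", lines, ignore.case = TRUE)
    if (length(beg) != 1)
        stop("SOFT file lacks a !dataset_table_begin delimiter")
    if (length(end) != 1 || end <= beg + 1)
        stop("SOFT file lacks a !dataset_table_end delimiter")
    tab <- read.delim(text = lines[(beg + 1):(end - 1)], header = TRUE,
                      check.names = FALSE, colClasses = "character")
    if (!all(c("ID_REF", "IDENTIFIER") %in% colnames(tab)))
        stop("dataset table needs ID_REF and IDENTIFIER columns")
    sampleCols <- setdiff(colnames(tab), c("ID_REF", "IDENTIFIER"))
    if (length(sampleCols) == 0) stop("SOFT dataset table has zero samples")
    vals <- suppressWarnings(
        matrix(as.numeric(as.matrix(tab[, sampleCols, drop = FALSE])),
               nrow(tab), length(sampleCols)))
    colnames(vals) <- sampleCols
    sym <- tab$IDENTIFIER
    keep <- !is.na(sym) & nzchar(sym) & rowSums(is.na(vals)) == 0
    vals <- vals[keep, , drop = FALSE]
    sym <- sym[keep]
    if (!nrow(vals)) stop("no complete probe rows in SOFT dataset table")
    if (anyDuplicated(toupper(sym))) {
        key <- toupper(sym)
        pick <- switch(collapse,
            maxMean = vapply(split(seq_along(key), key)[unique(key)],
                             function(i) i[which.max(rowMeans(
                                 vals[i, , drop = FALSE]))], integer(1)),
            first = vapply(split(seq_along(key), key)[unique(key)],
                           function(i) i[1L], integer(1)))
        pick <- sort(unname(pick))
        vals <- vals[pick, , drop = FALSE]
        sym <- sym[pick]
    }
    ExpressionCohort(vals, geneIds = sym, sampleIds = sampleCols)
}
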