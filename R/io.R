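# Tabular IO. All tables are UTF-8, tab-delimited by default; comma is
# accepted via `sep`. Gene symbols are stored case-preserved and matched
# case-insensitively elsewhere.

#' Read a genes x samples expression table
#'
#' First column holds gene identifiers, remaining columns one sample each,
#' with a header row of sample ids. Non-numeric expression cells and
#' duplicate gene ids are rejected with a cell-level report.
#'
#' @param path expression table (TSV by default).
#' @param clinicalPath optional per-sample clinical table with columns
#'   \code{sample}, \code{time}, \code{event}; every sample must exist in
#'   the matrix.
#' @param sep field separator, \code{"\t"} or \code{","}.
#' @return an [ExpressionCohort-class].
#' @export
readExpressionTable <- function(path, clinicalPath = NULL, sep = "\t") {
    raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                      colClasses = "character", fileEncoding = "UTF-8")
    if (ncol(raw) < 2) stop("expression table needs gene ids plus >= 1 sample")
    genes <- raw[[1]]
    if (anyDuplicated(genes))
        stop("duplicate gene ids: ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    vals <- as.matrix(raw[, -1, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
    bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)
    if (nrow(bad))
        stop("non-numeric expression cell(s): ",
             paste(sprintf("gene '%s' sample '%s' ('%s')",
                           genes[bad[, 1]], colnames(vals)[bad[, 2]],
                           vals[bad]), collapse = "; "))
    if (anyNA(num))
        stop("missing expression cells present; impute or clean upstream")
    clinical <- if (!is.null(clinicalPath))
        read.delim(clinicalPath, sep = sep, header = TRUE,
                   fileEncoding = "UTF-8")
    ExpressionCohort(num, geneIds = genes, sampleIds = colnames(vals),
                     clinical = clinical)
}

#' Write an ExpressionCohort back to disk
#'
#' Inverse of [readExpressionTable()]: read-then-write round-trips the
#' cohort up to float serialization (6 significant digits).
#'
#' @param cohort an [ExpressionCohort-class].
#' @param path output path.
#' @param clinicalPath optional path for the clinical annotation.
#' @param sep field separator.
#' @return invisibly, \code{path}.
#' @export
writeExpressionTable <- function(cohort, path, clinicalPath = NULL,
                                 sep = "\t") {
    m <- exprsValues(cohort)
    df <- data.frame(gene = rownames(m),
                     apply(m, 2, function(x) formatSig(x)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("gene", colnames(m))
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    if (!is.null(clinicalPath)) {
        cl <- clinicalData(cohort)
        cl$event <- as.integer(cl$event)
        write.table(cl, clinicalPath, sep = sep, quote = FALSE,
                    row.names = FALSE, fileEncoding = "UTF-8")
    }
    invisible(path)
}

#' Read a Ct table
#'
#' Expected columns: \code{sample}, \code{gene}, \code{condition},
#' \code{replicate}, \code{ct}. Ct values must be finite and positive and a
#' designated reference gene must appear in every (sample, condition) cell.
#'
#' @param path TSV/CSV path.
#' @param referenceGene reference (housekeeping) gene, default
#'   \code{"GAPDH"}.
#' @param sep field separator.
#' @return a validated \code{data.frame}.
#' @export
readCtTable <- function(path, referenceGene = "GAPDH", sep = "\t") {
    ct <- read.delim(path, sep = sep, header = TRUE, fileEncoding = "UTF-8")
    validateCtTable(ct, referenceGene)
}

#' @rdname readCtTable
#' @param ct an in-memory Ct \code{data.frame} to validate.
#' @export
validateCtTable <- function(ct, referenceGene = "GAPDH") {
    need <- c("sample", "gene", "condition", "replicate", "ct")
    if (!all(need %in% colnames(ct)))
        stop("Ct table needs columns: ", paste(need, collapse = ", "))
    if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
        stop("Ct values must be finite and > 0")
    cells <- unique(ct[, c("sample", "condition")])
    refOk <- vapply(seq_len(nrow(cells)), function(i)
        any(ct$sample == cells$sample[i] & ct$condition == cells$condition[i] &
            toupper(ct$gene) == toupper(referenceGene)), logical(1))
    if (!all(refOk))
        stop("reference gene '", referenceGene,
             "' missing in some sample/condition cells")
    ct
}

#' Read a TMA punch-score table
#'
#' Expected columns: \code{tumor}, \code{marker}, \code{punch},
#' \code{score}. Scores are the pathologist's ordinal 0-3 nuclear-staining
#' intensities; missing (non-evaluable) punches are \code{NA}.
#'
#' @param path TSV/CSV path.
#' @param sep field separator.
#' @return a validated \code{data.frame}.
#' @export
readPunchTable <- function(path, sep = "\t") {
    p <- read.delim(path, sep = sep, header = TRUE, fileEncoding = "UTF-8")
    validatePunchTable(p)
}

#' @rdname readPunchTable
#' @param punches an in-memory punch \code{data.frame} to validate.
#' @export
validatePunchTable <- function(punches) {
    need <- c("tumor", "marker", "punch", "score")
    if (!all(need %in% colnames(punches)))
        stop("punch table needs columns: ", paste(need, collapse = ", "))
    sc <- punches$score
    if (any(!is.na(sc) & !(sc %in% 0:3)))
        stop("punch scores must be in {0,1,2,3} or NA")
    nP <- table(paste(punches$tumor, punches$marker))
    if (any(nP < 1 | nP > 3))
        stop("each tumor-marker must have 1-3 punches")
    punches
}

#' Read a gene-set file
#'
#' One gene symbol per line; blank lines and \code{#} comments ignored.
#'
#' @param path text file path.
#' @return character vector of gene symbols.
#' @export
readGeneSet <- function(path) {
    x <- trimws(readLines(path, encoding = "UTF-8"))
    x <- sub("#.*$", "", x)
    x <- trimws(x)
    x[nzchar(x)]
}

#' Write a result object deterministically
#'
#' Serializes a named list of scalars/vectors or a \code{data.frame} with a
#' fixed field order and floats at 6 significant digits, so identical
#' results yield byte-identical files.
#'
#' @param results named list or \code{data.frame}.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return invisibly, \code{path}.
#' @export
writeResults <- function(results, path, format = c("tsv", "json")) {
    format <- match.arg(format)
    if (format == "json") {
        jsonlite::write_json(roundForOutput(results), path,
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        return(invisible(path))
    }
    df <- if (is.data.frame(results)) results else {
        stopifnot(!is.null(names(results)))
        as.data.frame(lapply(results, function(x)
            if (length(x) == 1) x else paste(formatSig(x), collapse = ",")),
            optional = TRUE, check.names = FALSE)
    }
    out <- as.data.frame(lapply(df, function(x)
        if (is.numeric(x)) formatSig(x) else as.character(x)),
        check.names = FALSE, optional = TRUE)
    colnames(out) <- colnames(df)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(path)
}

# 6-significant-digit decimal rendering shared by the writers
formatSig <- function(x) {
    if (!is.numeric(x)) return(as.character(x))
    vapply(x, function(v) {
        if (is.na(v)) "NA"
        else if (v == floor(v) && abs(v) < 1e15) format(v, scientific = FALSE)
        else format(signif(v, 6), scientific = FALSE, trim = TRUE)
    }, character(1))
}

roundForOutput <- function(x) {
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, roundForOutput))
    if (is.data.frame(x)) {
        x[] <- lapply(x, function(col)
            if (is.numeric(col)) signif(col, 6) else col)
        return(x)
    }
    if (is.numeric(x)) signif(x, 6) else x
}
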