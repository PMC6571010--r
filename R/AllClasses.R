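#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom BiocGenerics counts
NULL

.is_wholenumber <- function(x, tol = 1e-8) {
    is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

#' Gene-level read-count container
#'
#' A \linkS4class{SummarizedExperiment} subclass holding a non-negative
#' integer gene x sample count matrix (assay \code{"counts"}) together with
#' per-sample library sizes in \code{colData(x)$librarySize}. Library sizes
#' are fixed when the object is built -- they are the column sums of the
#' matrix at load time -- and deliberately do not change when genes are
#' filtered afterwards, so RPKM denominators do not drift with filter
#' settings.
#'
#' @seealso [readCounts()], [filterLowExpression()], [rpkmNormalize()]
#' @aliases CountMatrix-class
#' @exportClass CountMatrix
setClass("CountMatrix", contains = "SummarizedExperiment")

setValidity("CountMatrix", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- assay(object, "counts")
        if (!.is_wholenumber(m))
            msg <- c(msg, "counts must be finite integers")
        else if (any(m < 0))
            msg <- c(msg, "counts must be non-negative")
    }
    if (!"librarySize" %in% colnames(colData(object)))
        msg <- c(msg, "colData column 'librarySize' is required")
    else if (any(colData(object)$librarySize < 0))
        msg <- c(msg, "library sizes must be non-negative")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a CountMatrix
#'
#' @param counts integer matrix, genes in rows, samples in columns; both
#'   dimensions must be named.
#' @param librarySizes per-sample total read counts. Defaults to the column
#'   sums of \code{counts}; pass explicit values when the matrix was already
#'   subset so that the original totals are preserved.
#' @return A [CountMatrix-class] object.
#' @examples
#' m <- matrix(c(1L, 3L, 5L, 2L, 4L, 6L), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' cm <- CountMatrix(m)
#' librarySizes(cm)
#' @export
CountMatrix <- function(counts, librarySizes = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("'counts' must have row (gene) and column (sample) names")
    storage.mode(counts) <- "integer"
    if (is.null(librarySizes))
        librarySizes <- colSums(counts)
    if (length(librarySizes) != ncol(counts))
        stop("'librarySizes' must have one entry per sample")
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        colData = DataFrame(librarySize = as.numeric(librarySizes),
                            row.names = colnames(counts)))
    new("CountMatrix", se)
}

#' @describeIn CountMatrix library sizes recorded at load time
#' @param x,object a \code{CountMatrix}
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @rdname CountMatrix
#' @export
setMethod("librarySizes", "CountMatrix", function(x) {
    setNames(colData(x)$librarySize, colnames(x))
})

#' @rdname CountMatrix
#' @export
setMethod("counts", "CountMatrix", function(object) assay(object, "counts"))

#' Normalized log2-RPKM expression container
#'
#' A \linkS4class{SummarizedExperiment} subclass holding log2(RPKM + offset)
#' values (assay \code{"logRPKM"}) on the filtered gene set. The
#' normalization record (method and log offset) lives in
#' \code{metadata(x)$normalization}.
#'
#' @aliases ExpressionMatrix-class
#' @seealso [rpkmNormalize()], [pcomp()]
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
    msg <- character()
    if (!"logRPKM" %in% assayNames(object))
        msg <- c(msg, "assay 'logRPKM' is required")
    else if (!all(is.finite(assay(object, "logRPKM"))))
        msg <- c(msg, "expression values must be finite")
    if (is.null(metadata(object)$normalization))
        msg <- c(msg, "metadata 'normalization' record is required")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix from a log-scale value matrix
#'
#' Used by [rpkmNormalize()] and by the synthetic generators; values are
#' taken as already being on the log2 scale.
#'
#' @param values numeric matrix of log2 expression values with dimnames.
#' @param normalization list describing how the values were produced.
#' @return An [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(values,
                             normalization = list(method = "external",
                                                  logOffset = NA_real_)) {
    values <- as.matrix(values)
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("'values' must have row (gene) and column (sample) names")
    se <- SummarizedExperiment(assays = list(logRPKM = values))
    metadata(se)$normalization <- normalization
    new("ExpressionMatrix", se)
}

#' @describeIn ExpressionMatrix the log2 expression matrix
#' @param x an \code{ExpressionMatrix}
#' @export
setGeneric("logExpr", function(x) standardGeneric("logExpr"))

#' @rdname ExpressionMatrix
#' @export
setMethod("logExpr", "ExpressionMatrix", function(x) assay(x, "logRPKM"))

#' Pairwise regression fit with outlier band
#'
#' The result of regressing one sample's log2 expression (the target, on y)
#' on another sample's (the comparator, on x) across all genes, together
#' with the per-gene side relative to the band: +1 above, -1 below, 0
#' inside. The band is by default the pointwise prediction interval at
#' \code{bandLevel} (the conventional 99.9% bands correspond to
#' \code{bandLevel = 0.999}).
#'
#' @aliases PairwiseFit-class
#' @seealso [fitPair()], [plotPairFit()]
#' @exportClass PairwiseFit
setClass("PairwiseFit",
    slots = c(target = "character", comparator = "character",
              slope = "numeric", intercept = "numeric",
              residualSD = "numeric", nGenes = "integer",
              bandLevel = "numeric", bandType = "character",
              side = "integer", x = "numeric", y = "numeric"))

setValidity("PairwiseFit", function(object) {
    msg <- character()
    if (object@nGenes < 3L)
        msg <- c(msg, "at least 3 genes are needed for a band")
    if (object@bandLevel <= 0 || object@bandLevel >= 1)
        msg <- c(msg, "bandLevel must lie strictly between 0 and 1")
    if (length(object@side) != object@nGenes ||
        length(object@x) != object@nGenes ||
        length(object@y) != object@nGenes)
        msg <- c(msg, "side, x and y must have one entry per gene")
    if (!all(object@side %in% c(-1L, 0L, 1L)))
        msg <- c(msg, "side values must be -1, 0 or +1")
    if (length(msg)) msg else TRUE
})

#' @describeIn PairwiseFit per-gene band side (+1 above, -1 below, 0 inside)
#' @param x a \code{PairwiseFit}
#' @export
setGeneric("outlierSides", function(x) standardGeneric("outlierSides"))

#' @rdname PairwiseFit
#' @export
setMethod("outlierSides", "PairwiseFit", function(x) x@side)

setMethod("show", "PairwiseFit", function(object) {
    cat("PairwiseFit:", object@target, "~", object@comparator, "\n")
    cat(sprintf("  %d genes, slope %.4f, intercept %.4f, residual SD %.4f\n",
                object@nGenes, object@slope, object@intercept,
                object@residualSD))
    cat(sprintf("  %s band at level %.4f: %d above, %d below\n",
                object@bandType, object@bandLevel,
                sum(object@side == 1L), sum(object@side == -1L)))
})

#' Per-sample differential expression result
#'
#' Holds one row per (gene, sample) call with the consensus direction, the
#' number of pairwise fits in which the gene fell outside the band, and the
#' confirming one-sample t-test statistic and two-sided p-value. The
#' parameter record keeps the band level, test alpha and allowed shared
#' samples used for the run.
#'
#' @aliases PCompResult-class
#' @seealso [pcomp()]
#' @exportClass PCompResult
setClass("PCompResult",
    slots = c(calls = "data.frame", parameters = "list"))

setValidity("PCompResult", function(object) {
    need <- c("gene_id", "sample_id", "direction", "n_pairs_outside",
              "t_statistic", "p_value")
    msg <- character()
    if (!all(need %in% names(object@calls)))
        msg <- c(msg, paste("calls must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(object@calls[c("gene_id", "sample_id")]))
            msg <- c(msg, "a gene may appear at most once per sample")
        if (!all(object@calls$direction %in% c("up", "down")))
            msg <- c(msg, "direction must be 'up' or 'down'")
        p <- object@calls$p_value
        if (length(p) && (any(p < 0) || any(p > 1)))
            msg <- c(msg, "p-values must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn PCompResult the calls table (one row per gene x sample)
#' @param x,object a \code{PCompResult}
#' @export
setGeneric("deCalls", function(x) standardGeneric("deCalls"))

#' @rdname PCompResult
#' @export
setMethod("deCalls", "PCompResult", function(x) x@calls)

#' @describeIn PCompResult the parameter record of the run
#' @export
setGeneric("runParameters", function(x) standardGeneric("runParameters"))

#' @rdname PCompResult
#' @export
setMethod("runParameters", "PCompResult", function(x) x@parameters)

setMethod("show", "PCompResult", function(object) {
    calls <- object@calls
    cat("PCompResult:", nrow(calls), "calls in",
        length(unique(calls$sample_id)), "samples\n")
    if (nrow(calls)) {
        tab <- table(calls$sample_id, calls$direction)
        print(tab)
    }
    p <- object@parameters
    cat(sprintf("  bandLevel %.4g, testAlpha %.4g, allowedShared %d\n",
                p$bandLevel, p$testAlpha, p$allowedShared))
})

#' One fusion caller's report for one sample
#'
#' Parsed calls from a single caller on a single sample, in the package's
#' canonical column layout. \code{filtered} records whether the per-caller
#' confidence filter has already been applied.
#'
#' @aliases CallerReport-class
#' @seealso [parseCallerReport()], [filterConfidence()], [consensusFusions()]
#' @exportClass CallerReport
setClass("CallerReport",
    slots = c(caller = "character", sample = "character",
              calls = "data.frame", filtered = "logical",
              nDropped = "integer"))

.caller_call_cols <- c("gene5p", "gene3p", "chrom5p", "pos5p", "chrom3p",
                       "pos3p", "spanning_reads", "confidence")

setValidity("CallerReport", function(object) {
    msg <- character()
    if (!object@caller %in% c("ericscript", "jaffa", "fusioncatcher",
                              "canonical"))
        msg <- c(msg, "unknown caller tag")
    if (!all(.caller_call_cols %in% names(object@calls)))
        msg <- c(msg, paste("calls must have columns:",
                            paste(.caller_call_cols, collapse = ", ")))
    else if (nrow(object@calls)) {
        if (any(object@calls$spanning_reads < 1))
            msg <- c(msg, "spanning_reads must be >= 1 after parsing")
        if (any(object@calls$pos5p < 1) || any(object@calls$pos3p < 1))
            msg <- c(msg, "junction positions must be >= 1")
        if (any(!nzchar(object@calls$gene5p)) ||
            any(!nzchar(object@calls$gene3p)))
            msg <- c(msg, "gene symbols must be non-empty")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn CallerReport the parsed calls table
#' @param x,object a \code{CallerReport}
#' @export
setGeneric("fusionCalls", function(x) standardGeneric("fusionCalls"))

#' @rdname CallerReport
#' @export
setMethod("fusionCalls", "CallerReport", function(x) x@calls)

setMethod("show", "CallerReport", function(object) {
    cat(sprintf("CallerReport: %s / sample %s, %d calls%s (%d dropped at parse)\n",
                object@caller, object@sample, nrow(object@calls),
                if (object@filtered) " [confidence-filtered]" else "",
                object@nDropped))
})
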