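## Pipeline wrappers: compose the modules into the two workflows and
## freeze the on-disk output layout (column orders, rounding) so runs are
## reproducible byte for byte given the same inputs and parameters.

.write_tsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.write_manifest <- function(dir, params) {
    yaml::write_yaml(params, file.path(dir, "run_manifest.yaml"))
}

#' Run the per-sample differential expression pipeline
#'
#' Composes the expression pipeline end to end: read counts, filter
#' low-expressed genes, RPKM-normalize to log2, run [pcomp()], and
#' optionally score direction concordance against an external
#' differential-expression list. Writes de_calls.tsv (gene, sample,
#' direction, pairs outside, t, p with p printed in full precision),
#' optionally concordance.tsv, and an effective-parameter manifest.
#'
#' @param countsFile merged count TSV (see [readCounts()]).
#' @param annotation GTF path, gene-table TSV path, or a \code{GRanges}
#'   annotation as returned by [geneLengthsFromGtf()].
#' @param outDir output directory (created if needed).
#' @param referenceFile optional TSV with columns gene, sample, direction.
#' @param minSamples,minCount low-expression filter settings.
#' @param bandLevel,testAlpha,allowedShared,bandType [pcomp()] settings.
#' @param logOffset [rpkmNormalize()] offset.
#' @param plotPairs optional character vector "target:comparator" of pair
#'   plots to render as PDF.
#' @return The [PCompResult-class], invisibly.
#' @export
runPComp <- function(countsFile, annotation, outDir,
                     referenceFile = NULL, minSamples = 6L, minCount = 1L,
                     bandLevel = 0.999, testAlpha = 0.05,
                     allowedShared = 0L, bandType = "prediction",
                     logOffset = 1, plotPairs = NULL) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    ann <- .resolve_annotation(annotation)
    cm <- readCounts(countsFile)
    message(sprintf("loaded %d genes x %d samples", nrow(cm), ncol(cm)))
    cmF <- filterLowExpression(cm, minSamples = minSamples,
                               minCount = minCount)
    message(sprintf("low-expression filter: %d -> %d genes",
                    nrow(cm), nrow(cmF)))
    lens <- setNames(S4Vectors::mcols(ann)$length, names(ann))
    cmF <- cmF[rownames(cmF) %in% names(lens), ]
    expr <- rpkmNormalize(cmF, lens, logOffset = logOffset)
    res <- pcomp(expr, bandLevel = bandLevel, testAlpha = testAlpha,
                 allowedShared = allowedShared, bandType = bandType)
    message(sprintf("PComp: %d calls", nrow(deCalls(res))))
    .write_tsv(deCalls(res), file.path(outDir, "de_calls.tsv"))
    if (!is.null(referenceFile)) {
        ref <- utils::read.delim(referenceFile, check.names = FALSE)
        conc <- concordanceWithReference(res, ref)
        .write_tsv(conc, file.path(outDir, "concordance.tsv"))
    }
    if (!is.null(plotPairs)) {
        for (pair in plotPairs) {
            ids <- strsplit(pair, ":", fixed = TRUE)[[1L]]
            fit <- fitPair(expr, ids[1L], ids[2L], bandLevel = bandLevel,
                           bandType = bandType)
            renderPairPlot(fit, file.path(outDir,
                                          paste0("pair_", ids[1L], "_",
                                                 ids[2L], ".pdf")))
        }
    }
    .write_manifest(outDir, list(
        pipeline = "pcomp", countsFile = countsFile,
        minSamples = minSamples, minCount = minCount,
        bandLevel = bandLevel, testAlpha = testAlpha,
        allowedShared = allowedShared, bandType = bandType,
        logOffset = logOffset))
    invisible(res)
}

.resolve_annotation <- function(annotation) {
    if (is(annotation, "GRanges")) return(annotation)
    stopifnot(is.character(annotation), file.exists(annotation))
    if (grepl("\\.gtf(\\.gz)?$", annotation, ignore.case = TRUE))
        geneLengthsFromGtf(annotation)
    else
        readGeneTable(annotation)
}

#' Run the fusion meta-caller pipeline
#'
#' For every sample in the manifest: parse each caller's report, apply the
#' per-caller confidence filter, and form the >= \code{minCallers}
#' consensus. Across samples, read-through and recurrence flags are added.
#' When a segment file is supplied the consensus is additionally
#' classified against array breakpoints (TP / FP / unvalidated) and a
#' per-caller TP-rate table is written; comparison with arrays is an
#' optional confirmation step, so without segments only the consensus is
#' produced.
#'
#' @param reportManifest data.frame with columns sample, caller, path --
#'   one parsed report per row.
#' @param annotation gene annotation (path or \code{GRanges}), used for
#'   read-through flagging; NULL skips the flag.
#' @param outDir output directory.
#' @param segmentsFile optional segment TSV for breakpoint validation.
#' @param minCallers consensus threshold (default 2).
#' @param maxGap read-through span-gap ceiling in bp.
#' @param window breakpoint matching half-width in bp.
#' @param minRecurrentSamples distinct-sample count for the recurrence
#'   flag.
#' @return list with \code{consensus} (flagged, and classified when
#'   segments were given) and \code{rates} (or NULL), invisibly.
#' @export
runMetaCaller <- function(reportManifest, annotation = NULL, outDir,
                          segmentsFile = NULL, minCallers = 2L,
                          maxGap = 100000L, window = 100000L,
                          minRecurrentSamples = 2L) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    need <- c("sample", "caller", "path")
    if (!all(need %in% names(reportManifest)))
        stop("report manifest needs columns: ",
             paste(need, collapse = ", "))
    perSample <- lapply(split(reportManifest, reportManifest$sample),
                        function(grp) {
        reports <- lapply(seq_len(nrow(grp)), function(i) {
            rep <- parseCallerReport(grp$path[i], grp$caller[i],
                                     grp$sample[i])
            filt <- filterConfidence(rep)
            message(sprintf("%s/%s: %d calls, %d pass confidence",
                            grp$caller[i], grp$sample[i],
                            nrow(fusionCalls(rep)),
                            nrow(fusionCalls(filt))))
            filt
        })
        consensusFusions(reports, minCallers = minCallers)
    })
    consensus <- do.call(rbind, c(perSample, list(make.row.names = FALSE)))
    if (is.null(consensus) || !nrow(consensus))
        warning("empty consensus: no fusion passed ", minCallers,
                " callers")
    message(sprintf("consensus: %d fusions in %d samples",
                    nrow(consensus),
                    length(unique(consensus$sample_id))))
    if (!is.null(annotation) && nrow(consensus))
        consensus <- flagReadThrough(consensus,
                                     .resolve_annotation(annotation),
                                     maxGap = maxGap)
    consensus <- flagRecurrent(consensus,
                               minSamples = minRecurrentSamples)
    rates <- NULL
    if (!is.null(segmentsFile) && nrow(consensus)) {
        bps <- readBreakpoints(segmentsFile)
        consensus <- classifyFusions(consensus, bps, window = window)
        counted <- cbind(consensus, caller = "meta-caller")
        rates <- tpRateTable(counted)
        .write_tsv(rates, file.path(outDir, "tp_rates.tsv"))
    }
    .write_tsv(consensus, file.path(outDir, "consensus.tsv"))
    .write_manifest(outDir, list(
        pipeline = "metacaller", minCallers = minCallers,
        maxGap = maxGap, window = window,
        minRecurrentSamples = minRecurrentSamples,
        segments = if (is.null(segmentsFile)) "none" else segmentsFile))
    invisible(list(consensus = consensus, rates = rates))
}
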