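#' Read genomic-array segment boundaries as breakpoints
#'
#' Every copy-number or LOH segment contributes two breakpoints, its start
#' and its end. Two dialects are supported: \code{"tsv"}, a header table
#' with columns sample, chrom, start, end, type in 1-based inclusive
#' coordinates; and \code{"bed"}, a headerless BED-like table (chrom,
#' start, end, sample[, type]) in 0-based half-open coordinates, which are
#' converted to 1-based inclusive.
#'
#' @param path segment file.
#' @param dialect \code{"tsv"} or \code{"bed"}.
#' @return data.frame with columns sample_id, chrom, pos, source
#'   (\code{segment_start} / \code{segment_end}), segment_type.
#' @export
readBreakpoints <- function(path, dialect = c("tsv", "bed")) {
    dialect <- match.arg(dialect)
    if (dialect == "tsv") {
        tab <- utils::read.delim(path, header = TRUE, check.names = FALSE)
        miss <- setdiff(c("sample", "chrom", "start", "end", "type"),
                        names(tab))
        if (length(miss))
            stop("segment table is missing column(s): ",
                 paste(miss, collapse = ", "))
    } else {
        tab <- utils::read.delim(path, header = FALSE,
                                 check.names = FALSE)
        if (ncol(tab) < 4L)
            stop("BED dialect needs columns chrom, start, end, sample")
        names(tab)[1:4] <- c("chrom", "start", "end", "sample")
        tab$type <- if (ncol(tab) >= 5L) tab[[5L]] else "other"
        tab$start <- tab$start + 1L   # 0-based half-open -> 1-based inclusive
    }
    if (any(tab$end < tab$start))
        stop("segment with end < start")
    data.frame(
        sample_id = rep(as.character(tab$sample), 2L),
        chrom = rep(as.character(tab$chrom), 2L),
        pos = c(as.integer(tab$start), as.integer(tab$end)),
        source = rep(c("segment_start", "segment_end"), each = nrow(tab)),
        segment_type = rep(as.character(tab$type), 2L),
        stringsAsFactors = FALSE)
}

#' Match one fusion's junctions against array breakpoints
#'
#' A partner side matches when a breakpoint of the same sample lies on the
#' same chromosome within \code{window} bp of the junction position
#' (inclusive). A fusion with at least one matching side is classified TP;
#' otherwise it is left unvalidated here -- the FP label is only assigned
#' downstream from artifact flags or manual labels ([classifyFusions()]).
#'
#' @param fusion single-row data.frame with sample_id, chrom5p, pos5p,
#'   chrom3p, pos3p.
#' @param breakpoints breakpoint table from [readBreakpoints()]; only rows
#'   of the fusion's sample are considered.
#' @param window half-width of the matching window in bp (default 100000).
#' @return list with classification (\code{"TP"} or \code{"unvalidated"}),
#'   matched_side (\code{"5p"}, \code{"3p"}, \code{"both"}, \code{"none"}),
#'   and matched_breakpoint (single-row data.frame or NULL; the nearest
#'   matching breakpoint).
#' @export
matchFusion <- function(fusion, breakpoints, window = 100000L) {
    stopifnot(window >= 0)
    bp <- breakpoints[breakpoints$sample_id == fusion$sample_id, ,
                      drop = FALSE]
    sideMatch <- function(chrom, pos) {
        hit <- bp$chrom == chrom & abs(bp$pos - pos) <= window
        if (!any(hit)) return(NULL)
        cand <- bp[hit, , drop = FALSE]
        cand[which.min(abs(cand$pos - pos)), , drop = FALSE]
    }
    m5 <- sideMatch(fusion$chrom5p, fusion$pos5p)
    m3 <- sideMatch(fusion$chrom3p, fusion$pos3p)
    side <- if (!is.null(m5) && !is.null(m3)) "both"
        else if (!is.null(m5)) "5p"
        else if (!is.null(m3)) "3p"
        else "none"
    list(classification = if (side == "none") "unvalidated" else "TP",
         matched_side = side,
         matched_breakpoint = if (!is.null(m5)) m5 else m3)
}

#' Classify fusions as TP / FP / unvalidated against array breakpoints
#'
#' Applies [matchFusion()] to every fusion (within its own sample's
#' breakpoints) and then resolves the unmatched calls: those flagged as
#' read-through or recurrent -- or carrying a \code{manual_label} of
#' \code{"FP"}, which lets users reproduce hand-curated labels exactly --
#' become FP; the remainder stay unvalidated, since they could still be
#' true fusions from balanced translocations or inversions invisible to
#' the array. A matched fusion is TP regardless of flags.
#'
#' @param fusions data.frame with sample_id, chrom5p, pos5p, chrom3p,
#'   pos3p, and optionally read_through, recurrent, manual_label columns.
#' @param breakpoints table from [readBreakpoints()].
#' @param window matching half-width in bp (default 100000, inclusive).
#' @return \code{fusions} with classification, matched_side, matched_chrom
#'   and matched_pos columns.
#' @export
classifyFusions <- function(fusions, breakpoints, window = 100000L) {
    n <- nrow(fusions)
    cls <- character(n); side <- character(n)
    mch <- rep(NA_character_, n); mpos <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
        m <- matchFusion(fusions[i, ], breakpoints, window = window)
        cls[i] <- m$classification
        side[i] <- m$matched_side
        if (!is.null(m$matched_breakpoint)) {
            mch[i] <- m$matched_breakpoint$chrom
            mpos[i] <- m$matched_breakpoint$pos
        }
    }
    flagged <- rep(FALSE, n)
    if ("read_through" %in% names(fusions))
        flagged <- flagged | fusions$read_through %in% TRUE
    if ("recurrent" %in% names(fusions))
        flagged <- flagged | fusions$recurrent %in% TRUE
    if ("manual_label" %in% names(fusions))
        flagged <- flagged | fusions$manual_label %in% "FP"
    cls[cls == "unvalidated" & flagged] <- "FP"
    fusions$classification <- cls
    fusions$matched_side <- side
    fusions$matched_chrom <- mch
    fusions$matched_pos <- mpos
    fusions
}

#' Per-caller, per-sample true-positive rate table
#'
#' Summarizes fusion counts and TP counts into percentage rates, with a
#' totals row per caller computed from the summed counts (never from
#' averaged rates). Rates are 100 x tp / fusions_overall rounded half-up
#' to 2 decimals; a caller-sample cell with no fusions reports rate 0.
#'
#' Accepts either classified records (columns caller, sample_id,
#' classification -- counts are aggregated) or a pre-aggregated count
#' table (columns caller, sample_id, fusions_overall, tp), so published
#' summary tables can be fed in directly.
#'
#' @param x data.frame in one of the two layouts above.
#' @return data.frame with caller, sample_id (\code{"TOTAL"} for the
#'   totals row), fusions_overall, tp, tp_rate_percent.
#' @export
tpRateTable <- function(x) {
    if (all(c("fusions_overall", "tp") %in% names(x))) {
        agg <- x[c("caller", "sample_id", "fusions_overall", "tp")]
    } else if ("classification" %in% names(x)) {
        agg <- do.call(rbind, lapply(
            split(x, list(x$caller, x$sample_id), drop = TRUE),
            function(grp) data.frame(
                caller = grp$caller[1L], sample_id = grp$sample_id[1L],
                fusions_overall = nrow(grp),
                tp = sum(grp$classification == "TP"),
                stringsAsFactors = FALSE)))
    } else {
        stop("need either fusions_overall/tp counts or a classification column")
    }
    stopifnot(all(agg$tp <= agg$fusions_overall), all(agg$tp >= 0))
    totals <- do.call(rbind, lapply(split(agg, agg$caller), function(grp)
        data.frame(caller = grp$caller[1L], sample_id = "TOTAL",
                   fusions_overall = sum(grp$fusions_overall),
                   tp = sum(grp$tp), stringsAsFactors = FALSE)))
    out <- rbind(agg, totals)
    out$tp_rate_percent <- ifelse(
        out$fusions_overall == 0, 0,
        roundHalfUp(100 * out$tp / out$fusions_overall, 2))
    rownames(out) <- NULL
    out
}

#' Per-caller TP / FP / FN bookkeeping against a truth universe
#'
#' Given each caller's set of array-overlapping fusion keys and the truth
#' universe (the union of fusions labelled true across callers), computes
#' identified = |caller set|, TP = |set  truth|, FP = |set \\ truth|,
#' FN = |truth \\ set|; identified = TP + FP and |truth| = TP + FN hold by
#' construction.
#'
#' @param identifiedSets named list: caller -> character vector of fusion
#'   keys the caller identified in the array overlap.
#' @param truth character vector of fusion keys forming the truth
#'   universe.
#' @return data.frame with caller, identified, tp, fp, fn.
#' @export
callerOverlapTable <- function(identifiedSets, truth) {
    truth <- unique(truth)
    rows <- lapply(names(identifiedSets), function(cl) {
        ids <- unique(identifiedSets[[cl]])
        data.frame(caller = cl, identified = length(ids),
                   tp = length(intersect(ids, truth)),
                   fp = length(setdiff(ids, truth)),
                   fn = length(setdiff(truth, ids)),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
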