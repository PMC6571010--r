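#' Parse a fusion caller's report
#'
#' Reads one caller's output for one sample into the canonical call layout.
#' Supported dialects (header required; minimal column contracts):
#' \describe{
#'   \item{ericscript}{TSV: gene1, gene2, chr1, breakpoint1, chr2,
#'     breakpoint2, spanningreads, EricScore.}
#'   \item{jaffa}{CSV: "fusion genes" (A:B), chrom1, base1, chrom2, base2,
#'     "spanning reads", classification.}
#'   \item{fusioncatcher}{TSV: Gene_1_symbol, Gene_2_symbol,
#'     Fusion_point_for_gene_1 and _2 (chr:pos:strand),
#'     Spanning_unique_reads, Fusion_description.}
#'   \item{canonical}{TSV: sample, caller, gene5p, gene3p, chrom5p, pos5p,
#'     chrom3p, pos3p, spanning_reads, confidence.}
#' }
#' Rows with zero spanning reads or unparsable coordinates are dropped and
#' counted (the only evidence threshold applied at parse time is spanning
#' reads >= 1; lowly expressed fusions are deliberately not pre-filtered).
#'
#' @param path report file.
#' @param caller one of \code{"ericscript"}, \code{"jaffa"},
#'   \code{"fusioncatcher"}, \code{"canonical"}.
#' @param sample sample id the report belongs to.
#' @return A [CallerReport-class] (\code{filtered = FALSE}).
#' @export
parseCallerReport <- function(path,
                              caller = c("ericscript", "jaffa",
                                         "fusioncatcher", "canonical"),
                              sample) {
    caller <- match.arg(caller)
    stopifnot(file.exists(path))
    needCols <- function(tab, need) {
        miss <- setdiff(need, names(tab))
        if (length(miss))
            stop(sprintf("%s report is missing column(s): %s", caller,
                         paste(miss, collapse = ", ")))
    }
    if (caller == "ericscript") {
        tab <- utils::read.delim(path, check.names = FALSE)
        needCols(tab, c("gene1", "gene2", "chr1", "breakpoint1", "chr2",
                        "breakpoint2", "spanningreads", "EricScore"))
        calls <- data.frame(
            gene5p = as.character(tab$gene1), gene3p = as.character(tab$gene2),
            chrom5p = as.character(tab$chr1),
            pos5p = suppressWarnings(as.integer(tab$breakpoint1)),
            chrom3p = as.character(tab$chr2),
            pos3p = suppressWarnings(as.integer(tab$breakpoint2)),
            spanning_reads = suppressWarnings(as.integer(tab$spanningreads)),
            confidence = as.character(tab$EricScore),
            stringsAsFactors = FALSE)
    } else if (caller == "jaffa") {
        tab <- utils::read.csv(path, check.names = FALSE)
        needCols(tab, c("fusion genes", "chrom1", "base1", "chrom2", "base2",
                        "spanning reads", "classification"))
        parts <- strsplit(as.character(tab[["fusion genes"]]), ":", fixed = TRUE)
        if (any(lengths(parts) != 2L))
            stop("jaffa 'fusion genes' entries must be of the form A:B")
        calls <- data.frame(
            gene5p = vapply(parts, `[`, character(1), 1L),
            gene3p = vapply(parts, `[`, character(1), 2L),
            chrom5p = as.character(tab$chrom1),
            pos5p = suppressWarnings(as.integer(tab$base1)),
            chrom3p = as.character(tab$chrom2),
            pos3p = suppressWarnings(as.integer(tab$base2)),
            spanning_reads = suppressWarnings(
                as.integer(tab[["spanning reads"]])),
            confidence = as.character(tab$classification),
            stringsAsFactors = FALSE)
    } else if (caller == "fusioncatcher") {
        tab <- utils::read.delim(path, check.names = FALSE)
        needCols(tab, c("Gene_1_symbol", "Gene_2_symbol",
                        "Fusion_point_for_gene_1", "Fusion_point_for_gene_2",
                        "Spanning_unique_reads", "Fusion_description"))
        splitPoint <- function(v) {
            parts <- strsplit(as.character(v), ":", fixed = TRUE)
            ok <- lengths(parts) >= 2L
            list(chrom = ifelse(ok, vapply(parts, `[`, character(1), 1L),
                                NA_character_),
                 pos = suppressWarnings(as.integer(
                     ifelse(ok, vapply(parts, `[`, character(1), 2L),
                            NA_character_))))
        }
        p1 <- splitPoint(tab$Fusion_point_for_gene_1)
        p2 <- splitPoint(tab$Fusion_point_for_gene_2)
        calls <- data.frame(
            gene5p = as.character(tab$Gene_1_symbol),
            gene3p = as.character(tab$Gene_2_symbol),
            chrom5p = p1$chrom, pos5p = p1$pos,
            chrom3p = p2$chrom, pos3p = p2$pos,
            spanning_reads = suppressWarnings(
                as.integer(tab$Spanning_unique_reads)),
            confidence = as.character(tab$Fusion_description),
            stringsAsFactors = FALSE)
    } else {
        tab <- utils::read.delim(path, check.names = FALSE)
        needCols(tab, c("sample", "caller", "gene5p", "gene3p", "chrom5p",
                        "pos5p", "chrom3p", "pos3p", "spanning_reads",
                        "confidence"))
        tab <- tab[tab$sample == sample, , drop = FALSE]
        calls <- data.frame(
            gene5p = as.character(tab$gene5p),
            gene3p = as.character(tab$gene3p),
            chrom5p = as.character(tab$chrom5p),
            pos5p = suppressWarnings(as.integer(tab$pos5p)),
            chrom3p = as.character(tab$chrom3p),
            pos3p = suppressWarnings(as.integer(tab$pos3p)),
            spanning_reads = suppressWarnings(as.integer(tab$spanning_reads)),
            confidence = as.character(tab$confidence),
            stringsAsFactors = FALSE)
    }
    ok <- !is.na(calls$pos5p) & !is.na(calls$pos3p) &
        !is.na(calls$spanning_reads) & calls$spanning_reads >= 1L &
        calls$pos5p >= 1L & calls$pos3p >= 1L
    nDropped <- sum(!ok)
    if (nDropped)
        message(sprintf("%s/%s: dropped %d row(s) with zero spanning reads or unparsable coordinates",
                        caller, sample, nDropped))
    calls <- calls[ok, , drop = FALSE]
    rownames(calls) <- NULL
    new("CallerReport", caller = caller, sample = sample, calls = calls,
        filtered = FALSE, nDropped = as.integer(nDropped))
}

#' Apply the per-caller confidence filter
#'
#' Reduces a report to the caller's high-confidence subset:
#' EricScript keeps calls with Eric score strictly over \code{ericMin}
#' (default 0.90); JAFFA keeps calls whose classification equals
#' \code{jaffaTag} exactly after whitespace trimming (case-sensitive,
#' default \code{"HighConfidence"}); FusionCatcher keeps calls whose
#' description contains none of the \code{fcBlacklist} artifact tags
#' (matched case-insensitively as fixed substrings). FusionCatcher does
#' not publish a single high-confidence column, so the blacklist predicate
#' is explicit and overridable. Canonical reports keep calls whose
#' confidence token is \code{"pass"} (they are expected to carry an
#' upstream filter decision).
#'
#' @param report an unfiltered [CallerReport-class].
#' @param ericMin strict lower bound on the Eric score.
#' @param jaffaTag the JAFFA classification that passes.
#' @param fcBlacklist artifact tags that disqualify a FusionCatcher call.
#' @return The report with only passing calls and \code{filtered = TRUE}.
#' @export
filterConfidence <- function(report, ericMin = 0.90,
                             jaffaTag = "HighConfidence",
                             fcBlacklist = c("banned", "readthrough",
                                             "read_through", "adjacent",
                                             "conjoing")) {
    stopifnot(is(report, "CallerReport"))
    if (report@filtered)
        stop("report is already confidence-filtered")
    calls <- report@calls
    keep <- switch(report@caller,
        ericscript = {
            score <- suppressWarnings(as.numeric(calls$confidence))
            if (nrow(calls) && anyNA(score))
                stop("ericscript confidence field is not numeric")
            score > ericMin
        },
        jaffa = trimws(calls$confidence) == jaffaTag,
        fusioncatcher = {
            desc <- tolower(calls$confidence)
            !Reduce(`|`, lapply(tolower(fcBlacklist), grepl, x = desc,
                                fixed = TRUE),
                    init = logical(nrow(calls)))
        },
        canonical = tolower(trimws(calls$confidence)) == "pass")
    initialize(report, calls = calls[keep, , drop = FALSE],
               filtered = TRUE)
}

#' Canonical fusion key of a gene-symbol pair
#'
#' Unordered pair of uppercased, whitespace-trimmed symbols joined with
#' \code{"--"} after lexicographic sorting, so that the same fusion is
#' matched across callers regardless of reported orientation. Vectorized.
#'
#' @param gene5p,gene3p character vectors of partner symbols.
#' @return character vector of keys.
#' @examples
#' fusionKey("ZMYM5", "PSPC1") == fusionKey("PSPC1", "ZMYM5")
#' @export
fusionKey <- function(gene5p, gene3p) {
    a <- toupper(trimws(gene5p))
    b <- toupper(trimws(gene3p))
    ifelse(a <= b, paste(a, b, sep = "--"), paste(b, a, sep = "--"))
}

#' Consensus fusion call across callers for one sample
#'
#' Groups confidence-filtered calls by [fusionKey()] and keeps keys
#' supported by at least \code{minCallers} distinct callers. The
#' representative junction coordinates are taken from the supporting call
#' with the most spanning reads (ties broken by caller-name lexical
#' order). Intragenic keys (both partners the same symbol) are kept but
#' flagged.
#'
#' @param reports list of filtered [CallerReport-class] objects for one
#'   sample, one per caller.
#' @param minCallers minimum number of distinct supporting callers.
#' @return data.frame with one row per consensus fusion: fusion_key,
#'   sample_id, gene5p/gene3p and junction coordinates of the
#'   representative call, spanning_reads, supporters (comma-separated),
#'   n_callers, intragenic.
#' @export
consensusFusions <- function(reports, minCallers = 2L) {
    stopifnot(length(reports) >= 1L)
    callers <- vapply(reports, function(r) r@caller, character(1))
    if (anyDuplicated(callers))
        stop("duplicate caller in reports: ",
             paste(unique(callers[duplicated(callers)]), collapse = ", "))
    if (!all(vapply(reports, function(r) r@filtered, logical(1))))
        stop("all reports must be confidence-filtered first")
    samples <- unique(vapply(reports, function(r) r@sample, character(1)))
    if (length(samples) != 1L)
        stop("reports come from mixed samples: ",
             paste(samples, collapse = ", "))
    calls <- do.call(rbind, lapply(reports, function(r) {
        if (!nrow(r@calls)) return(NULL)
        cbind(r@calls, caller = r@caller, stringsAsFactors = FALSE)
    }))
    empty <- data.frame(fusion_key = character(), sample_id = character(),
                        gene5p = character(), gene3p = character(),
                        chrom5p = character(), pos5p = integer(),
                        chrom3p = character(), pos3p = integer(),
                        spanning_reads = integer(), supporters = character(),
                        n_callers = integer(), intragenic = logical())
    if (is.null(calls) || !nrow(calls)) return(empty)
    calls$fusion_key <- fusionKey(calls$gene5p, calls$gene3p)
    rows <- lapply(split(calls, calls$fusion_key), function(grp) {
        supp <- sort(unique(grp$caller))
        if (length(supp) < minCallers) return(NULL)
        grp <- grp[order(-grp$spanning_reads, grp$caller), ]
        rep <- grp[1L, ]
        data.frame(fusion_key = rep$fusion_key, sample_id = samples,
                   gene5p = rep$gene5p, gene3p = rep$gene3p,
                   chrom5p = rep$chrom5p, pos5p = rep$pos5p,
                   chrom3p = rep$chrom3p, pos3p = rep$pos3p,
                   spanning_reads = rep$spanning_reads,
                   supporters = paste(supp, collapse = ","),
                   n_callers = length(supp),
                   intragenic = toupper(trimws(rep$gene5p)) ==
                       toupper(trimws(rep$gene3p)),
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$fusion_key), ]
}

#' Flag read-through candidates among consensus fusions
#'
#' A consensus fusion is a read-through candidate when its partners lie on
#' the same chromosome with a gap between their gene spans (end of the
#' upstream span to start of the downstream span, 0 when the spans
#' overlap) of at most \code{maxGap} bp, inclusive. Such neighboring-gene
#' chimeras are classic transcriptional read-through false positives. The
#' flag never deletes a call; final FP labeling is a reporting category.
#' Fusions with a partner missing from the annotation get NA (logged).
#'
#' @param fusions consensus data.frame from [consensusFusions()] (any
#'   table with gene5p/gene3p columns works).
#' @param ann gene-span \code{GRanges} with a \code{symbol} metadata
#'   column, as from [geneLengthsFromGtf()] or [readGeneTable()].
#' @param maxGap maximum span gap in bp (default 100000, inclusive).
#' @return \code{fusions} with a logical \code{read_through} column.
#' @export
flagReadThrough <- function(fusions, ann, maxGap = 100000L) {
    sym <- toupper(trimws(S4Vectors::mcols(ann)$symbol))
    chrom <- as.character(GenomicRanges::seqnames(ann))
    s <- GenomicRanges::start(ann)
    e <- GenomicRanges::end(ann)
    idx5 <- match(toupper(trimws(fusions$gene5p)), sym)
    idx3 <- match(toupper(trimws(fusions$gene3p)), sym)
    known <- !is.na(idx5) & !is.na(idx3)
    if (any(!known))
        message(sprintf("read-through flag not evaluable for %d fusion(s) with partners missing from the annotation",
                        sum(!known)))
    rt <- rep(NA, nrow(fusions))
    if (any(known)) {
        same <- chrom[idx5[known]] == chrom[idx3[known]]
        gap <- pmax(0L,
                    pmax(s[idx5[known]], s[idx3[known]]) -
                    pmin(e[idx5[known]], e[idx3[known]]))
        rt[known] <- same & gap <= maxGap
    }
    fusions$read_through <- rt
    fusions
}

#' Flag recurrent fusions across samples
#'
#' A fusion key is flagged recurrent when it appears in at least
#' \code{minSamples} distinct samples -- in cohorts where every case
#' carries a private rearrangement pattern, the same fusion recurring
#' across cases is far more likely an artifact than independent identical
#' breakage. A companion column marks fusions one of whose partner genes
#' recurs in \emph{other} keys (with a different partner); these are
#' reported but not auto-labelled false positives, since arrays can miss
#' balanced events.
#'
#' @param fusions data.frame of consensus fusions from all samples, with
#'   fusion_key and sample_id columns.
#' @param minSamples distinct-sample count at which a key is recurrent.
#' @return \code{fusions} with logical \code{recurrent} and
#'   \code{partner_recurrent} columns.
#' @export
flagRecurrent <- function(fusions, minSamples = 2L) {
    if (!nrow(fusions)) {
        fusions$recurrent <- logical(0)
        fusions$partner_recurrent <- logical(0)
        return(fusions)
    }
    perKey <- tapply(fusions$sample_id, fusions$fusion_key,
                     function(s) length(unique(s)))
    fusions$recurrent <- unname(perKey[fusions$fusion_key] >= minSamples)
    keys <- unique(fusions$fusion_key)
    parts <- strsplit(keys, "--", fixed = TRUE)
    geneKeys <- table(unlist(lapply(parts, unique)))
    partnerOf <- function(key) {
        gs <- strsplit(key, "--", fixed = TRUE)[[1L]]
        any(geneKeys[gs] >= 2, na.rm = TRUE)
    }
    fusions$partner_recurrent <- vapply(fusions$fusion_key, partnerOf,
                                        logical(1), USE.NAMES = FALSE)
    fusions
}
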