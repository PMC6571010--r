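#' Read a gene-level count table
#'
#' Reads htseq-count-style output into a [CountMatrix-class]. Two dialects
#' are supported: \code{"merged"}, a single TSV with a header row, a gene-id
#' first column and one numeric column per sample; and \code{"htseq"}, a set
#' of per-sample two-column files (gene id, count) without a header, given
#' as a named vector of paths where the names become the sample ids.
#'
#' htseq-count appends summary rows whose identifiers start with two
#' underscores (\code{__no_feature}, \code{__ambiguous}, ...). These rows
#' are excluded from the gene set and their counts are \emph{not} added to
#' the library sizes: library sizes are the column sums over retained gene
#' rows.
#'
#' @param path file path (merged dialect) or named character vector of
#'   per-sample file paths (htseq dialect).
#' @param dialect \code{"merged"} or \code{"htseq"}.
#' @return A [CountMatrix-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write.table(data.frame(gene_id = c("g1", "g2", "g3"),
#'                        s1 = c(1L, 3L, 5L), s2 = c(2L, 4L, 6L)),
#'             tf, sep = "\t", quote = FALSE, row.names = FALSE)
#' librarySizes(readCounts(tf))   # 9 12
#' @export
readCounts <- function(path, dialect = c("merged", "htseq")) {
    dialect <- match.arg(dialect)
    if (dialect == "merged") {
        stopifnot(length(path) == 1L, file.exists(path))
        tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                                 colClasses = "character")
        if (ncol(tab) < 2L)
            stop("count table needs one gene-id column and >= 1 sample column")
        genes <- tab[[1L]]
        m <- matrix(NA_real_, nrow(tab), ncol(tab) - 1L,
                    dimnames = list(genes, colnames(tab)[-1L]))
        for (j in seq_len(ncol(tab) - 1L)) {
            v <- suppressWarnings(as.numeric(tab[[j + 1L]]))
            if (anyNA(v)) {
                bad <- which(is.na(v))[1L]
                stop(sprintf("malformed numeric cell at row '%s', column '%s'",
                             genes[bad], colnames(tab)[j + 1L]))
            }
            m[, j] <- v
        }
    } else {
        if (is.null(names(path)) || any(!nzchar(names(path))))
            stop("htseq dialect needs a named vector: sample id -> file")
        stopifnot(all(file.exists(path)))
        cols <- lapply(path, function(f) {
            tab <- utils::read.delim(f, header = FALSE,
                                     colClasses = "character")
            v <- suppressWarnings(as.numeric(tab[[2L]]))
            if (anyNA(v)) {
                bad <- which(is.na(v))[1L]
                stop(sprintf("malformed numeric cell at row '%s' in '%s'",
                             tab[[1L]][bad], f))
            }
            setNames(v, tab[[1L]])
        })
        genes <- names(cols[[1L]])
        for (v in cols[-1L])
            if (!identical(names(v), genes))
                stop("per-sample htseq files disagree on gene rows")
        m <- do.call(cbind, cols)
        dimnames(m) <- list(genes, names(path))
    }
    if (anyDuplicated(rownames(m)))
        stop("duplicate gene id: ",
             paste(unique(rownames(m)[duplicated(rownames(m))]),
                   collapse = ", "))
    keep <- !startsWith(rownames(m), "__")
    m <- m[keep, , drop = FALSE]
    CountMatrix(m)
}

#' Filter low-expressed genes
#'
#' Retains genes with a count of at least \code{minCount} in at least
#' \code{minSamples} samples. The defaults implement the cohort rule used
#' in a ten-sample design: at least six samples covered by at least one
#' read. Library sizes are those recorded at load time and are not
#' recomputed.
#'
#' @param cm a [CountMatrix-class].
#' @param minSamples minimum number of samples meeting \code{minCount}.
#' @param minCount minimum per-sample count.
#' @return A filtered [CountMatrix-class] with unchanged library sizes.
#' @export
filterLowExpression <- function(cm, minSamples = 6L, minCount = 1L) {
    stopifnot(is(cm, "CountMatrix"))
    if (minSamples < 1L || minSamples > ncol(cm))
        stop("'minSamples' must lie between 1 and the number of samples")
    keep <- rowSums(counts(cm) >= minCount) >= minSamples
    if (!any(keep))
        warning("no gene passed the low-expression filter")
    cm[keep, ]
}

#' RPKM-normalize a count matrix to log2 scale
#'
#' Computes RPKM(g, s) = counts(g, s) * 1e9 / (length(g) * librarySize(s))
#' and returns log2(RPKM + \code{logOffset}). Library sizes are the totals
#' recorded when the counts were loaded, so normalization is invariant
#' under gene filtering.
#'
#' @param cm a [CountMatrix-class] (typically after [filterLowExpression()]).
#' @param lengths gene lengths in bp: a named numeric vector, or a
#'   \code{GRanges} annotation carrying a \code{length} metadata column and
#'   gene ids as names (as returned by [geneLengthsFromGtf()]).
#' @param logOffset value added to RPKM before taking log2 (default 1, so a
#'   zero count maps to 0).
#' @return An [ExpressionMatrix-class].
#' @export
rpkmNormalize <- function(cm, lengths, logOffset = 1) {
    stopifnot(is(cm, "CountMatrix"))
    if (is(lengths, "GRanges"))
        lengths <- setNames(S4Vectors::mcols(lengths)$length, names(lengths))
    lens <- lengths[rownames(cm)]
    if (anyNA(lens) || is.null(names(lengths))) {
        missing <- rownames(cm)[!rownames(cm) %in% names(lengths)]
        stop("no gene length for: ", paste(missing, collapse = ", "))
    }
    libs <- librarySizes(cm)
    if (any(libs <= 0))
        stop("zero library size for sample: ",
             paste(names(libs)[libs <= 0], collapse = ", "))
    rpkm <- counts(cm) * 1e9 / outer(as.numeric(lens), as.numeric(libs))
    ExpressionMatrix(log2(rpkm + logOffset),
                     normalization = list(method = "RPKM",
                                          logOffset = logOffset))
}

#' Gene lengths and spans from a GTF annotation
#'
#' Computes the union-exon length per gene (overlapping exons merged) and
#' the gene span (min start to max end) used for read-through flagging.
#'
#' @param gtf path to a GTF file with exon features carrying gene_id
#'   attributes.
#' @return A \code{GRanges} of gene spans, named by gene id, with metadata
#'   columns \code{gene_id}, \code{symbol} (the gene_name attribute when
#'   present, else the gene id) and \code{length} (union-exon bp).
#' @examples
#' \dontrun{ann <- geneLengthsFromGtf("genes.gtf"); ann$length}
#' @export
geneLengthsFromGtf <- function(gtf) {
    gr <- rtracklayer::import(gtf, format = "gtf")
    ex <- gr[gr$type == "exon"]
    if (!length(ex))
        stop("GTF contains no exon features")
    if (is.null(ex$gene_id) || anyNA(ex$gene_id))
        stop("exon features must carry gene_id attributes")
    byGene <- GenomicRanges::split(ex, ex$gene_id)
    lens <- sum(IRanges::width(GenomicRanges::reduce(byGene)))
    spans <- unlist(range(byGene))
    sym <- as.character(if (is.null(ex$gene_name)) ex$gene_id else
        ex$gene_name)
    symbol <- vapply(split(sym, as.character(ex$gene_id)), `[`, character(1),
                     1L)
    S4Vectors::mcols(spans) <- S4Vectors::DataFrame(
        gene_id = names(spans),
        symbol = symbol[names(spans)],
        length = as.integer(lens[names(spans)]))
    spans
}

#' Read a simplified gene table as annotation
#'
#' Alternative to GTF input: a TSV with columns gene_id, symbol, chrom,
#' start, end, strand and optionally length. Coordinates are 1-based
#' inclusive. When the length column is absent the span length is used.
#'
#' @param path TSV path with a header row.
#' @return A \code{GRanges} in the same layout as [geneLengthsFromGtf()].
#' @export
readGeneTable <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE)
    need <- c("gene_id", "symbol", "chrom", "start", "end", "strand")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("gene table is missing column(s): ", paste(miss, collapse = ", "))
    if (any(tab$end < tab$start))
        stop("gene table has end < start")
    gr <- GenomicRanges::GRanges(tab$chrom,
                                 IRanges::IRanges(tab$start, tab$end),
                                 strand = tab$strand)
    len <- if ("length" %in% names(tab)) tab$length else
        tab$end - tab$start + 1L
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        gene_id = tab$gene_id, symbol = tab$symbol,
        length = as.integer(len))
    names(gr) <- tab$gene_id
    gr
}
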