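#' @importFrom stats rnorm rlnorm rnbinom rpois runif setNames qt pt sd
NULL

## evaluate expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(if (exists(".Random.seed", envir = globalenv(),
                           inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Simulation settings for the synthetic cohort
#'
#' Describes the cohort the generators emulate: a ten-sample set in which
#' every sample carries private up/down-spiked genes, a handful of true
#' fusions, caller-specific false positives, read-through chimeras of
#' adjacent genes, and array segments whose boundaries sit near the true
#' fusion junctions. All generators are deterministic given \code{seed}
#' (each derives its own substream as seed + a fixed offset).
#'
#' @aliases SimulationSpec-class
#' @exportClass SimulationSpec
setClass("SimulationSpec", slots = c(
    seed = "integer", nGenes = "integer", nSamples = "integer",
    baselineMeanlog = "numeric", baselineSdlog = "numeric",
    dispersion = "numeric", spikesPerSample = "integer",
    spikeEffect = "numeric", fusionsPerSample = "integer",
    fpPerCaller = "integer", readThroughsPerSample = "integer",
    callerSensitivity = "numeric", breakpointJitterSd = "numeric",
    extraBreakpointsPerSample = "integer"))

setValidity("SimulationSpec", function(object) {
    msg <- character()
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "a scalar seed is mandatory")
    if (object@nSamples < 4L) msg <- c(msg, "need at least 4 samples")
    if (object@nGenes < 100L) msg <- c(msg, "need at least 100 genes")
    if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
    if (any(object@callerSensitivity < 0 | object@callerSensitivity > 1))
        msg <- c(msg, "caller sensitivities must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct a SimulationSpec
#'
#' Defaults describe the reference synthetic cohort: 10 samples, 5000
#' genes with a negative-binomial baseline (log-normal gene means), 20
#' private spikes per sample at +/-4 log2 units, 5 true fusions per
#' sample, 30 caller-specific false positives per caller, 3 read-through
#' pairs per sample, per-caller detection probability 0.95, and array
#' breakpoints jittered around true junctions with 25 kb SD (truncated at
#' the 100 kb matching window).
#'
#' @param seed integer seed (mandatory).
#' @param nGenes,nSamples cohort dimensions.
#' @param baselineMeanlog,baselineSdlog log-normal parameters of the
#'   per-gene baseline mean counts.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param spikesPerSample private differentially expressed genes planted
#'   per sample (half up, half down).
#' @param spikeEffect absolute log2 effect of a spike.
#' @param fusionsPerSample true fusions planted per sample.
#' @param fpPerCaller caller-specific false-positive calls per caller and
#'   sample.
#' @param readThroughsPerSample adjacent-gene read-through chimeras
#'   planted per sample.
#' @param callerSensitivity per-caller detection probability for true
#'   fusions (scalar, or named vector over ericscript/jaffa/fusioncatcher).
#' @param breakpointJitterSd SD in bp of the array-breakpoint jitter
#'   around true junctions.
#' @param extraBreakpointsPerSample unrelated array segments per sample.
#' @return A [SimulationSpec-class].
#' @export
simulationSpec <- function(seed, nGenes = 5000L, nSamples = 10L,
                           baselineMeanlog = 4, baselineSdlog = 1.2,
                           dispersion = 0.05, spikesPerSample = 20L,
                           spikeEffect = 4, fusionsPerSample = 5L,
                           fpPerCaller = 30L, readThroughsPerSample = 3L,
                           callerSensitivity = 0.95,
                           breakpointJitterSd = 25000,
                           extraBreakpointsPerSample = 10L) {
    new("SimulationSpec", seed = as.integer(seed),
        nGenes = as.integer(nGenes), nSamples = as.integer(nSamples),
        baselineMeanlog = baselineMeanlog, baselineSdlog = baselineSdlog,
        dispersion = dispersion,
        spikesPerSample = as.integer(spikesPerSample),
        spikeEffect = spikeEffect,
        fusionsPerSample = as.integer(fusionsPerSample),
        fpPerCaller = as.integer(fpPerCaller),
        readThroughsPerSample = as.integer(readThroughsPerSample),
        callerSensitivity = callerSensitivity,
        breakpointJitterSd = breakpointJitterSd,
        extraBreakpointsPerSample = as.integer(extraBreakpointsPerSample))
}

.sim_samples <- function(spec) paste0("T", seq_len(spec@nSamples))

#' Simulate a read-count matrix with private per-sample spikes
#'
#' Counts are drawn per gene and sample from a negative binomial with
#' log-normal gene means and mild library-size variation. Spiked entries
#' have their mean multiplied by 2^effect before drawing; spiked genes are
#' picked among genes with baseline mean >= 50 so that both up and down
#' spikes remain detectable after normalization, and each spiked gene is
#' private to one sample.
#'
#' @param spec a [SimulationSpec-class].
#' @return list with \code{counts} (a [CountMatrix-class]) and
#'   \code{truth} (data.frame gene_id, sample_id, direction, effect).
#' @export
simulateCounts <- function(spec) {
    stopifnot(is(spec, "SimulationSpec"))
    .with_seed(spec@seed + 101L, {
        genes <- sprintf("GENE%05d", seq_len(spec@nGenes))
        samples <- .sim_samples(spec)
        means <- rlnorm(spec@nGenes, spec@baselineMeanlog,
                        spec@baselineSdlog)
        libFactor <- runif(spec@nSamples, 0.8, 1.2)
        mu <- outer(means, libFactor)
        pool <- which(means >= 50)
        nSpike <- spec@spikesPerSample * spec@nSamples
        if (nSpike > length(pool))
            stop("not enough well-expressed genes to plant private spikes")
        spiked <- sample(pool, nSpike)
        truth <- data.frame(
            gene_id = genes[spiked],
            sample_id = rep(samples, each = spec@spikesPerSample),
            direction = rep_len(c("up", "down"), nSpike),
            effect = rep_len(c(1, -1), nSpike) * spec@spikeEffect,
            stringsAsFactors = FALSE)
        if (spec@spikesPerSample == 0L) truth <- truth[0L, ]
        for (k in seq_len(nrow(truth))) {
            i <- spiked[k]; j <- match(truth$sample_id[k], samples)
            mu[i, j] <- mu[i, j] * 2^truth$effect[k]
        }
        m <- matrix(rnbinom(length(mu), size = 1 / spec@dispersion,
                            mu = mu),
                    nrow = spec@nGenes,
                    dimnames = list(genes, samples))
        lens <- setNames(sample(500:10000, spec@nGenes, replace = TRUE),
                         genes)
        list(counts = CountMatrix(m), truth = truth, lengths = lens)
    })
}

#' Simulate a log2 expression matrix directly
#'
#' Gaussian log-expression generator used for calibrating the PComp
#' statistic without the count layer: gene baselines drawn with SD
#' \code{geneMeanSd} around \code{geneMeanCenter} (set \code{geneMeanSd =
#' 0} for an i.i.d. null matrix), i.i.d. noise of SD \code{noiseSd} on
#' top, and optional private per-sample spikes of +/- \code{spikeEffect}
#' log2 units.
#'
#' @param seed integer seed.
#' @param nGenes,nSamples matrix dimensions.
#' @param noiseSd per-entry Gaussian noise SD.
#' @param geneMeanSd SD of per-gene baseline means.
#' @param geneMeanCenter center of per-gene baseline means.
#' @param spikesPerSample private spiked genes per sample.
#' @param spikeEffect absolute log2 effect (alternating up/down).
#' @return list with \code{expr} (an [ExpressionMatrix-class]) and
#'   \code{truth} (data.frame gene_id, sample_id, direction, effect).
#' @export
simulateLogExpression <- function(seed, nGenes = 2000L, nSamples = 10L,
                                  noiseSd = 0.5, geneMeanSd = 2,
                                  geneMeanCenter = 5,
                                  spikesPerSample = 0L, spikeEffect = 4) {
    .with_seed(seed, {
        genes <- sprintf("GENE%05d", seq_len(nGenes))
        samples <- paste0("T", seq_len(nSamples))
        base <- rnorm(nGenes, geneMeanCenter, geneMeanSd)
        m <- base + matrix(rnorm(nGenes * nSamples, 0, noiseSd),
                           nGenes, nSamples)
        dimnames(m) <- list(genes, samples)
        nSpike <- spikesPerSample * nSamples
        truth <- data.frame(gene_id = character(), sample_id = character(),
                            direction = character(), effect = numeric(),
                            stringsAsFactors = FALSE)
        if (nSpike > 0L) {
            spiked <- sample(nGenes, nSpike)
            truth <- data.frame(
                gene_id = genes[spiked],
                sample_id = rep(samples, each = spikesPerSample),
                direction = rep_len(c("up", "down"), nSpike),
                effect = rep_len(c(1, -1), nSpike) * spikeEffect,
                stringsAsFactors = FALSE)
            for (k in seq_len(nSpike))
                m[spiked[k], truth$sample_id[k]] <-
                    m[spiked[k], truth$sample_id[k]] + truth$effect[k]
        }
        list(expr = ExpressionMatrix(
                 m, normalization = list(method = "simulated",
                                         logOffset = NA_real_)),
             truth = truth)
    })
}

#' Simulate a toy genome annotation
#'
#' Builds non-overlapping gene models on a few chromosomes, with a set of
#' deliberately adjacent gene pairs (span gap well under 100 kb) that seed
#' read-through chimeras; all other neighboring genes are spaced ~300 kb
#' apart. Each gene carries 1-4 exons.
#'
#' @param spec a [SimulationSpec-class].
#' @param nGenomeGenes number of genes in the annotation.
#' @param nChroms number of chromosomes.
#' @param nAdjacentPairs adjacent gene pairs planted for read-throughs.
#' @return list with \code{genes} (span \code{GRanges} with gene_id,
#'   symbol, length as in [geneLengthsFromGtf()]), \code{exons} (exon
#'   \code{GRanges} ready for GTF export) and \code{adjacentPairs}
#'   (data.frame gene_a, gene_b).
#' @export
simulateToyGenome <- function(spec, nGenomeGenes = 240L, nChroms = 4L,
                              nAdjacentPairs = 12L) {
    stopifnot(is(spec, "SimulationSpec"), nAdjacentPairs * 2 < nGenomeGenes)
    .with_seed(spec@seed + 202L, {
        perChrom <- ceiling(nGenomeGenes / nChroms)
        ids <- sprintf("FG%04d", seq_len(nGenomeGenes))
        chrom <- paste0("chr", rep(seq_len(nChroms), each = perChrom))[
            seq_len(nGenomeGenes)]
        ## mark gene indices that start an adjacent pair (never spanning a
        ## chromosome boundary, never two pairs sharing a gene)
        adjStart <- integer(0)
        cand <- which(seq_len(nGenomeGenes) %% perChrom != 0L)
        while (length(adjStart) < nAdjacentPairs && length(cand)) {
            pick <- sample(cand, 1L)
            adjStart <- c(adjStart, pick)
            cand <- setdiff(cand, c(pick - 1L, pick, pick + 1L))
        }
        start <- integer(nGenomeGenes)
        width <- sample(5000:40000, nGenomeGenes, replace = TRUE)
        pos <- 1e5L
        for (i in seq_len(nGenomeGenes)) {
            if (i > 1L && chrom[i] != chrom[i - 1L]) pos <- 1e5L
            start[i] <- pos
            gap <- if (i %in% adjStart) sample(2000:40000, 1L) else
                sample(250000:400000, 1L)
            pos <- start[i] + width[i] + gap
        }
        end <- start + width - 1L
        exonList <- lapply(seq_len(nGenomeGenes), function(i) {
            nEx <- sample(1:4, 1L)
            bounds <- sort(sample(seq(start[i], end[i]), 2L * nEx))
            IRanges::IRanges(bounds[seq(1L, 2L * nEx, 2L)],
                             bounds[seq(2L, 2L * nEx, 2L)])
        })
        ## pin exon structure to the full span so span == gene range
        exonList <- lapply(seq_len(nGenomeGenes), function(i) {
            ir <- exonList[[i]]
            IRanges::start(ir)[1L] <- start[i]
            IRanges::end(ir)[length(ir)] <- end[i]
            ir
        })
        nEx <- lengths(exonList)
        exons <- GenomicRanges::GRanges(
            rep(chrom, nEx),
            unlist(IRanges::IRangesList(exonList)),
            strand = rep(sample(c("+", "-"), nGenomeGenes, replace = TRUE),
                         nEx))
        exons$type <- "exon"
        exons$gene_id <- rep(ids, nEx)
        exons$gene_name <- rep(ids, nEx)
        exons$transcript_id <- paste0(rep(ids, nEx), ".t1")
        lens <- vapply(split(exons, exons$gene_id), function(g)
            sum(IRanges::width(GenomicRanges::reduce(g))), integer(1))
        genes <- GenomicRanges::GRanges(chrom,
                                        IRanges::IRanges(start, end))
        S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
            gene_id = ids, symbol = ids, length = as.integer(lens[ids]))
        names(genes) <- ids
        list(genes = genes, exons = exons,
             adjacentPairs = data.frame(gene_a = ids[adjStart],
                                        gene_b = ids[adjStart + 1L],
                                        stringsAsFactors = FALSE))
    })
}

#' Write a toy genome annotation as GTF
#'
#' @param genome result of [simulateToyGenome()].
#' @param path output GTF path.
#' @return \code{path}, invisibly.
#' @export
writeToyGenomeGtf <- function(genome, path) {
    rtracklayer::export(genome$exons, path, format = "gtf")
    invisible(path)
}

.sim_callers <- c("ericscript", "jaffa", "fusioncatcher")

.sensitivity_of <- function(spec, caller) {
    s <- spec@callerSensitivity
    if (length(s) == 1L) return(unname(s))
    if (is.null(names(s)) || !caller %in% names(s))
        stop("callerSensitivity must be scalar or named per caller")
    unname(s[caller])
}

.write_caller_files <- function(calls, dir, sample) {
    paths <- c(
        ericscript = file.path(dir, paste0("eric_", sample, ".tsv")),
        jaffa = file.path(dir, paste0("jaffa_", sample, ".csv")),
        fusioncatcher = file.path(dir, paste0("fc_", sample, ".tsv")))
    er <- calls[calls$caller == "ericscript", ]
    utils::write.table(
        data.frame(gene1 = er$gene5p, gene2 = er$gene3p,
                   chr1 = er$chrom5p, breakpoint1 = er$pos5p,
                   chr2 = er$chrom3p, breakpoint2 = er$pos3p,
                   spanningreads = er$spanning_reads,
                   EricScore = er$confidence),
        paths["ericscript"], sep = "\t", quote = FALSE, row.names = FALSE)
    ja <- calls[calls$caller == "jaffa", ]
    pairLab <- if (nrow(ja)) paste0(ja$gene5p, ":", ja$gene3p) else
        character(0)
    jd <- data.frame(pairLab, ja$chrom5p,
                     ja$pos5p, ja$chrom3p, ja$pos3p, ja$spanning_reads,
                     ja$confidence, check.names = FALSE)
    names(jd) <- c("fusion genes", "chrom1", "base1", "chrom2", "base2",
                   "spanning reads", "classification")
    utils::write.csv(jd, paths["jaffa"], quote = FALSE, row.names = FALSE)
    fc <- calls[calls$caller == "fusioncatcher", ]
    fcPoint <- function(chrom, pos) {
        if (!nrow(fc)) return(character(0))
        paste0(chrom, ":", pos, ":+")
    }
    utils::write.table(
        data.frame(Gene_1_symbol = fc$gene5p, Gene_2_symbol = fc$gene3p,
                   Fusion_point_for_gene_1 = fcPoint(fc$chrom5p, fc$pos5p),
                   Fusion_point_for_gene_2 = fcPoint(fc$chrom3p, fc$pos3p),
                   Spanning_unique_reads = fc$spanning_reads,
                   Fusion_description = fc$confidence),
        paths["fusioncatcher"], sep = "\t", quote = FALSE,
        row.names = FALSE)
    paths
}

.passing_confidence <- function(caller, n) {
    switch(caller,
           ericscript = sprintf("%.4f", runif(n, 0.905, 0.999)),
           jaffa = rep("HighConfidence", n),
           fusioncatcher = rep("known,exon-exon", n))
}

.failing_confidence <- function(caller, n) {
    switch(caller,
           ericscript = sprintf("%.4f", runif(n, 0.1, 0.9)),
           jaffa = rep("LowConfidence", n),
           fusioncatcher = rep("banned,readthrough", n))
}

#' Simulate per-caller fusion reports with planted truths
#'
#' For every sample: true fusions between distant genes (each caller
#' detects each truth independently with its sensitivity and reports it
#' with a passing confidence value), caller-specific false positives (half
#' with passing and half with failing confidence, so the filters are
#' exercised in both directions), and read-through chimeras of adjacent
#' gene pairs written by two callers with passing confidence so they
#' survive to the consensus where the gap flag must catch them. The first
#' adjacent pair is replanted in the first two samples to exercise the
#' recurrence flag. Spanning reads are >= 1 throughout.
#'
#' @param spec a [SimulationSpec-class].
#' @param genome result of [simulateToyGenome()].
#' @param dir output directory for the vendor-dialect report files.
#' @return list with \code{files} (data.frame sample, caller, path) and
#'   \code{truth} (list with data.frames \code{fusions} and
#'   \code{readThroughs}).
#' @export
simulateCallerReports <- function(spec, genome, dir) {
    stopifnot(is(spec, "SimulationSpec"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    genes <- genome$genes
    adjacentGenes <- unique(unlist(genome$adjacentPairs))
    distant <- setdiff(names(genes), adjacentGenes)
    chromOf <- setNames(as.character(GenomicRanges::seqnames(genes)),
                        names(genes))
    posIn <- function(g) {
        sample(seq(GenomicRanges::start(genes[g]),
                   GenomicRanges::end(genes[g])), 1L)
    }
    .with_seed(spec@seed + 303L, {
        samples <- .sim_samples(spec)
        truthRows <- list(); rtRows <- list(); fileRows <- list()
        for (s in samples) {
            ## plant truths: partner genes on different chromosomes
            truths <- NULL
            if (spec@fusionsPerSample > 0L) {
                g5 <- sample(distant, spec@fusionsPerSample)
                g3 <- vapply(g5, function(a)
                    sample(distant[chromOf[distant] != chromOf[a]], 1L),
                    character(1))
                truths <- data.frame(
                    sample_id = s, gene5p = g5, gene3p = g3,
                    chrom5p = chromOf[g5],
                    pos5p = vapply(g5, posIn, numeric(1)),
                    chrom3p = chromOf[g3],
                    pos3p = vapply(g3, posIn, numeric(1)),
                    fusion_key = fusionKey(g5, g3),
                    stringsAsFactors = FALSE)
                truthRows[[s]] <- truths
            }
            ## read-through plan: first adjacent pair recurs in samples 1-2
            nRT <- spec@readThroughsPerSample
            rt <- NULL
            if (nRT > 0L) {
                idx <- if (s %in% samples[1:2])
                    c(1L, sample(2:nrow(genome$adjacentPairs), nRT - 1L))
                else sample(2:nrow(genome$adjacentPairs), nRT)
                rt <- genome$adjacentPairs[idx, ]
                rtRows[[s]] <- data.frame(
                    sample_id = s,
                    fusion_key = fusionKey(rt$gene_a, rt$gene_b),
                    stringsAsFactors = FALSE)
            }
            calls <- list()
            for (cl in .sim_callers) {
                sens <- .sensitivity_of(spec, cl)
                det <- if (is.null(truths)) logical(0) else
                    runif(nrow(truths)) < sens
                if (any(det)) {
                    tr <- truths[det, ]
                    calls[[length(calls) + 1L]] <- data.frame(
                        caller = cl, gene5p = tr$gene5p, gene3p = tr$gene3p,
                        chrom5p = tr$chrom5p, pos5p = tr$pos5p,
                        chrom3p = tr$chrom3p, pos3p = tr$pos3p,
                        spanning_reads = rpois(nrow(tr), 20) + 1L,
                        confidence = .passing_confidence(cl, nrow(tr)),
                        stringsAsFactors = FALSE)
                }
                if (spec@fpPerCaller > 0L) {
                    f5 <- sample(distant, spec@fpPerCaller, replace = TRUE)
                    f3 <- vapply(f5, function(a)
                        sample(setdiff(distant, a), 1L), character(1))
                    nPass <- ceiling(spec@fpPerCaller / 2)
                    conf <- c(.passing_confidence(cl, nPass),
                              .failing_confidence(cl,
                                                  spec@fpPerCaller - nPass))
                    calls[[length(calls) + 1L]] <- data.frame(
                        caller = cl, gene5p = f5, gene3p = f3,
                        chrom5p = chromOf[f5],
                        pos5p = vapply(f5, posIn, numeric(1)),
                        chrom3p = chromOf[f3],
                        pos3p = vapply(f3, posIn, numeric(1)),
                        spanning_reads = rpois(spec@fpPerCaller, 3) + 1L,
                        confidence = conf, stringsAsFactors = FALSE)
                }
                if (!is.null(rt) && cl %in% c("jaffa", "fusioncatcher")) {
                    calls[[length(calls) + 1L]] <- data.frame(
                        caller = cl, gene5p = rt$gene_a, gene3p = rt$gene_b,
                        chrom5p = chromOf[rt$gene_a],
                        pos5p = GenomicRanges::end(genes[rt$gene_a]),
                        chrom3p = chromOf[rt$gene_b],
                        pos3p = GenomicRanges::start(genes[rt$gene_b]),
                        spanning_reads = rpois(nrow(rt), 10) + 1L,
                        confidence = .passing_confidence(cl, nrow(rt)),
                        stringsAsFactors = FALSE)
                }
            }
            calls <- do.call(rbind, calls)
            paths <- .write_caller_files(calls, dir, s)
            fileRows[[s]] <- data.frame(sample = s, caller = .sim_callers,
                                        path = unname(paths),
                                        stringsAsFactors = FALSE)
        }
        list(files = do.call(rbind, c(fileRows, list(make.row.names = FALSE))),
             truth = list(
                 fusions = do.call(rbind, c(truthRows,
                                            list(make.row.names = FALSE))),
                 readThroughs = do.call(rbind,
                                        c(rtRows,
                                          list(make.row.names = FALSE)))))
    })
}

#' Simulate array segments consistent with planted fusions
#'
#' For every true fusion, one partner junction (the 5' one) receives a
#' segment boundary jittered by a truncated Gaussian (SD
#' \code{breakpointJitterSd}, truncated at +/- \code{window} so a planted
#' truth always validates); unrelated segments are added per sample.
#'
#' @param spec a [SimulationSpec-class].
#' @param fusionTruth data.frame of planted fusions (from
#'   [simulateCallerReports()]'s truth).
#' @param path output TSV path (columns sample, chrom, start, end, type).
#' @param window truncation bound of the jitter in bp.
#' @return The segment table, invisibly; the file is written to
#'   \code{path}.
#' @export
simulateBreakpoints <- function(spec, fusionTruth, path,
                                window = 100000L) {
    stopifnot(is(spec, "SimulationSpec"))
    .with_seed(spec@seed + 404L, {
        segs <- list()
        if (!is.null(fusionTruth) && nrow(fusionTruth)) {
            jit <- pmin(window, pmax(-window,
                round(rnorm(nrow(fusionTruth), 0,
                            spec@breakpointJitterSd))))
            bp <- pmax(1L, fusionTruth$pos5p + jit)
            segs[[1L]] <- data.frame(
                sample = fusionTruth$sample_id,
                chrom = fusionTruth$chrom5p,
                start = bp,
                end = bp + sample(200000:2000000, nrow(fusionTruth),
                                  replace = TRUE),
                type = sample(c("CNV_loss", "CNV_gain", "LOH"),
                              nrow(fusionTruth), replace = TRUE),
                stringsAsFactors = FALSE)
        }
        ## unrelated segments sit beyond the simulated gene territory so
        ## the planted truth labels stay exact
        nExtra <- spec@extraBreakpointsPerSample
        if (nExtra > 0L) {
            samples <- .sim_samples(spec)
            segs[[length(segs) + 1L]] <- data.frame(
                sample = rep(samples, each = nExtra),
                chrom = sample(paste0("chr", 1:4),
                               nExtra * length(samples), replace = TRUE),
                start = st <- sample(2e8:3e8, nExtra * length(samples),
                                     replace = TRUE),
                end = st + sample(200000:2000000, nExtra * length(samples),
                                  replace = TRUE),
                type = "CNV_loss", stringsAsFactors = FALSE)
        }
        segs <- do.call(rbind, segs)
        utils::write.table(segs, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        invisible(segs)
    })
}

#' Generate the complete synthetic data set
#'
#' Writes everything the two pipelines consume into \code{dir}:
#' counts.tsv, genes.gtf, per-sample caller reports (eric_*.tsv,
#' jaffa_*.csv, fc_*.tsv), segments.tsv, and the truth tables under
#' truth/.
#'
#' @param spec a [SimulationSpec-class].
#' @param dir output directory (created if needed).
#' @return list with the generated objects and file paths, invisibly.
#' @export
simulateAll <- function(spec, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    sim <- simulateCounts(spec)
    countsPath <- file.path(dir, "counts.tsv")
    utils::write.table(
        data.frame(gene_id = rownames(counts(sim$counts)),
                   counts(sim$counts), check.names = FALSE),
        countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
    ## expression genes live on their own tiled pseudo-chromosome; only
    ## their lengths matter for normalization
    lens <- sim$lengths
    starts <- cumsum(c(1, utils::head(lens, -1) + 10000))
    geneTablePath <- file.path(dir, "gene_table.tsv")
    utils::write.table(
        data.frame(gene_id = names(lens), symbol = names(lens),
                   chrom = "chrE", start = starts,
                   end = starts + lens - 1L, strand = "+",
                   length = lens),
        geneTablePath, sep = "\t", quote = FALSE, row.names = FALSE)
    genome <- simulateToyGenome(spec)
    gtfPath <- writeToyGenomeGtf(genome, file.path(dir, "genes.gtf"))
    reports <- simulateCallerReports(spec, genome, dir)
    segPath <- file.path(dir, "segments.tsv")
    segments <- simulateBreakpoints(spec, reports$truth$fusions, segPath)
    truthDir <- file.path(dir, "truth")
    if (!dir.exists(truthDir)) dir.create(truthDir)
    utils::write.table(sim$truth, file.path(truthDir, "de_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(reports$truth$fusions))
        utils::write.table(reports$truth$fusions,
                           file.path(truthDir, "fusion_truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(reports$truth$readThroughs))
        utils::write.table(reports$truth$readThroughs,
                           file.path(truthDir, "readthrough_truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(list(counts = sim$counts, deTruth = sim$truth,
                   genome = genome, reports = reports,
                   segments = segments,
                   paths = list(counts = countsPath, gtf = gtfPath,
                                geneTable = geneTablePath,
                                segments = segPath, dir = dir)))
}
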