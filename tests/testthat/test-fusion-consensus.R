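eric_df <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
        data.frame(gene1 = r[[1]], gene2 = r[[2]], chr1 = "chr1",
                   breakpoint1 = 1000L, chr2 = "chr2", breakpoint2 = 2000L,
                   spanningreads = as.integer(r[[3]]), EricScore = r[[4]])))
}

test_that("parseCallerReport reads all four dialects", {
    ## ericscript
    ePath <- write_tsv_tmp(eric_df(list("A", "B", 5, 0.95),
                                   list("C", "D", 2, 0.5)))
    er <- parseCallerReport(ePath, "ericscript", "T1")
    expect_equal(nrow(fusionCalls(er)), 2L)
    expect_false(er@filtered)

    ## jaffa (comma-separated, spaces in headers)
    jd <- data.frame(a = c("A:B", "E:F"), chrom1 = "chr1", base1 = 100L,
                     chrom2 = "chr3", base2 = 300L, sr = c(4L, 6L),
                     cls = c("HighConfidence", "LowConfidence"))
    names(jd) <- c("fusion genes", "chrom1", "base1", "chrom2", "base2",
                   "spanning reads", "classification")
    jPath <- tempfile(fileext = ".csv")
    write.csv(jd, jPath, quote = FALSE, row.names = FALSE)
    ja <- parseCallerReport(jPath, "jaffa", "T1")
    expect_equal(fusionCalls(ja)$gene5p, c("A", "E"))
    expect_equal(fusionCalls(ja)$pos3p, c(300L, 300L))

    ## fusioncatcher chr:pos:strand coordinates
    fd <- data.frame(Gene_1_symbol = "G1", Gene_2_symbol = "G2",
                     Fusion_point_for_gene_1 = "chr5:1234:+",
                     Fusion_point_for_gene_2 = "chr9:987:-",
                     Spanning_unique_reads = 3L,
                     Fusion_description = "known")
    fc <- parseCallerReport(write_tsv_tmp(fd), "fusioncatcher", "T1")
    expect_equal(fusionCalls(fc)$chrom5p, "chr5")
    expect_equal(fusionCalls(fc)$pos3p, 987L)

    ## canonical, filtered to the requested sample
    cd <- data.frame(sample = c("T1", "T2"), caller = "ericscript",
                     gene5p = c("A", "B"), gene3p = c("X", "Y"),
                     chrom5p = "chr1", pos5p = 10L, chrom3p = "chr2",
                     pos3p = 20L, spanning_reads = 2L, confidence = "pass")
    cn <- parseCallerReport(write_tsv_tmp(cd), "canonical", "T1")
    expect_equal(fusionCalls(cn)$gene5p, "A")
})

test_that("parseCallerReport drops zero-spanning-read rows and checks columns", {
    path <- write_tsv_tmp(eric_df(list("A", "B", 0, 0.95),
                                  list("C", "D", 3, 0.99)))
    expect_message(rep <- parseCallerReport(path, "ericscript", "T1"),
                   "dropped 1")
    expect_equal(nrow(fusionCalls(rep)), 1L)
    expect_equal(rep@nDropped, 1L)

    noCol <- write_tsv_tmp(data.frame(gene1 = "A", gene2 = "B"))
    expect_error(parseCallerReport(noCol, "ericscript", "T1"),
                 "missing column")
})

test_that("filterConfidence applies each caller's rule with strict boundaries", {
    ePath <- write_tsv_tmp(eric_df(list("A", "B", 5, 0.95),
                                   list("C", "D", 5, 0.90),
                                   list("E", "F", 5, 0.905)))
    er <- filterConfidence(parseCallerReport(ePath, "ericscript", "T1"))
    expect_true(er@filtered)
    ## 0.90 is removed (strict >), 0.905 and 0.95 kept
    expect_setequal(fusionCalls(er)$gene5p, c("A", "E"))
    expect_error(filterConfidence(er), "already")

    jd <- data.frame(a = c("A:B", "C:D", "E:F"), chrom1 = "chr1",
                     base1 = 1L, chrom2 = "chr2", base2 = 2L, sr = 3L,
                     cls = c("HighConfidence", "LowConfidence",
                             " HighConfidence "))
    names(jd) <- c("fusion genes", "chrom1", "base1", "chrom2", "base2",
                   "spanning reads", "classification")
    jPath <- tempfile(fileext = ".csv")
    write.csv(jd, jPath, quote = TRUE, row.names = FALSE)
    ja <- filterConfidence(parseCallerReport(jPath, "jaffa", "T1"))
    expect_setequal(fusionCalls(ja)$gene5p, c("A", "E"))  # trimmed, exact

    fd <- data.frame(Gene_1_symbol = c("G1", "G3", "G5"),
                     Gene_2_symbol = c("G2", "G4", "G6"),
                     Fusion_point_for_gene_1 = "chr5:10:+",
                     Fusion_point_for_gene_2 = "chr9:20:-",
                     Spanning_unique_reads = 3L,
                     Fusion_description = c("known,exon-exon",
                                            "banned,healthy",
                                            "readthrough"))
    fc <- filterConfidence(parseCallerReport(write_tsv_tmp(fd),
                                             "fusioncatcher", "T1"))
    expect_equal(fusionCalls(fc)$gene5p, "G1")
})

test_that("fusionKey is unordered, normalized, idempotent and flags intragenic pairs", {
    expect_equal(fusionKey("ZMYM5", "PSPC1"), fusionKey("PSPC1", "ZMYM5"))
    expect_equal(fusionKey("abc ", "XYZ"), "ABC--XYZ")
    expect_equal(fusionKey("TP53", "TP53"), "TP53--TP53")
    ## idempotent on already-normalized symbols
    k <- fusionKey("aaa", "bbb")
    parts <- strsplit(k, "--", fixed = TRUE)[[1]]
    expect_equal(fusionKey(parts[1], parts[2]), k)
    ## symmetry over random symbol pairs
    set.seed(1)
    for (i in 1:25) {
        a <- paste0(sample(LETTERS, 4), collapse = "")
        b <- paste0(sample(LETTERS, 4), collapse = "")
        expect_equal(fusionKey(a, b), fusionKey(b, a))
    }
    intra <- report_from_keys("ericscript", "T1", "TP53--TP53")
    cons <- consensusFusions(list(intra,
                                  report_from_keys("jaffa", "T1",
                                                   "TP53--TP53")))
    expect_true(cons$intragenic)
})

test_that("consensusFusions keeps >= 2-caller fusions and picks the best-supported junction", {
    er <- report_from_keys("ericscript", "T1", c("A--B", "C--D"),
                           spanning = c(5L, 2L))
    fc <- report_from_keys("fusioncatcher", "T1", c("A--B", "E--F"),
                           spanning = c(9L, 3L))
    ja <- report_from_keys("jaffa", "T1", "A--B", spanning = 1L)
    cons <- consensusFusions(list(er, fc, ja))
    expect_equal(cons$fusion_key, "A--B")   # C--D and E--F are single-caller
    expect_equal(cons$n_callers, 3L)
    expect_equal(cons$supporters, "ericscript,fusioncatcher,jaffa")
    expect_equal(cons$spanning_reads, 9L)   # fusioncatcher had most reads
    cons3 <- consensusFusions(list(er, fc, ja), minCallers = 3L)
    expect_equal(cons3$fusion_key, "A--B")
    ## errors: duplicate caller, unfiltered report, mixed samples
    expect_error(consensusFusions(list(er, er)), "duplicate caller")
    raw <- er; raw@filtered <- FALSE
    expect_error(consensusFusions(list(raw, fc)), "filtered")
    other <- report_from_keys("jaffa", "T2", "A--B")
    expect_error(consensusFusions(list(er, other)), "mixed samples")
})

test_that("consensus voting equals exhaustive enumeration on random instances", {
    set.seed(99)
    universe <- apply(expand.grid(LETTERS[1:6], LETTERS[7:12]), 1,
                      function(r) fusionKey(r[1], r[2]))
    for (i in 1:200) {
        sets <- lapply(c("ericscript", "jaffa", "fusioncatcher"),
                       function(cl) sample(universe, rpois(1, 4)))
        names(sets) <- c("ericscript", "jaffa", "fusioncatcher")
        minC <- sample(1:3, 1)
        reports <- lapply(names(sets), function(cl)
            report_from_keys(cl, "T1", sets[[cl]]))
        got <- consensusFusions(reports, minCallers = minC)$fusion_key
        expect_equal(got, oracle_consensus_keys(sets, minC))
    }
})

test_that("consensus is monotone in calls and in the caller threshold", {
    er <- report_from_keys("ericscript", "T1", c("A--B", "C--D"))
    ja <- report_from_keys("jaffa", "T1", c("A--B"))
    fc <- report_from_keys("fusioncatcher", "T1", character())
    base <- consensusFusions(list(er, ja, fc))$fusion_key
    ## adding a call never removes a consensus fusion
    fc2 <- report_from_keys("fusioncatcher", "T1", "C--D")
    more <- consensusFusions(list(er, ja, fc2))$fusion_key
    expect_true(all(base %in% more))
    ## raising min_callers never adds one
    stricter <- consensusFusions(list(er, ja, fc2), minCallers = 3L)$fusion_key
    expect_true(all(stricter %in% more))
})

test_that("per-sample consensus equals joint processing then splitting", {
    keysBySample <- list(T1 = c("A--B", "C--D"), T2 = c("A--B"))
    perSample <- lapply(names(keysBySample), function(s)
        consensusFusions(list(
            report_from_keys("ericscript", s, keysBySample[[s]]),
            report_from_keys("jaffa", s, keysBySample[[s]]))))
    joint <- do.call(rbind, perSample)
    for (s in names(keysBySample)) {
        expect_equal(sort(joint$fusion_key[joint$sample_id == s]),
                     sort(keysBySample[[s]]))
    }
})

test_that("flagReadThrough uses the inclusive span gap on one chromosome", {
    ann <- GenomicRanges::GRanges(
        c("chr1", "chr1", "chr2", "chr1"),
        IRanges::IRanges(c(1000, 7000, 7000, 210000),
                         c(5000, 12000, 12000, 220000)))
    S4Vectors::mcols(ann) <- S4Vectors::DataFrame(
        gene_id = c("gA", "gB", "gC", "gD"),
        symbol = c("GA", "GB", "GC", "GD"),
        length = 100L)
    names(ann) <- ann$gene_id
    fus <- data.frame(gene5p = c("GA", "GA", "GA", "GA"),
                      gene3p = c("GB", "GC", "GD", "GX"),
                      stringsAsFactors = FALSE)
    expect_message(out <- flagReadThrough(fus, ann, maxGap = 100000L),
                   "missing")
    expect_equal(out$read_through, c(TRUE, FALSE, FALSE, NA))
    ## gap exactly maxGap is inclusive: spans [1k,5k] and [105001+5000]
    ann2 <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(c(1000, 105000),
                                                    c(5000, 110000)))
    S4Vectors::mcols(ann2) <- S4Vectors::DataFrame(
        gene_id = c("gA", "gB"), symbol = c("GA", "GB"), length = 10L)
    fus2 <- data.frame(gene5p = "GA", gene3p = "GB")
    expect_true(flagReadThrough(fus2, ann2, maxGap = 100000L)$read_through)
    expect_false(flagReadThrough(fus2, ann2, maxGap = 99999L)$read_through)
    ## overlapping spans have gap 0
    ann3 <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(c(1000, 3000),
                                                    c(5000, 8000)))
    S4Vectors::mcols(ann3) <- S4Vectors::mcols(ann2)
    expect_true(flagReadThrough(fus2, ann3, maxGap = 0L)$read_through)
})

test_that("flagRecurrent marks multi-sample keys and partner recurrence", {
    fus <- data.frame(
        fusion_key = c(rep("PSPC1--ZMYM5", 6), "AA--BB", "AA--CC"),
        sample_id = c(paste0("T", 1:6), "T1", "T2"),
        stringsAsFactors = FALSE)
    out <- flagRecurrent(fus)
    expect_true(all(out$recurrent[1:6]))        # six instances
    expect_false(any(out$recurrent[7:8]))        # single-sample keys
    ## AA appears in two different keys -> partner recurrence, not FP
    expect_true(all(out$partner_recurrent[7:8]))
    expect_false(any(out$partner_recurrent[1:6]))
})
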