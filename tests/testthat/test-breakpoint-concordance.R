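seg_df <- function(sample, chrom, start, end, type = "CNV_loss") {
    data.frame(sample = sample, chrom = chrom, start = start, end = end,
               type = type, stringsAsFactors = FALSE)
}

test_that("readBreakpoints yields two breakpoints per segment and converts BED", {
    bp <- readBreakpoints(write_tsv_tmp(seg_df("T1", "chr1", 1000000L,
                                               2000000L)))
    expect_equal(sort(bp$pos), c(1000000L, 2000000L))
    expect_setequal(bp$source, c("segment_start", "segment_end"))

    ## BED dialect: 0-based half-open start 999999 -> 1-based 1000000
    bedPath <- tempfile(fileext = ".bed")
    write.table(data.frame("chr1", 999999L, 2000000L, "T1", "LOH"),
                bedPath, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    bed <- readBreakpoints(bedPath, dialect = "bed")
    expect_equal(sort(bed$pos), c(1000000L, 2000000L))
    expect_equal(unique(bed$segment_type), "LOH")

    ## mixed samples partition correctly; bad segments error
    two <- rbind(seg_df("T1", "chr1", 10L, 20L), seg_df("T2", "chr2", 5L, 9L))
    bps <- readBreakpoints(write_tsv_tmp(two))
    expect_equal(sort(unique(bps$sample_id)), c("T1", "T2"))
    expect_error(readBreakpoints(write_tsv_tmp(seg_df("T1", "chr1", 10L, 5L))),
                 "end < start")
})

test_that("matchFusion applies the inclusive +/- window on the same chromosome", {
    bps <- readBreakpoints(write_tsv_tmp(seg_df("T1", "chr1", 1000000L,
                                                5000000L)))
    fus <- function(pos5, chrom5 = "chr1")
        data.frame(sample_id = "T1", chrom5p = chrom5, pos5p = pos5,
                   chrom3p = "chr9", pos3p = 42L)
    ## exactly 100 kb away matches (inclusive), one bp further does not
    expect_equal(matchFusion(fus(1100000L), bps)$classification, "TP")
    expect_equal(matchFusion(fus(1100001L), bps)$classification,
                 "unvalidated")
    ## same position on a different chromosome never matches
    expect_equal(matchFusion(fus(1000000L, "chr2"), bps)$classification,
                 "unvalidated")
    ## window 0 requires exact equality
    expect_equal(matchFusion(fus(1000000L), bps, window = 0L)$classification,
                 "TP")
    expect_equal(matchFusion(fus(1000001L), bps, window = 0L)$classification,
                 "unvalidated")
    ## matched side bookkeeping
    both <- data.frame(sample_id = "T1", chrom5p = "chr1", pos5p = 1000000L,
                       chrom3p = "chr1", pos3p = 5000000L)
    expect_equal(matchFusion(both, bps)$matched_side, "both")
})

test_that("window matching equals the exhaustive pairwise check on random instances", {
    set.seed(123)
    for (i in 1:200) {
        nB <- sample(1:8, 1)
        segs <- seg_df("T1", sample(paste0("chr", 1:3), nB, replace = TRUE),
                       start = sample(1:5000, nB),
                       end = sample(5001:10000, nB))
        bps <- readBreakpoints(write_tsv_tmp(segs))
        window <- sample(c(0L, 10L, 500L, 2000L), 1)
        f <- data.frame(sample_id = "T1",
                        chrom5p = sample(paste0("chr", 1:3), 1),
                        pos5p = sample(1:10000, 1),
                        chrom3p = sample(paste0("chr", 1:3), 1),
                        pos3p = sample(1:10000, 1))
        got <- matchFusion(f, bps, window = window)$classification == "TP"
        want <- oracle_window_match(f$chrom5p, f$pos5p, bps, window) ||
            oracle_window_match(f$chrom3p, f$pos3p, bps, window)
        expect_equal(got, want)
    }
})

test_that("matching is monotone in the window and per-sample independent", {
    segs <- rbind(seg_df("T1", "chr1", 1000L, 2000L),
                  seg_df("T2", "chr1", 500000L, 600000L))
    bps <- readBreakpoints(write_tsv_tmp(segs))
    f <- data.frame(sample_id = "T1", chrom5p = "chr1", pos5p = 9000L,
                    chrom3p = "chr9", pos3p = 1L)
    cls <- vapply(c(0L, 5000L, 7000L, 100000L), function(w)
        matchFusion(f, bps, window = w)$classification, character(1))
    expect_equal(cls, c("unvalidated", "unvalidated", "TP", "TP"))
    ## T2's breakpoints must never validate a T1 fusion
    fT1 <- data.frame(sample_id = "T1", chrom5p = "chr1", pos5p = 500000L,
                      chrom3p = "chr9", pos3p = 1L)
    expect_equal(matchFusion(fT1, bps)$classification, "unvalidated")
})

test_that("classifyFusions assigns FP only to unmatched flagged fusions", {
    bps <- readBreakpoints(write_tsv_tmp(seg_df("T1", "chr1", 1000000L,
                                                2000000L)))
    fus <- data.frame(
        sample_id = "T1",
        chrom5p = c("chr1", "chr5", "chr5", "chr5"),
        pos5p = c(1050000L, 1L, 1L, 1L),
        chrom3p = "chr9", pos3p = 42L,
        read_through = c(TRUE, TRUE, FALSE, FALSE),
        recurrent = c(FALSE, FALSE, TRUE, FALSE))
    out <- classifyFusions(fus, bps)
    ## matched fusion is TP regardless of flags
    expect_equal(out$classification,
                 c("TP", "FP", "FP", "unvalidated"))
    ## manual labels reproduce hand curation
    fus$manual_label <- c(NA, NA, NA, "FP")
    out2 <- classifyFusions(fus, bps)
    expect_equal(out2$classification[4], "FP")
})

test_that("tpRateTable reproduces rates from counts with half-up rounding", {
    counts <- data.frame(
        caller = "meta-caller", sample_id = c("T1", "T2"),
        fusions_overall = c(30L, 10L), tp = c(14L, 5L))
    out <- tpRateTable(counts)
    tot <- out[out$sample_id == "TOTAL", ]
    expect_equal(tot$fusions_overall, 40L)
    expect_equal(tot$tp, 19L)
    expect_equal(tot$tp_rate_percent, 47.50)
    expect_equal(out$tp_rate_percent[out$sample_id == "T1"], 46.67)
    ## single-call edge and zero-fusion convention
    one <- tpRateTable(data.frame(caller = "x", sample_id = "T1",
                                  fusions_overall = 1L, tp = 1L))
    expect_equal(one$tp_rate_percent, c(100, 100))
    zero <- tpRateTable(data.frame(caller = "x", sample_id = "T1",
                                   fusions_overall = 0L, tp = 0L))
    expect_equal(zero$tp_rate_percent, c(0, 0))
})

test_that("tpRateTable aggregates classified records and totals use summed counts", {
    rec <- data.frame(
        caller = rep(c("a", "b"), each = 4),
        sample_id = rep(c("T1", "T2"), 4),
        classification = c("TP", "FP", "TP", "unvalidated",
                           "FP", "FP", "TP", "TP"))
    out <- tpRateTable(rec)
    aTot <- out[out$caller == "a" & out$sample_id == "TOTAL", ]
    expect_equal(aTot$fusions_overall, 4L)
    expect_equal(aTot$tp, 2L)
    expect_equal(aTot$tp_rate_percent, 50)
    ## totals come from counts, not averaged per-sample rates
    skew <- data.frame(caller = "c", sample_id = c("T1", "T2"),
                       fusions_overall = c(99L, 1L), tp = c(0L, 1L))
    skewTot <- tpRateTable(skew)
    expect_equal(skewTot$tp_rate_percent[skewTot$sample_id == "TOTAL"],
                 1.00)
})

test_that("callerOverlapTable satisfies the TP/FP/FN identities", {
    truth <- sprintf("K%02d", 1:29)
    sets <- list(meta = truth[1:19],
                 exact = truth,
                 noisy = c(truth[1:10], "X--Y", "P--Q"))
    out <- callerOverlapTable(sets, truth)
    expect_equal(out$fn[out$caller == "meta"], 10L)
    expect_equal(out$fp[out$caller == "exact"], 0L)
    expect_equal(out$fn[out$caller == "exact"], 0L)
    expect_equal(out$identified, out$tp + out$fp)
    expect_equal(out$tp + out$fn, rep(29L, 3))
    ## random sets against brute-force set arithmetic
    set.seed(9)
    for (i in 1:50) {
        ids <- sample(truth, sample(0:29, 1))
        extra <- sprintf("E%d", seq_len(sample(0:5, 1)))
        got <- callerOverlapTable(list(x = c(ids, extra)), truth)
        expect_equal(got$tp, sum(truth %in% c(ids, extra)))
        expect_equal(got$fp, length(extra))
        expect_equal(got$fn, sum(!truth %in% ids))
    }
})

test_that("roundHalfUp rounds ties upward at two decimals", {
    expect_equal(roundHalfUp(47.505, 2), 47.51)
    expect_equal(roundHalfUp(8.208955, 2), 8.21)
    expect_equal(roundHalfUp(0.484, 2), 0.48)
    expect_equal(roundHalfUp(2.565, 2), 2.57)
})
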