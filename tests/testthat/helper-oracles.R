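## Independent oracles: every reference implementation here deliberately
## takes a different route from the package code (lm()/predict.lm() and
## t.test() instead of closed forms; per-base marking instead of interval
## arithmetic; exhaustive enumeration instead of grouped voting).

make_expr <- function(m) {
    ExpressionMatrix(m, normalization = list(method = "test",
                                             logOffset = NA_real_))
}

make_counts <- function(m, librarySizes = NULL) {
    CountMatrix(m, librarySizes = librarySizes)
}

rand_matrix <- function(nGenes, nSamples, seed, mean = 5, sd = 1) {
    set.seed(seed)
    matrix(rnorm(nGenes * nSamples, mean, sd), nGenes, nSamples,
           dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                           paste0("s", seq_len(nSamples))))
}

## band sides via lm() + predict.lm(interval = "prediction"/"confidence")
oracle_band_sides <- function(m, target, comparator, level = 0.999,
                              interval = "prediction") {
    df <- data.frame(x = m[, comparator], y = m[, target])
    fit <- stats::lm(y ~ x, data = df)
    band <- suppressWarnings(
        stats::predict(fit, newdata = df, interval = interval,
                       level = level))
    unname(ifelse(df$y > band[, "upr"], 1L,
                  ifelse(df$y < band[, "lwr"], -1L, 0L)))
}

## full per-sample DE statistic by plain enumeration + t.test()
oracle_pcomp <- function(m, bandLevel = 0.999, testAlpha = 0.05,
                         allowedShared = 0L) {
    out <- list()
    for (target in colnames(m)) {
        comps <- setdiff(colnames(m), target)
        sides <- sapply(comps, function(cc)
            oracle_band_sides(m, target, cc, level = bandLevel))
        need <- length(comps) - allowedShared
        for (g in seq_len(nrow(m))) {
            s <- sides[g, ]
            dir <- NULL
            if (sum(s == 1L) >= need && !any(s == -1L)) dir <- "up"
            if (sum(s == -1L) >= need && !any(s == 1L)) dir <- "down"
            if (is.null(dir)) next
            tt <- stats::t.test(m[g, comps], mu = m[g, target])
            if (tt$p.value < testAlpha)
                out[[length(out) + 1L]] <- data.frame(
                    gene_id = rownames(m)[g], sample_id = target,
                    direction = dir, p_value = unname(tt$p.value),
                    stringsAsFactors = FALSE)
        }
    }
    if (length(out)) do.call(rbind, out) else
        data.frame(gene_id = character(), sample_id = character(),
                   direction = character(), p_value = numeric())
}

## union-exon length by marking individual bases
oracle_union_length <- function(starts, ends) {
    covered <- logical(max(ends))
    for (i in seq_along(starts))
        covered[starts[i]:ends[i]] <- TRUE
    sum(covered)
}

## consensus voting by counting supporting callers per key
oracle_consensus_keys <- function(callerSets, minCallers = 2L) {
    keys <- unique(as.character(unlist(callerSets)))
    keep <- vapply(keys, function(k)
        sum(vapply(callerSets, function(s) k %in% s, logical(1))) >=
            minCallers, logical(1))
    sort(keys[keep])
}

## exhaustive fusion x breakpoint window check
oracle_window_match <- function(chrom, pos, bp, window) {
    hit <- FALSE
    for (i in seq_len(nrow(bp)))
        if (bp$chrom[i] == chrom && abs(bp$pos[i] - pos) <= window)
            hit <- TRUE
    hit
}

## minimal filtered CallerReport built straight from fusion keys
report_from_keys <- function(caller, sample, keys, spanning = NULL) {
    parts <- strsplit(keys, "--", fixed = TRUE)
    n <- length(keys)
    calls <- data.frame(
        gene5p = if (n) vapply(parts, `[`, character(1), 1L) else character(),
        gene3p = if (n) vapply(parts, `[`, character(1), 2L) else character(),
        chrom5p = rep("chr1", n), pos5p = rep(1000L, n),
        chrom3p = rep("chr2", n), pos3p = rep(2000L, n),
        spanning_reads = if (is.null(spanning)) rep(5L, n) else spanning,
        confidence = rep("pass", n), stringsAsFactors = FALSE)
    new("CallerReport", caller = caller, sample = sample, calls = calls,
        filtered = TRUE, nDropped = 0L)
}

write_tsv_tmp <- function(df, ext = ".tsv", sep = "\t") {
    path <- tempfile(fileext = ext)
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
    path
}
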