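#' Fit one sample pair with an outlier band
#'
#' Regresses the target sample's log2 expression (y) on the comparator's
#' (x) across genes by ordinary least squares and classifies every gene
#' against a band around the fitted line. The default band is the pointwise
#' \emph{prediction} interval at \code{bandLevel}: its half-width at
#' \eqn{x_g} is
#' \deqn{t_{1-\alpha/2,\,n-2}\; s \sqrt{1 + 1/n + (x_g-\bar x)^2 / S_{xx}}}
#' with \eqn{\alpha = 1 - } \code{bandLevel}, \eqn{s} the residual standard
#' deviation and \eqn{S_{xx} = \sum (x-\bar x)^2}. A mean-confidence band
#' (the same expression without the leading 1) is available via
#' \code{bandType = "confidence"} but shrinks towards zero width as the
#' number of genes grows, which makes it unsuitable for flagging individual
#' gene points.
#'
#' The target is always plotted on y, so a gene above the band (side +1)
#' is over-expressed in the target relative to the comparator.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param target,comparator sample ids; must differ.
#' @param bandLevel coverage of the band, strictly in (0, 1); 0.999
#'   reproduces 99.9% bands (pair-level p = 0.001).
#' @param bandType \code{"prediction"} (default) or \code{"confidence"}.
#' @return A [PairwiseFit-class].
#' @export
fitPair <- function(expr, target, comparator, bandLevel = 0.999,
                    bandType = c("prediction", "confidence")) {
    bandType <- match.arg(bandType)
    stopifnot(is(expr, "ExpressionMatrix"))
    if (identical(target, comparator))
        stop("target and comparator must differ")
    m <- logExpr(expr)
    if (!all(c(target, comparator) %in% colnames(m)))
        stop("unknown sample id: ",
             paste(setdiff(c(target, comparator), colnames(m)),
                   collapse = ", "))
    y <- m[, target]
    x <- m[, comparator]
    n <- length(x)
    if (n < 3L)
        stop("at least 3 genes are required")
    xbar <- mean(x)
    sxx <- sum((x - xbar)^2)
    if (sxx == 0)
        stop("degenerate comparator: zero variance in '", comparator, "'")
    slope <- sum((x - xbar) * (y - mean(y))) / sxx
    intercept <- mean(y) - slope * xbar
    fitted <- intercept + slope * x
    res <- y - fitted
    s <- sqrt(sum(res^2) / (n - 2L))
    lev <- (x - xbar)^2 / sxx + 1 / n
    if (bandType == "prediction") lev <- lev + 1
    hw <- stats::qt(1 - (1 - bandLevel) / 2, df = n - 2L) * s * sqrt(lev)
    side <- integer(n)
    side[y > fitted + hw] <- 1L
    side[y < fitted - hw] <- -1L
    new("PairwiseFit", target = target, comparator = comparator,
        slope = slope, intercept = intercept, residualSD = s,
        nGenes = n, bandLevel = bandLevel, bandType = bandType,
        side = setNames(side, rownames(m)),
        x = setNames(unname(x), rownames(m)),
        y = setNames(unname(y), rownames(m)))
}

#' Consensus outliers across all pairwise fits of one sample
#'
#' A gene is reported for the target sample when it lies outside the band
#' on the \emph{same} side in at least \code{n_fits - allowedShared} fits
#' and never on the opposite side in the remaining fits. With the strict
#' default (\code{allowedShared = 0}) this is the all-pairs rule: outside,
#' same side, in every comparison. Direction is \code{up} for +1 and
#' \code{down} for -1.
#'
#' @param fits list of [PairwiseFit-class] objects sharing one target
#'   sample (one fit per comparator).
#' @param allowedShared number of comparators allowed to share the target's
#'   expression (fits in which the gene may sit inside the band).
#' @return data.frame with columns gene_id, direction, n_pairs_outside.
#' @export
consensusOutliers <- function(fits, allowedShared = 0L) {
    stopifnot(length(fits) >= 1L)
    targets <- vapply(fits, function(f) f@target, character(1))
    if (length(unique(targets)) != 1L)
        stop("fits come from mixed target samples: ",
             paste(unique(targets), collapse = ", "))
    genes <- names(fits[[1L]]@side)
    sides <- vapply(fits, function(f) {
        if (!identical(names(f@side), genes))
            stop("fits disagree on the gene set")
        f@side
    }, integer(length(genes)))
    sides <- matrix(sides, nrow = length(genes),
                    dimnames = list(genes, NULL))
    nFits <- length(fits)
    nPos <- rowSums(sides == 1L)
    nNeg <- rowSums(sides == -1L)
    need <- nFits - allowedShared
    up <- nPos >= need & nNeg == 0L
    down <- nNeg >= need & nPos == 0L
    data.frame(
        gene_id = c(genes[up], genes[down]),
        direction = rep(c("up", "down"), c(sum(up), sum(down))),
        n_pairs_outside = c(nPos[up], nNeg[down]),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' One-sample t-test of a gene's value in one sample against the rest
#'
#' Two-sided one-sample t-test of the non-target samples' expression
#' values against the hypothesized mean equal to the target sample's value,
#' with n - 2 degrees of freedom in an n-sample cohort. Degenerate
#' conventions when the rest have zero variance: p = 1 (t = 0) if their
#' common value equals the target's, p = 0 otherwise.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param gene gene id.
#' @param target sample id whose value is tested against the rest.
#' @return list with t_statistic, p_value, df and a degenerate flag.
#' @export
oneSampleTest <- function(expr, gene, target) {
    m <- logExpr(expr)
    stopifnot(gene %in% rownames(m), target %in% colnames(m))
    value <- m[gene, target]
    rest <- m[gene, colnames(m) != target]
    if (length(rest) < 3L)
        stop("at least 3 non-target samples are required")
    sdr <- stats::sd(rest)
    df <- length(rest) - 1L
    if (sdr == 0) {
        eq <- isTRUE(all.equal(mean(rest), value))
        return(list(t_statistic = if (eq) 0 else
                        sign(mean(rest) - value) * Inf,
                    p_value = if (eq) 1 else 0,
                    df = df, degenerate = TRUE))
    }
    t <- (mean(rest) - value) / (sdr / sqrt(length(rest)))
    list(t_statistic = t, p_value = 2 * stats::pt(-abs(t), df),
         df = df, degenerate = FALSE)
}

## vectorized t-test over a set of candidate genes for one target sample
.one_sample_tests <- function(m, genes, target) {
    rest <- m[genes, colnames(m) != target, drop = FALSE]
    value <- m[genes, target]
    k <- ncol(rest)
    mu <- rowMeans(rest)
    sdr <- sqrt(rowSums((rest - mu)^2) / (k - 1L))
    t <- ifelse(sdr == 0,
                ifelse(mu == value, 0, sign(mu - value) * Inf),
                (mu - value) / (sdr / sqrt(k)))
    p <- ifelse(is.infinite(t), 0,
                ifelse(sdr == 0, 1, 2 * stats::pt(-abs(t), k - 1L)))
    data.frame(gene_id = genes, t_statistic = t, p_value = p,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample differential expression by pairwise comparison (PComp)
#'
#' For every sample in turn: fit a regression with an outlier band against
#' each of the other n - 1 samples ([fitPair()]), keep genes outside the
#' band on the same side in all (or all but \code{allowedShared})
#' comparisons ([consensusOutliers()]), and confirm each candidate with a
#' two-sided one-sample t-test of the remaining samples against the
#' target's value. Candidates with p below \code{testAlpha} are reported,
#' sorted by p within sample.
#'
#' @param expr an [ExpressionMatrix-class] with at least 3 samples.
#' @param bandLevel band coverage per pair (default 0.999, i.e. 99.9%).
#' @param testAlpha p-value threshold of the confirming t-test (default
#'   0.05; a stringent cohort analysis would use 0.001).
#' @param allowedShared samples allowed to share the target's expression
#'   (default 0: strict all-pairs consensus).
#' @param bandType passed to [fitPair()].
#' @return A [PCompResult-class].
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(50 * 6, 5, 0.3), 50, 6,
#'             dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
#' m[1, 1] <- m[1, 1] + 6
#' res <- pcomp(ExpressionMatrix(m))
#' deCalls(res)
#' @export
pcomp <- function(expr, bandLevel = 0.999, testAlpha = 0.05,
                  allowedShared = 0L, bandType = "prediction") {
    stopifnot(is(expr, "ExpressionMatrix"))
    m <- logExpr(expr)
    samples <- colnames(m)
    if (length(samples) < 3L)
        stop("PComp requires at least 3 samples")
    out <- vector("list", length(samples))
    for (i in seq_along(samples)) {
        target <- samples[i]
        fits <- lapply(setdiff(samples, target), function(comp) {
            tryCatch(fitPair(expr, target, comp, bandLevel = bandLevel,
                             bandType = bandType),
                     error = function(e) stop(sprintf(
                         "pair %s ~ %s: %s", target, comp,
                         conditionMessage(e)), call. = FALSE))
        })
        cand <- consensusOutliers(fits, allowedShared = allowedShared)
        if (!nrow(cand)) next
        tt <- .one_sample_tests(m, cand$gene_id, target)
        cand <- cbind(cand, tt[c("t_statistic", "p_value")])
        cand <- cand[cand$p_value < testAlpha, , drop = FALSE]
        if (!nrow(cand)) next
        cand$sample_id <- target
        out[[i]] <- cand[order(cand$p_value), ]
    }
    calls <- do.call(rbind, out)
    if (is.null(calls))
        calls <- data.frame(gene_id = character(), direction = character(),
                            n_pairs_outside = integer(),
                            t_statistic = numeric(), p_value = numeric(),
                            sample_id = character())
    calls <- calls[c("gene_id", "sample_id", "direction", "n_pairs_outside",
                     "t_statistic", "p_value")]
    rownames(calls) <- NULL
    new("PCompResult", calls = calls,
        parameters = list(bandLevel = bandLevel, testAlpha = testAlpha,
                          allowedShared = as.integer(allowedShared),
                          bandType = bandType))
}

#' Direction concordance with an external differential-expression list
#'
#' Overlaps PComp calls with a reference list (for example genes flagged by
#' a transcriptomic-array analysis) per sample and reports how often the
#' up/down assignment agrees. Concordance is 100 x (genes with identical
#' direction) / (overlap genes), rounded to 2 decimals; samples with an
#' empty overlap report NA.
#'
#' @param result a [PCompResult-class].
#' @param reference data.frame with columns gene, sample and direction
#'   (tokens \code{up} / \code{down}).
#' @return data.frame with one row per sample: n_overlap_up (both methods
#'   say up), n_overlap_down, n_overlap, concordance_percent.
#' @export
concordanceWithReference <- function(result, reference) {
    stopifnot(is(result, "PCompResult"))
    need <- c("gene", "sample", "direction")
    miss <- setdiff(need, names(reference))
    if (length(miss))
        stop("reference is missing column(s): ", paste(miss, collapse = ", "))
    bad <- setdiff(unique(reference$direction), c("up", "down"))
    if (length(bad))
        stop("unknown direction token in reference: ",
             paste(bad, collapse = ", "))
    calls <- deCalls(result)
    samples <- sort(unique(c(calls$sample_id, reference$sample)))
    rows <- lapply(samples, function(s) {
        a <- calls[calls$sample_id == s, ]
        b <- reference[reference$sample == s, ]
        shared <- intersect(a$gene_id, b$gene)
        da <- setNames(a$direction, a$gene_id)[shared]
        db <- setNames(b$direction, b$gene)[shared]
        nUp <- sum(da == "up" & db == "up")
        nDown <- sum(da == "down" & db == "down")
        data.frame(sample_id = s, n_overlap_up = nUp,
                   n_overlap_down = nDown, n_overlap = length(shared),
                   concordance_percent = if (length(shared) == 0) NA_real_
                   else roundHalfUp(100 * (nUp + nDown) / length(shared), 2),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.005 -> 0.01), matching how
#' percentage tables are conventionally printed, unlike [round()]'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
roundHalfUp <- function(x, digits = 2) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
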