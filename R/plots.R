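#' Plot one pairwise fit with its outlier band
#'
#' Scatter of per-gene log2 expression for a sample pair, the regression
#' line (solid), the band curves (dashed) and optional highlighted genes.
#'
#' @param fit a [PairwiseFit-class].
#' @param highlight character vector of gene ids to emphasize.
#' @param ... passed to [graphics::plot()].
#' @return \code{fit}, invisibly.
#' @export
plotPairFit <- function(fit, highlight = NULL, ...) {
    stopifnot(is(fit, "PairwiseFit"))
    x <- fit@x; y <- fit@y
    n <- fit@nGenes
    xbar <- mean(x)
    sxx <- sum((x - xbar)^2)
    grid <- seq(min(x), max(x), length.out = 200L)
    lev <- (grid - xbar)^2 / sxx + 1 / n
    if (fit@bandType == "prediction") lev <- lev + 1
    hw <- stats::qt(1 - (1 - fit@bandLevel) / 2, df = n - 2L) *
        fit@residualSD * sqrt(lev)
    mid <- fit@intercept + fit@slope * grid
    graphics::plot(x, y, pch = 16, cex = 0.4, col = "grey40",
                   xlab = fit@comparator, ylab = fit@target,
                   ylim = range(c(y, mid + hw, mid - hw)), ...)
    graphics::abline(fit@intercept, fit@slope, col = "red")
    graphics::lines(grid, mid + hw, col = "red", lty = 2)
    graphics::lines(grid, mid - hw, col = "red", lty = 2)
    if (!is.null(highlight)) {
        idx <- match(highlight, names(x))
        idx <- idx[!is.na(idx)]
        graphics::points(x[idx], y[idx], pch = 16, col = "forestgreen",
                         cex = 0.9)
    }
    invisible(fit)
}

#' Render a pairwise fit plot to a file
#'
#' Thin device wrapper around [plotPairFit()]; the format follows the
#' file extension (.pdf or .png).
#'
#' @param fit a [PairwiseFit-class].
#' @param file output path ending in .pdf or .png.
#' @param highlight passed to [plotPairFit()].
#' @param width,height device size in inches.
#' @return \code{file}, invisibly.
#' @export
renderPairPlot <- function(fit, file, highlight = NULL, width = 5,
                           height = 5) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           pdf = grDevices::pdf(file, width = width, height = height),
           png = grDevices::png(file, width = width * 96,
                                height = height * 96),
           stop("unsupported plot format: .", ext))
    on.exit(grDevices::dev.off())
    plotPairFit(fit, highlight = highlight)
    invisible(file)
}
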