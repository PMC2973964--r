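# Manhattan plot and trait histograms. The data series behind each figure
# (positions, -log10 p, highlight mask; histogram breaks and counts) are
# exposed as plain objects so they can be tested independently of the
# raster backend; PNG generation itself is only smoke-tested.

#' Manhattan plot data series
#'
#' One point per region at the region midpoint, chromosomes concatenated
#' left to right along a cumulative genome coordinate, y = -log10(p).
#' Regions with p at or below \code{highlightThreshold} are flagged for
#' highlighting. p = 0 cannot be log-transformed and is clamped to the
#' smallest representable positive double with a warning; p = 1 plots at 0.
#'
#' @param results result data.frame from [analyzeCC()] or [analyzeQT()].
#' @param pColumn which p-value column to plot; default picks
#'   \code{pPearson} or \code{pReg}, whichever the results carry.
#' @param highlightThreshold p-value threshold for highlighting.
#' @return data.frame with \code{region}, \code{chrom}, \code{x} (cumulative
#'   midpoint bp), \code{logP} and logical \code{highlight}.
#' @export
manhattanData <- function(results, pColumn = NULL, highlightThreshold = 1e-4) {
    if (is.null(pColumn))
        pColumn <- if ("pPearson" %in% names(results)) "pPearson" else "pReg"
    p <- results[[pColumn]]
    keep <- !is.na(p)
    r <- results[keep, , drop = FALSE]; p <- p[keep]
    if (any(p == 0)) {
        warning("p-values of 0 clamped to the smallest representable double")
        p[p == 0] <- .Machine$double.xmin
    }
    chroms <- unique(r$chrom)
    num <- suppressWarnings(as.numeric(chroms))
    chroms <- chroms[order(is.na(num), num, chroms)]
    offset <- 0
    x <- numeric(nrow(r))
    for (ch in chroms) {
        i <- r$chrom == ch
        x[i] <- offset + (r$start[i] + r$end[i]) / 2
        if (any(i)) offset <- offset + max(r$end[i]) + 1
    }
    data.frame(region = r$region, chrom = r$chrom, x = x,
               logP = -log10(p), highlight = p <= highlightThreshold)
}

#' Render the Manhattan plot
#'
#' @inheritParams manhattanData
#' @param path output PNG path.
#' @param width,height image size in pixels.
#' @param pointSize point expansion factor.
#' @return the path, invisibly.
#' @export
plotManhattan <- function(results, path, pColumn = NULL,
                          highlightThreshold = 1e-4, width = 1000,
                          height = 500, pointSize = 1) {
    stopifnot(width > 0, height > 0)
    md <- manhattanData(results, pColumn, highlightThreshold)
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    if (nrow(md)) {
        plot(md$x, md$logP, pch = 20, cex = pointSize,
             col = ifelse(md$highlight, "red", "grey40"),
             xlab = "Position (bp, chromosomes concatenated)",
             ylab = expression(-log[10](italic(p))),
             main = "Region collapsing association scan")
        graphics::abline(h = -log10(highlightThreshold), lty = 2,
                         col = "red")
    } else {
        plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "Position (bp)",
             ylab = expression(-log[10](italic(p))),
             main = "Region collapsing association scan")
    }
    invisible(path)
}

#' Freedman-Diaconis histogram breaks
#'
#' @param x numeric values (NAs dropped); a constant or empty vector falls
#'   back to a single unit-width bin.
#' @return numeric vector of break points.
#' @export
fdBreaks <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(0, 1))
    if (diff(range(x)) == 0) return(c(x[1] - 0.5, x[1] + 0.5))
    n <- max(1, grDevices::nclass.FD(x))
    seq(min(x), max(x), length.out = n + 1)
}

#' Trait histogram data
#'
#' @param traits numeric trait values across all individuals.
#' @param breaks histogram breaks; default Freedman-Diaconis on the data.
#' @return list with \code{breaks}, \code{counts} and \code{mids}.
#' @export
traitHistogramData <- function(traits, breaks = fdBreaks(traits)) {
    x <- traits[!is.na(traits)]
    h <- if (length(x)) graphics::hist(x, breaks = breaks, plot = FALSE,
                                       include.lowest = TRUE)
         else list(breaks = breaks, counts = integer(length(breaks) - 1),
                   mids = (breaks[-1] + breaks[-length(breaks)]) / 2)
    list(breaks = h$breaks, counts = h$counts, mids = h$mids)
}

#' Carrier / non-carrier histogram data
#'
#' Shared Freedman-Diaconis breaks computed on the pooled trait so the two
#' group histograms are directly comparable.
#'
#' @param carrierTraits,nonCarrierTraits trait values per group.
#' @return list with \code{breaks}, \code{mids}, \code{carrierCounts},
#'   \code{nonCarrierCounts}.
#' @export
groupHistogramData <- function(carrierTraits, nonCarrierTraits) {
    breaks <- fdBreaks(c(carrierTraits, nonCarrierTraits))
    hc <- traitHistogramData(carrierTraits, breaks)
    hn <- traitHistogramData(nonCarrierTraits, breaks)
    list(breaks = breaks, mids = hc$mids, carrierCounts = hc$counts,
         nonCarrierCounts = hn$counts)
}

#' Render the overall trait histogram
#'
#' @inheritParams traitHistogramData
#' @param path output PNG path.
#' @param width,height image size in pixels.
#' @return the path, invisibly.
#' @export
plotTraitHistogram <- function(traits, path, width = 800, height = 500) {
    hd <- traitHistogramData(traits)
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    plotBars(hd$mids, hd$counts, "grey60", "Quantitative trait",
             "Trait distribution, all individuals")
    invisible(path)
}

#' Render the carrier vs non-carrier trait histogram
#'
#' Carriers in red, non-carriers in blue, on shared breaks; drawn for every
#' region whose regression p reaches the reporting threshold.
#'
#' @inheritParams groupHistogramData
#' @param path output PNG path.
#' @param width,height image size in pixels.
#' @param title plot title (typically the region name).
#' @return the path, invisibly.
#' @export
plotGroupHistogram <- function(carrierTraits, nonCarrierTraits, path,
                               width = 800, height = 500, title = "") {
    hd <- groupHistogramData(carrierTraits, nonCarrierTraits)
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    ylim <- c(0, max(1, hd$carrierCounts, hd$nonCarrierCounts))
    plotBars(hd$mids, hd$nonCarrierCounts,
             grDevices::rgb(0, 0, 1, 0.5), "Quantitative trait", title,
             ylim = ylim)
    if (length(hd$mids))
        graphics::barplot(hd$carrierCounts,
                          width = diff(hd$breaks)[1], space = 0,
                          col = grDevices::rgb(1, 0, 0, 0.5), add = TRUE,
                          axes = FALSE)
    graphics::legend("topright", fill = c("red", "blue"),
                     legend = c("carrier", "non-carrier"), bty = "n")
    invisible(path)
}

plotBars <- function(mids, counts, col, xlab, main, ylim = NULL) {
    if (!length(mids)) {
        plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = xlab,
             ylab = "Count", main = main)
        return(invisible(NULL))
    }
    w <- if (length(mids) > 1) diff(mids)[1] else 1
    if (is.null(ylim)) ylim <- c(0, max(1, counts))
    graphics::barplot(counts, width = w, space = 0, col = col,
                      names.arg = signif(mids, 3), xlab = xlab,
                      ylab = "Count", main = main, ylim = ylim)
    invisible(NULL)
}
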