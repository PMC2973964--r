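# Region construction (gene +/- flanks, sliding windows) and marker
# assignment. Regions are GRanges; coordinates are 1-based and interval
# membership is inclusive at both ends, the linkage/MAP convention.

#' @importFrom GenomicRanges GRanges findOverlaps start end
#' @importFrom IRanges IRanges
NULL

markerRanges <- function(markers) {
    GenomicRanges::GRanges(
        seqnames = if (nrow(markers)) markers$chrom else character(),
        ranges = IRanges::IRanges(start = markers$bp, width = 1))
}

#' Build gene-centric analysis regions
#'
#' One region per gene, named by gene name, spanning
#' \code{[max(0, start - flankUp), stop + flankDown]}. Overlapping gene
#' regions are allowed and analysed independently.
#'
#' @param genes data.frame from [readGeneFile()] (already restricted to the
#'   chromosome under analysis by the caller).
#' @param flankUp,flankDown non-negative flank sizes in bp added upstream of
#'   the transcription start and downstream of the stop.
#' @return A \code{GRanges}, one range per gene, with metadata columns
#'   \code{name} and \code{geneID}.
#' @examples
#' g <- data.frame(geneID = "51150", geneName = "SDF4", chrom = "1",
#'                 startBp = 1142151L, stopBp = 1157274L)
#' buildGeneRegions(g, flankUp = 50000, flankDown = 50000)
#' @export
buildGeneRegions <- function(genes, flankUp = 0, flankDown = 0) {
    stopifnot(flankUp >= 0, flankDown >= 0)
    gr <- GenomicRanges::GRanges(
        seqnames = if (nrow(genes)) genes$chrom else character(),
        ranges = IRanges::IRanges(
            start = pmax(0L, as.integer(genes$startBp - flankUp)),
            end = as.integer(genes$stopBp + flankDown)))
    S4Vectors::mcols(gr)$name <- genes$geneName
    S4Vectors::mcols(gr)$geneID <- genes$geneID
    names(gr) <- genes$geneName
    gr
}

#' Build sliding-window analysis regions
#'
#' Windows \code{[k*step, k*step + window]} on a grid anchored at bp 0, for
#' every k whose window overlaps the span of the observed marker positions.
#' Anchoring at 0 (rather than at the first marker) keeps window identities
#' reproducible across datasets. Windows containing zero markers are still
#' emitted, so they appear in the per-chromosome output with \code{"(0/0)"}
#' counts. Window names encode chromosome, start and end.
#'
#' @param markers marker table for one chromosome.
#' @param windowBp window length in bp (> 0).
#' @param stepBp step between window starts in bp (> 0); defaults to half the
#'   window, giving two-fold overlapping "sliding" windows. A step larger
#'   than the window leaves gaps and is permitted with a warning.
#' @return A \code{GRanges} with metadata column \code{name}.
#' @examples
#' mk <- data.frame(name = paste0("S", 1:3), chrom = "1",
#'                  bp = c(100L, 500L, 900L))
#' buildSlidingWindows(mk, windowBp = 500, stepBp = 250)
#' @export
buildSlidingWindows <- function(markers, windowBp, stepBp = windowBp / 2) {
    stopifnot(windowBp > 0, stepBp > 0)
    if (stepBp > windowBp)
        warning("step exceeds window length: tiling leaves gaps")
    if (!nrow(markers))
        return(GenomicRanges::GRanges())
    lo <- min(markers$bp); hi <- max(markers$bp)
    # smallest k-range on the 0-anchored grid whose union covers [lo, hi]
    kmin <- max(0, floor(lo / stepBp))
    kmax <- max(kmin, ceiling((hi - windowBp) / stepBp))
    k <- seq.int(kmin, kmax)
    starts <- as.integer(k * stepBp)
    gr <- GenomicRanges::GRanges(
        seqnames = markers$chrom[1],
        ranges = IRanges::IRanges(start = starts,
                                  end = as.integer(starts + windowBp)))
    nm <- sprintf("%s:%d-%d", markers$chrom[1], starts, starts + windowBp)
    S4Vectors::mcols(gr)$name <- nm
    names(gr) <- nm
    gr
}

#' Assign markers to regions
#'
#' Interval-tree overlap of single-bp marker positions against region
#' intervals; both region bounds are inclusive.
#'
#' @param markers marker table for the chromosome.
#' @param regions \code{GRanges} of analysis regions.
#' @return list (one element per region) of integer marker indices, each
#'   sorted by position within the region.
#' @export
assignMarkers <- function(markers, regions) {
    out <- rep(list(integer()), length(regions))
    if (!nrow(markers) || !length(regions)) return(out)
    hits <- GenomicRanges::findOverlaps(markerRanges(markers), regions,
                                        ignore.strand = TRUE)
    sp <- split(S4Vectors::queryHits(hits),
                factor(S4Vectors::subjectHits(hits),
                       levels = seq_along(regions)))
    lapply(sp, function(i) i[order(markers$bp[i])])
}
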