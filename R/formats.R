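# Readers for linkage-format inputs and writers for the tabular result files.

#' Read a marker map file
#'
#' Reads a whitespace-delimited per-chromosome map file. Two dialects are
#' auto-detected per file: 3 columns (chromosome, marker, bp position) or
#' 4 columns in PLINK style (chromosome, marker, genetic position, bp
#' position). Mixed column counts within one file are rejected, as are rows
#' with a non-integer bp or more than one chromosome value in the file.
#'
#' @param path path to the map file.
#' @return data.frame with columns \code{name}, \code{chrom}, \code{bp}
#'   (integer, 1-based) and \code{geneticPos} (numeric, \code{NA} for
#'   3-column files), in file order.
#' @examples
#' f <- tempfile()
#' writeLines(c("1 SNP1 1111", "1 SNP2 2111"), f)
#' readMap(f)
#' @export
readMap <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
        return(data.frame(name = character(), chrom = character(),
                          bp = integer(), geneticPos = numeric()))
    toks <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(toks)
    if (any(!nf %in% c(3L, 4L)))
        stop(sprintf("map file '%s': line %d has %d fields (expected 3 or 4)",
                     path, which(!nf %in% c(3L, 4L))[1],
                     nf[which(!nf %in% c(3L, 4L))[1]]))
    if (length(unique(nf)) > 1)
        stop(sprintf("map file '%s': mixed 3- and 4-column rows", path))
    ncol <- nf[1]
    m <- do.call(rbind, toks)
    bpcol <- if (ncol == 3L) 3L else 4L
    bp <- suppressWarnings(as.integer(m[, bpcol]))
    if (anyNA(bp) || any(m[, bpcol] != as.character(bp)))
        stop(sprintf("map file '%s': line %d has non-integer bp '%s'",
                     path, which(is.na(bp) | m[, bpcol] != as.character(bp))[1],
                     m[which(is.na(bp) | m[, bpcol] != as.character(bp))[1], bpcol]))
    if (any(bp < 0))
        stop(sprintf("map file '%s': negative bp position", path))
    if (length(unique(m[, 1])) > 1)
        stop(sprintf("map file '%s': more than one chromosome (%s)",
                     path, paste(unique(m[, 1]), collapse = ", ")))
    gp <- if (ncol == 4L) suppressWarnings(as.numeric(m[, 3])) else
        rep(NA_real_, nrow(m))
    data.frame(name = m[, 2], chrom = m[, 1], bp = bp, geneticPos = gp)
}

#' Read a pre-Makeped linkage pedigree file
#'
#' Parses a whitespace-delimited PED file with six leading columns (pedigree
#' id, individual id, father, mother, sex, affection status or trait value)
#' followed by two allele columns per marker of the companion map.
#'
#' In \code{"binary"} mode the sixth column is read as 1 = unaffected
#' (control), 2 = affected (case), and any value in \code{missingTraitCodes}
#' (default \code{"0"} and \code{"-9"}) as missing. In \code{"quantitative"}
#' mode it is read as a real number with \code{missingTraitCodes} (default
#' \code{"-9"}) as the missing sentinel. Allele tokens are kept verbatim;
#' \code{"0"} marks a missing allele, and a half-called pair such as
#' \code{"0 A"} is treated as a fully missing genotype downstream.
#'
#' @param path path to the PED file.
#' @param markers marker table from [readMap()] for the companion map; the
#'   expected genotype column count is \code{2 * nrow(markers)}.
#' @param traitMode \code{"binary"} or \code{"quantitative"}.
#' @param missingTraitCodes character vector of sentinel tokens for a missing
#'   phenotype; defaults depend on \code{traitMode} (\code{"0"} is a legal
#'   quantitative trait value, so only \code{"-9"} is a quantitative default).
#' @return A \linkS4class{GenotypePanel}.
#' @export
readPed <- function(path, markers,
                    traitMode = c("binary", "quantitative"),
                    missingTraitCodes = NULL) {
    traitMode <- match.arg(traitMode)
    if (is.null(missingTraitCodes))
        missingTraitCodes <- if (traitMode == "binary") c("0", "-9") else "-9"
    nm <- nrow(markers)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    n <- length(lines)
    a1 <- matrix(character(), nrow = nm, ncol = n)
    a2 <- matrix(character(), nrow = nm, ncol = n)
    ind <- data.frame(pedID = character(n), indivID = character(n),
                      fatherID = character(n), motherID = character(n),
                      sex = integer(n), phenotype = numeric(n))
    for (i in seq_len(n)) {
        tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
        if (length(tok) != 6 + 2 * nm)
            stop(sprintf(
                "ped file '%s': individual '%s' (line %d) has %d genotype fields, expected %d (2 x %d markers)",
                path, if (length(tok) >= 2) tok[2] else "?", i,
                max(0L, length(tok) - 6L), 2L * nm, nm))
        ind$pedID[i] <- tok[1]; ind$indivID[i] <- tok[2]
        ind$fatherID[i] <- tok[3]; ind$motherID[i] <- tok[4]
        sx <- suppressWarnings(as.integer(tok[5]))
        ind$sex[i] <- if (is.na(sx)) 0L else sx
        ind$phenotype[i] <- parseTrait(tok[6], traitMode, missingTraitCodes,
                                       path, i)
        if (nm) {
            g <- tok[-(1:6)]
            a1[, i] <- g[seq(1, 2 * nm, by = 2)]
            a2[, i] <- g[seq(2, 2 * nm, by = 2)]
        }
    }
    genotypePanel(markers, ind, a1, a2, traitMode)
}

parseTrait <- function(token, traitMode, missingCodes, path, line) {
    if (token %in% missingCodes) return(NA_real_)
    v <- suppressWarnings(as.numeric(token))
    if (is.na(v))
        stop(sprintf("ped file '%s': line %d has non-numeric trait '%s'",
                     path, line, token))
    if (traitMode == "binary" && !v %in% c(1, 2))
        stop(sprintf("ped file '%s': line %d has affection status '%s' (expected 1, 2 or a missing code)",
                     path, line, token))
    v
}

#' Read a gene-coordinate file
#'
#' Five whitespace-delimited columns: gene id, gene name, chromosome, start bp,
#' stop bp. Records are returned in file order; filtering to the chromosome
#' under analysis is the caller's job.
#'
#' @param path path to the gene file.
#' @return data.frame with columns \code{geneID}, \code{geneName},
#'   \code{chrom}, \code{startBp}, \code{stopBp}.
#' @export
readGeneFile <- function(path) {
    g <- utils::read.table(path, header = FALSE, colClasses = "character")
    if (ncol(g) != 5)
        stop(sprintf("gene file '%s': expected 5 columns, found %d",
                     path, ncol(g)))
    out <- data.frame(geneID = g[[1]], geneName = g[[2]], chrom = g[[3]],
                      startBp = as.integer(g[[4]]), stopBp = as.integer(g[[5]]))
    bad <- which(out$startBp > out$stopBp)
    if (length(bad))
        stop(sprintf("gene file '%s': gene '%s' has start %d > stop %d",
                     path, out$geneName[bad[1]], out$startBp[bad[1]],
                     out$stopBp[bad[1]]))
    out
}

# ---- output formatting -------------------------------------------------

#' Format a p-value for result tables
#'
#' Two significant figures; scientific notation (upper-case E) below 1e-3,
#' mirroring the visual style of the summary tables.
#' @param p numeric vector of p-values (NA allowed).
#' @return character vector.
#' @export
formatPval <- function(p) {
    out <- character(length(p))
    out[is.na(p)] <- ""
    ok <- !is.na(p)
    sci <- ok & p < 1e-3 & p > 0
    out[sci] <- toupper(sprintf("%.2e", p[sci]))
    out[ok & !sci] <- vapply(p[ok & !sci],
                             function(x) format(signif(x, 2), scientific = FALSE),
                             character(1))
    out
}

formatChi2 <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))

#' Format a permutation record
#'
#' @param nExceed number of permutation replicates at least as extreme as the
#'   observed statistic.
#' @param nPerm number of permutations.
#' @return e.g. \code{"Perm: 1/10 = 0.1"}; no pseudocount, so zero exceedances
#'   print as \code{"= 0"}.
#' @export
formatPerm <- function(nExceed, nPerm) {
    sprintf("Perm: %d/%d = %s", nExceed, nPerm,
            vapply(nExceed / nPerm,
                   function(p) format(p, scientific = FALSE, trim = TRUE),
                   character(1)))
}

ccColumns <- c("Gene/Wind", "Chr", "Start", "End_Pos", "N_SNPs", "CaseRV",
               "CaseNoRV", "ContRV", "ContNoRV", "ChiSq", "P-val",
               "FisherExPval")

ccResultLines <- function(results, minCell) {
    fisher <- ifelse(results$fisherSkipped, sprintf("No < %d", minCell),
                     formatPval(results$pFisher))
    data.frame(
        results$region, results$chrom, results$start, results$end,
        sprintf("(%d/%d)", results$nSNPs, results$nRare),
        results$caseRV, results$caseNoRV, results$contRV, results$contNoRV,
        formatChi2(results$chi2), formatPval(results$pPearson), fisher,
        check.names = FALSE)
}

writeTabTable <- function(df, header, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(header, collapse = "\t"), con)
    if (nrow(df))
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write case-control result tables
#'
#' \code{writeCCSummary} writes the tab-delimited summary file containing only
#' regions with Pearson p at or below \code{sigThreshold};
#' \code{writeCCChromosome} writes the per-chromosome companion file with one
#' row for every analysed region (including empty \code{"(0/0)"} windows) plus
#' a trailing permutation column.
#'
#' @param results data.frame from [analyzeCC()].
#' @param path output file path.
#' @param sigThreshold significance threshold for inclusion in the summary.
#' @param minCell minimum-cell threshold used (printed in the skip sentinel
#'   \code{"No < T"}).
#' @return the path, invisibly.
#' @export
writeCCSummary <- function(results, path, sigThreshold = 0.05, minCell = 30) {
    keep <- !is.na(results$pPearson) & results$pPearson <= sigThreshold
    writeTabTable(ccResultLines(results[keep, , drop = FALSE], minCell),
                  ccColumns, path)
}

#' @rdname writeCCSummary
#' @export
writeCCChromosome <- function(results, path, minCell = 30) {
    df <- ccResultLines(results, minCell)
    df$Permutations <- ifelse(is.na(results$nPerm), "",
                              formatPerm(results$nExceed, results$nPerm))
    writeTabTable(df, c(ccColumns, "Permutations"), path)
}

#' Write the permutation summary file
#'
#' One row per permuted region: the 2x2 carrier counts, the asymptotic
#' Pearson p and the permutation record.
#' @inheritParams writeCCSummary
#' @export
writeCCPermutationFile <- function(results, path) {
    keep <- !is.na(results$nPerm)
    r <- results[keep, , drop = FALSE]
    df <- data.frame(
        r$region, r$chrom, r$start, r$end,
        sprintf("case: (%d/%d) cont: (%d/%d)", r$caseRV, r$caseNoRV,
                r$contRV, r$contNoRV),
        formatPval(r$pPearson),
        if (nrow(r)) formatPerm(r$nExceed, r$nPerm) else character(),
        check.names = FALSE)
    writeTabTable(df, c("Gene/Window", "Chr", "Start", "End",
                        "Case:(RV/NonRV) Control:(RV/NonRV)", "Pval",
                        "Permutation Results"), path)
}

qtColumns <- c("Gene", "Chr", "Start", "End_pos", "SNPs/rvSNPs", "QT+RV",
               "QT-RV", "QT+RV_mean", "QT-RV_mean", "p-val", "BetaCoef",
               "St.Er", "[lowCI - upCI]", "t-test", "t-test_p-val")

fmtNum <- function(x, digits = 3) {
    out <- sprintf("%.*f", digits, x)
    out <- sub("0+$", "", out)
    out <- sub("\\.$", "", out)
    out[is.na(x)] <- ""
    out
}

qtResultLines <- function(results) {
    ci <- ifelse(is.na(results$ciLow), "",
                 sprintf("[%s - %s]", fmtNum(results$ciLow),
                         fmtNum(results$ciHigh)))
    data.frame(
        results$region, results$chrom, results$start, results$end,
        sprintf("(%d/%d)", results$nSNPs, results$nRare),
        results$nCarrier, results$nNonCarrier,
        fmtNum(results$meanCarrier), fmtNum(results$meanNonCarrier),
        formatPval(results$pReg), fmtNum(results$beta), fmtNum(results$se),
        ci, fmtNum(results$tStat), formatPval(results$pT),
        check.names = FALSE)
}

#' Write quantitative-trait result tables
#'
#' \code{writeQTSummary} keeps only regions with regression p at or below
#' \code{sigThreshold}; \code{writeQTChromosome} writes every region.
#' Degenerate regions (an empty carrier group) are written with empty
#' statistic fields rather than dropped, so genome-wide bookkeeping stays
#' intact.
#'
#' @param results data.frame from [analyzeQT()].
#' @param path output file path.
#' @param sigThreshold significance threshold for the summary file.
#' @return the path, invisibly.
#' @export
writeQTSummary <- function(results, path, sigThreshold = 0.05) {
    keep <- !is.na(results$pReg) & results$pReg <= sigThreshold
    writeTabTable(qtResultLines(results[keep, , drop = FALSE]), qtColumns, path)
}

#' @rdname writeQTSummary
#' @export
writeQTChromosome <- function(results, path) {
    writeTabTable(qtResultLines(results), qtColumns, path)
}

#' Write the per-region SNP list
#'
#' Lists every marker analysed within a region — common markers included, not
#' only the rare subset — with chromosome, position and minor allele
#' frequency.
#'
#' @param markers marker table (as from [panelMarkers()]).
#' @param markerIdx integer indices of the region's member markers.
#' @param mafs data.frame from [computeMaf()] aligned with \code{markers}.
#' @param path output file path.
#' @export
writeRegionSnplist <- function(markers, markerIdx, mafs, path) {
    df <- data.frame(markers$name[markerIdx], markers$chrom[markerIdx],
                     markers$bp[markerIdx],
                     fmtNum(mafs$maf[markerIdx], 3),
                     check.names = FALSE)
    writeTabTable(df, c("Marker", "Chromosome", "Position", "MAF"), path)
}
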