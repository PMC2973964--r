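# Case-control (CCRaVAT) statistics: 2x2 carrier-by-status table, Pearson
# chi-squared, Fisher's exact test under the minimum-cell rule, permutation
# empirical p-values.

#' Build the carrier x case-control 2x2 table
#'
#' @param carrier integer carrier vector from [collapseRegion()] (1/0/NA).
#' @param phenotype binary phenotype vector (1 = control, 2 = case, NA).
#' @return named integer vector \code{c(caseRV, caseNoRV, contRV, contNoRV)}.
#' @export
carrierTable <- function(carrier, phenotype) {
    ok <- !is.na(carrier) & !is.na(phenotype)
    c(caseRV = sum(ok & phenotype == 2 & carrier == 1L),
      caseNoRV = sum(ok & phenotype == 2 & carrier == 0L),
      contRV = sum(ok & phenotype == 1 & carrier == 1L),
      contNoRV = sum(ok & phenotype == 1 & carrier == 0L))
}

as2x2 <- function(tab) matrix(as.numeric(tab), nrow = 2, byrow = TRUE)

#' Pearson chi-squared test of a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) statistic on 1 df with the
#' asymptotic upper-tail p-value. A table with any zero row or column margin
#' is degenerate and returns chi-squared 0, p 1 — the convention the
#' per-chromosome output uses for regions with no rare-variant carriers.
#'
#' @param tab counts \code{c(caseRV, caseNoRV, contRV, contNoRV)} or a 2x2
#'   matrix.
#' @return list with \code{chi2} and \code{p}.
#' @examples
#' pearsonChi2(c(26, 1877, 7, 2906))  # chi2 21.44
#' @export
pearsonChi2 <- function(tab) {
    m <- if (is.matrix(tab)) tab else as2x2(tab)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0))
        return(list(chi2 = 0, p = 1))
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    list(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

#' Fisher's exact test of a 2x2 table
#'
#' Two-sided exact p summing, over all tables with the observed margins,
#' the hypergeometric probabilities no larger than that of the observed
#' table. Degenerate tables (a zero margin) have a single attainable table
#' and return p 1.
#'
#' @inheritParams pearsonChi2
#' @return the two-sided p-value.
#' @examples
#' fisherExact(c(1, 1921, 7, 2926))  # 0.158
#' @export
fisherExact <- function(tab) {
    m <- if (is.matrix(tab)) tab else as2x2(tab)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
    stats::fisher.test(m)$p.value
}

#' Minimum-cell rule gating Fisher's exact test
#'
#' Asymptotic chi-squared results are unreliable when cell counts are low, so
#' Fisher's exact test is run exactly when the smallest observed (not
#' expected) cell count falls below the threshold; otherwise the output
#' carries the sentinel \code{"No < T"}.
#'
#' @inheritParams pearsonChi2
#' @param threshold non-negative minimum cell count (default 30).
#' @return TRUE if Fisher's exact test should run.
#' @export
minCellRule <- function(tab, threshold = 30) {
    stopifnot(threshold >= 0)
    min(tab) < threshold
}

# 31-bit polynomial string hash; used to give each region its own
# reproducible permutation stream independent of processing order.
regionSeed <- function(seed, name) {
    h <- as.double(seed %% 2147483647)
    for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
    as.integer(h)
}

# Evaluate a function with a private RNG state seeded from `seed`,
# restoring the caller's stream afterwards.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    force(expr)
}

chi2closed <- function(a, b, c, d) {
    a <- as.numeric(a); b <- as.numeric(b)
    c <- as.numeric(c); d <- as.numeric(d)
    n <- a + b + c + d
    den <- (a + b) * (c + d) * (a + c) * (b + d)
    out <- n * (a * d - b * c)^2 / den
    out[den == 0] <- 0
    out
}

#' Permutation empirical p-value for the carrier test
#'
#' Case/control labels are permuted uniformly among the individuals with
#' non-missing carrier status and phenotype, preserving the case and control
#' totals, and the chi-squared statistic is recomputed for each replicate.
#' Holding carrier status fixed, a uniform label permutation makes the
#' case-carrier cell hypergeometric with the observed margins, so replicates
#' are drawn directly from that distribution and scored with the closed-form
#' statistic. Ties with the observed statistic count as exceedances, and the
#' empirical p is \code{nExceed / nPerm} with no pseudocount (zero
#' exceedances report p 0).
#'
#' @param carrier carrier vector from [collapseRegion()].
#' @param phenotype binary phenotype vector (1/2/NA).
#' @param nPerm number of permutations (>= 1).
#' @param seed integer seed for this region's stream.
#' @return list with \code{nExceed}, \code{nPerm} and \code{pEmp}.
#' @export
permuteEmpiricalP <- function(carrier, phenotype, nPerm, seed) {
    if (nPerm < 1) stop("nPerm must be at least 1")
    tab <- carrierTable(carrier, phenotype)
    obs <- pearsonChi2(tab)$chi2
    nCase <- tab[["caseRV"]] + tab[["caseNoRV"]]
    nRV <- tab[["caseRV"]] + tab[["contRV"]]
    nNoRV <- tab[["caseNoRV"]] + tab[["contNoRV"]]
    a <- withSeed(seed, stats::rhyper(nPerm, nRV, nNoRV, nCase))
    stat <- chi2closed(a, nCase - a, nRV - a, nNoRV - (nCase - a))
    nExceed <- sum(stat >= obs - 1e-12)
    list(nExceed = nExceed, nPerm = as.integer(nPerm), pEmp = nExceed / nPerm)
}

#' Analyse one region: case-control collapsing test
#'
#' Collapses the region's rare markers to carrier status, builds the 2x2
#' table, applies the Pearson test, runs Fisher's exact test when the
#' minimum-cell rule fires, and (when \code{nPerm > 0}) permutes labels for
#' regions whose asymptotic p reaches \code{permTrigger}.
#'
#' @param panel a binary-trait \linkS4class{GenotypePanel}.
#' @param region one-element \code{GRanges} (name, start, end).
#' @param markerIdx,rareIdx member / rare-member marker indices.
#' @param mafs data.frame from [computeMaf()].
#' @param minCell minimum-cell threshold for the Fisher gate.
#' @param nPerm permutations per triggered region (0 disables).
#' @param permTrigger run permutations when the Pearson p is at or below
#'   this.
#' @param seed global seed; the region stream is derived from it and the
#'   region name.
#' @param strictMissing see [collapseRegion()].
#' @return one-row data.frame (see [analyzeCC()] for columns).
#' @export
analyzeRegionCC <- function(panel, region, markerIdx, rareIdx, mafs,
                            minCell = 30, nPerm = 0, permTrigger = 0.05,
                            seed = 1, strictMissing = FALSE) {
    carrier <- collapseRegion(panel, rareIdx, mafs, strictMissing)
    ph <- phenotypes(panel)
    tab <- carrierTable(carrier, ph)
    pe <- pearsonChi2(tab)
    runFisher <- minCellRule(tab, minCell)
    pf <- if (runFisher) fisherExact(tab) else NA_real_
    res <- data.frame(
        region = S4Vectors::mcols(region)$name,
        chrom = as.character(GenomicRanges::seqnames(region)),
        start = GenomicRanges::start(region),
        end = GenomicRanges::end(region),
        nSNPs = length(markerIdx), nRare = length(rareIdx),
        caseRV = tab[["caseRV"]], caseNoRV = tab[["caseNoRV"]],
        contRV = tab[["contRV"]], contNoRV = tab[["contNoRV"]],
        chi2 = pe$chi2, pPearson = pe$p, pFisher = pf,
        fisherSkipped = !runFisher,
        nExceed = NA_integer_, nPerm = NA_integer_, pEmp = NA_real_)
    if (nPerm > 0 && !is.na(pe$p) && pe$p <= permTrigger) {
        pm <- permuteEmpiricalP(carrier, ph, nPerm,
                                regionSeed(seed, res$region))
        res$nExceed <- pm$nExceed; res$nPerm <- pm$nPerm; res$pEmp <- pm$pEmp
    }
    res
}

#' Case-control collapsing analysis over a set of regions
#'
#' @param panel a binary-trait \linkS4class{GenotypePanel}.
#' @param regions \code{GRanges} of analysis regions (see
#'   [buildGeneRegions()], [buildSlidingWindows()]).
#' @param mafCutoff MAF threshold defining low-frequency/rare variants.
#' @param mafGroup reference sample for MAF computation (see [computeMaf()]).
#' @inheritParams analyzeRegionCC
#' @return data.frame with one row per region: region identity and span,
#'   total and rare SNP counts, the four 2x2 cells, \code{chi2},
#'   \code{pPearson}, \code{pFisher} (NA when the minimum-cell rule skipped
#'   it, with \code{fisherSkipped} set), and the permutation record
#'   (\code{nExceed}, \code{nPerm}, \code{pEmp}; NA when not permuted).
#' @export
analyzeCC <- function(panel, regions, mafCutoff = 0.05, minCell = 30,
                      nPerm = 0, permTrigger = 0.05, seed = 1,
                      strictMissing = FALSE,
                      mafGroup = c("phenotyped", "controls", "all")) {
    stopifnot(traitMode(panel) == "binary")
    mafGroup <- match.arg(mafGroup)
    mafs <- computeMaf(panel, group = mafGroup)
    rare <- selectRare(mafs, mafCutoff)
    members <- assignMarkers(panelMarkers(panel), regions)
    rows <- lapply(seq_along(regions), function(i) {
        analyzeRegionCC(panel, regions[i], members[[i]],
                        intersect(members[[i]], rare), mafs,
                        minCell = minCell, nPerm = nPerm,
                        permTrigger = permTrigger, seed = seed,
                        strictMissing = strictMissing)
    })
    if (!length(rows)) return(emptyCCResult())
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

emptyCCResult <- function() {
    data.frame(region = character(), chrom = character(), start = integer(),
               end = integer(), nSNPs = integer(), nRare = integer(),
               caseRV = integer(), caseNoRV = integer(), contRV = integer(),
               contNoRV = integer(), chi2 = numeric(), pPearson = numeric(),
               pFisher = numeric(), fisherSkipped = logical(),
               nExceed = integer(), nPerm = integer(), pEmp = numeric())
}
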