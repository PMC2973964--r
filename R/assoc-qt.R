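# Quantitative-trait (QuTie) statistics: trait means by carrier status,
# linear regression of the trait on the 0/1 carrier indicator, two-sample
# t-test.

#' Split trait values by carrier status
#'
#' Individuals with a missing trait or missing carrier status are excluded
#' jointly before grouping.
#'
#' @param carrier carrier vector from [collapseRegion()] (1/0/NA).
#' @param trait numeric trait vector (NA = missing).
#' @return list with counts, means and variances per group
#'   (\code{nCarrier}, \code{nNonCarrier}, \code{meanCarrier},
#'   \code{meanNonCarrier}, \code{varCarrier}, \code{varNonCarrier}) plus
#'   the group trait vectors \code{carrierTraits}, \code{nonCarrierTraits}.
#' @export
splitGroups <- function(carrier, trait) {
    ok <- !is.na(carrier) & !is.na(trait)
    x <- trait[ok & carrier == 1L]
    y <- trait[ok & carrier == 0L]
    list(nCarrier = length(x), nNonCarrier = length(y),
         meanCarrier = if (length(x)) mean(x) else NA_real_,
         meanNonCarrier = if (length(y)) mean(y) else NA_real_,
         varCarrier = if (length(x) > 1) stats::var(x) else NA_real_,
         varNonCarrier = if (length(y) > 1) stats::var(y) else NA_real_,
         carrierTraits = x, nonCarrierTraits = y)
}

#' Ordinary least squares of the trait on carrier status
#'
#' Carriers are coded 1 and non-carriers 0, so the slope is exactly
#' mean(carrier traits) - mean(non-carrier traits). The two-sided p comes
#' from the t distribution on n - 2 df; the 95\% interval is
#' \code{beta +/- 1.96 se} (normal multiplier, deterministic across df).
#' Degenerate designs — an empty group, or zero residual variance — are
#' flagged undefined with the p = 1 convention rather than dropped.
#'
#' @inheritParams splitGroups
#' @return list with \code{beta}, \code{se}, \code{ciLow}, \code{ciHigh},
#'   \code{p} and logical \code{undefined}.
#' @export
regressOnCarrier <- function(carrier, trait) {
    ok <- !is.na(carrier) & !is.na(trait)
    x <- as.numeric(carrier[ok]); y <- trait[ok]
    undef <- list(beta = NA_real_, se = NA_real_, ciLow = NA_real_,
                  ciHigh = NA_real_, p = 1, undefined = TRUE)
    if (length(unique(x)) < 2 || length(x) < 3) return(undef)
    fit <- stats::lm(y ~ x)
    # summary.lm warns on a perfect fit; the zero-residual branch below
    # handles that case explicitly
    sm <- suppressWarnings(summary(fit))$coefficients
    if (nrow(sm) < 2 || !is.finite(sm[2, 2]) || sm[2, 2] == 0) {
        if (nrow(sm) >= 2 && sm[2, 2] == 0)  # zero residual variance
            return(list(beta = sm[2, 1], se = 0, ciLow = sm[2, 1],
                        ciHigh = sm[2, 1],
                        p = if (sm[2, 1] == 0) 1 else 0, undefined = TRUE))
        return(undef)
    }
    beta <- sm[2, 1]; se <- sm[2, 2]
    list(beta = beta, se = se, ciLow = beta - 1.96 * se,
         ciHigh = beta + 1.96 * se, p = sm[2, 4], undefined = FALSE)
}

#' Two-sample t-test of carrier vs non-carrier trait means
#'
#' Pooled-variance Student's t on n1 + n2 - 2 df by default; Welch's
#' unequal-variance form behind \code{welch = TRUE}. Two-sided p. With a
#' binary predictor the pooled t equals the regression beta/se ratio exactly.
#' Degenerate groups (fewer than two members, or zero pooled variance) are
#' flagged undefined.
#'
#' @param groups list from [splitGroups()].
#' @param welch use Welch's unequal-variance t-test.
#' @return list with \code{t}, \code{p}, \code{undefined}.
#' @export
twoSampleT <- function(groups, welch = FALSE) {
    x <- groups$carrierTraits; y <- groups$nonCarrierTraits
    if (length(x) < 2 || length(y) < 2)
        return(list(t = NA_real_, p = 1, undefined = TRUE))
    if (stats::var(x) == 0 && stats::var(y) == 0) {
        if (mean(x) == mean(y)) return(list(t = 0, p = 1, undefined = TRUE))
        return(list(t = NA_real_, p = 0, undefined = TRUE))
    }
    tt <- stats::t.test(x, y, var.equal = !welch)
    list(t = unname(tt$statistic), p = tt$p.value, undefined = FALSE)
}

#' Analyse one region: quantitative-trait collapsing test
#'
#' Collapses the region to carrier status, splits the trait by group,
#' regresses the trait on the indicator and optionally adds the two-sample
#' t-test.
#'
#' @param panel a quantitative-trait \linkS4class{GenotypePanel}.
#' @param region one-element \code{GRanges}.
#' @param markerIdx,rareIdx member / rare-member marker indices.
#' @param mafs data.frame from [computeMaf()].
#' @param ttest also run the two-sample t-test.
#' @param welch use Welch's form of the t-test.
#' @param strictMissing see [collapseRegion()].
#' @return one-row data.frame (see [analyzeQT()]).
#' @export
analyzeRegionQT <- function(panel, region, markerIdx, rareIdx, mafs,
                            ttest = TRUE, welch = FALSE,
                            strictMissing = FALSE) {
    carrier <- collapseRegion(panel, rareIdx, mafs, strictMissing)
    trait <- phenotypes(panel)
    g <- splitGroups(carrier, trait)
    reg <- regressOnCarrier(carrier, trait)
    tt <- if (ttest) twoSampleT(g, welch) else
        list(t = NA_real_, p = NA_real_, undefined = TRUE)
    data.frame(
        region = S4Vectors::mcols(region)$name,
        chrom = as.character(GenomicRanges::seqnames(region)),
        start = GenomicRanges::start(region),
        end = GenomicRanges::end(region),
        nSNPs = length(markerIdx), nRare = length(rareIdx),
        nCarrier = g$nCarrier, nNonCarrier = g$nNonCarrier,
        meanCarrier = g$meanCarrier, meanNonCarrier = g$meanNonCarrier,
        pReg = reg$p, beta = reg$beta, se = reg$se,
        ciLow = reg$ciLow, ciHigh = reg$ciHigh,
        tStat = tt$t, pT = tt$p, undefined = reg$undefined)
}

#' Quantitative-trait collapsing analysis over a set of regions
#'
#' @inheritParams analyzeRegionQT
#' @param regions \code{GRanges} of analysis regions.
#' @param mafCutoff MAF threshold defining low-frequency/rare variants.
#' @param mafGroup reference sample for MAF computation (see [computeMaf()]).
#' @return data.frame with one row per region: identity and span, SNP
#'   counts, group sizes and means, regression p / beta / se / 95\% CI,
#'   t statistic and p, and an \code{undefined} flag for degenerate regions.
#' @export
analyzeQT <- function(panel, regions, mafCutoff = 0.05, ttest = TRUE,
                      welch = FALSE, strictMissing = FALSE,
                      mafGroup = c("phenotyped", "all")) {
    stopifnot(traitMode(panel) == "quantitative")
    mafGroup <- match.arg(mafGroup)
    mafs <- computeMaf(panel, group = mafGroup)
    rare <- selectRare(mafs, mafCutoff)
    members <- assignMarkers(panelMarkers(panel), regions)
    rows <- lapply(seq_along(regions), function(i) {
        analyzeRegionQT(panel, regions[i], members[[i]],
                        intersect(members[[i]], rare), mafs,
                        ttest = ttest, welch = welch,
                        strictMissing = strictMissing)
    })
    if (!length(rows)) return(emptyQTResult())
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

emptyQTResult <- function() {
    data.frame(region = character(), chrom = character(), start = integer(),
               end = integer(), nSNPs = integer(), nRare = integer(),
               nCarrier = integer(), nNonCarrier = integer(),
               meanCarrier = numeric(), meanNonCarrier = numeric(),
               pReg = numeric(), beta = numeric(), se = numeric(),
               ciLow = numeric(), ciHigh = numeric(), tStat = numeric(),
               pT = numeric(), undefined = logical())
}
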