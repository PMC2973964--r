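# Minor-allele frequencies, rare-variant selection, and collapsing of a
# region's rare variants into a per-individual carrier indicator (the
# "super-locus").

#' Compute per-marker minor allele frequencies
#'
#' The MAF is the frequency of the rarer allele among called chromosomes:
#' count of the less-frequent allele divided by twice the number of
#' non-missing genotypes. By default frequencies are computed over all
#' phenotyped individuals jointly (cases and controls together, or all
#' trait-bearing individuals), so cases and controls share one rare-marker
#' set and the 2x2 construction stays symmetric; \code{group} restricts the
#' reference sample. A frequency tie at 0.5 is broken by taking the
#' lexicographically smaller allele token as the minor allele. Monomorphic
#' markers get MAF 0 with an undefined minor allele; markers with no called
#' genotypes get MAF \code{NA} with a warning and are never selected as rare.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param group which individuals the frequencies are computed in:
#'   \code{"phenotyped"} (default), \code{"controls"} (binary panels only;
#'   the \code{--maf-in-controls} behaviour) or \code{"all"}.
#' @return data.frame, one row per marker, with columns \code{marker}
#'   (index), \code{name}, \code{minorAllele}, \code{maf} and \code{nCalled}.
#' @export
computeMaf <- function(panel, group = c("phenotyped", "controls", "all")) {
    group <- match.arg(group)
    ph <- phenotypes(panel)
    keep <- switch(group,
                   phenotyped = !is.na(ph),
                   controls = !is.na(ph) & ph == 1,
                   all = rep(TRUE, nIndividuals(panel)))
    a1 <- SummarizedExperiment::assay(panel, "allele1")[, keep, drop = FALSE]
    a2 <- SummarizedExperiment::assay(panel, "allele2")[, keep, drop = FALSE]
    miss <- a1 == "0" | a2 == "0"
    nm <- nMarkers(panel)
    minor <- rep(NA_character_, nm)
    maf <- rep(NA_real_, nm)
    nCalled <- integer(nm)
    mknames <- panelMarkers(panel)$name
    for (j in seq_len(nm)) {
        ok <- !miss[j, ]
        nCalled[j] <- sum(ok)
        if (!nCalled[j]) next
        counts <- table(c(a1[j, ok], a2[j, ok]))
        if (length(counts) > 2)
            stop(sprintf("marker '%s' has %d distinct alleles (at most 2 supported)",
                         mknames[j], length(counts)))
        if (length(counts) == 1) { maf[j] <- 0; next }
        # tie at 0.5: lexicographically smaller token is the minor allele
        ord <- order(counts, names(counts))
        minor[j] <- names(counts)[ord[1]]
        maf[j] <- counts[ord[1]] / (2 * nCalled[j])
    }
    if (any(nCalled == 0) && nm)
        warning(sprintf("%d marker(s) with no called genotypes: MAF undefined, excluded from rare selection",
                        sum(nCalled == 0)))
    data.frame(marker = seq_len(nm), name = mknames, minorAllele = minor,
               maf = maf, nCalled = nCalled)
}

#' Select rare markers under a MAF cutoff
#'
#' Polymorphic markers with \code{0 < maf <= cutoff}. Monomorphic markers are
#' excluded: with no minor allele present there is nothing to carry.
#'
#' @param mafs data.frame from [computeMaf()].
#' @param cutoff MAF cutoff in (0, 0.5]; the conventional low-frequency/rare
#'   threshold is 0.05.
#' @return integer vector of rare marker indices.
#' @export
selectRare <- function(mafs, cutoff = 0.05) {
    stopifnot(cutoff > 0, cutoff <= 0.5)
    which(!is.na(mafs$maf) & mafs$maf > 0 & mafs$maf <= cutoff)
}

#' Collapse a region's rare variants into carrier status
#'
#' An individual is a carrier if at least one minor allele is observed at at
#' least one rare marker of the region — homozygous-minor genotypes count
#' once; carrier status is presence/absence, not an allele count. Individuals
#' whose genotypes are missing at every rare marker, and individuals with a
#' missing phenotype, are marked missing. Individuals called at some rare
#' markers (all major) but missing at others are counted as non-carriers by
#' default (an optimistic call that keeps most of a GWAS panel in the
#' analysis); \code{strictMissing = TRUE} excludes them instead.
#'
#' A region with no rare markers yields all-phenotyped-non-carrier status, so
#' downstream tables have empty carrier cells, chi-squared 0 and p 1.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param rareIdx integer indices of the region's rare markers (from
#'   [selectRare()] intersected with the region's members).
#' @param mafs data.frame from [computeMaf()].
#' @param strictMissing exclude individuals with any missing rare genotype
#'   (unless a minor allele was already observed).
#' @return integer vector per individual: 1 = carrier, 0 = non-carrier,
#'   \code{NA} = missing.
#' @export
collapseRegion <- function(panel, rareIdx, mafs, strictMissing = FALSE) {
    n <- nIndividuals(panel)
    ph <- phenotypes(panel)
    carrier <- rep(0L, n)
    if (length(rareIdx)) {
        a1 <- SummarizedExperiment::assay(panel, "allele1")[rareIdx, , drop = FALSE]
        a2 <- SummarizedExperiment::assay(panel, "allele2")[rareIdx, , drop = FALSE]
        minor <- mafs$minorAllele[rareIdx]
        miss <- a1 == "0" | a2 == "0"
        hasMinor <- (!miss) & (a1 == minor | a2 == minor)
        anyMinor <- colSums(hasMinor) > 0
        allMissing <- colSums(!miss) == 0
        anyMissing <- colSums(miss) > 0
        carrier[anyMinor] <- 1L
        carrier[!anyMinor & allMissing] <- NA_integer_
        if (strictMissing)
            carrier[!anyMinor & anyMissing] <- NA_integer_
    }
    carrier[is.na(ph)] <- NA_integer_
    carrier
}
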