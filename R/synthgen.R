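# Synthetic fixture generator: Hardy-Weinberg genotypes with a controlled
# MAF spectrum, phenotypes with planted carrier effects, and writers that
# round-trip through the MAP/PED readers. Markers are simulated without LD:
# the collapsing statistics operate on carrier status only, so independent
# markers exercise every code path.

#' Simulate a genotype panel under Hardy-Weinberg proportions
#'
#' Each marker is biallelic with the requested minor allele frequency;
#' alleles are drawn independently (random mating), so genotype proportions
#' are p^2 / 2p(1-p) / (1-p)^2. Missingness is applied per genotype,
#' independently, at the stated rate. Phenotypes are left missing; see
#' [genCCPhenotypes()] and [genQTPhenotypes()].
#'
#' @param nIndividuals number of individuals.
#' @param mafs numeric vector of per-marker minor allele frequencies in
#'   [0, 0.5]; its length sets the marker count. A marker with MAF 0 is
#'   monomorphic for the major allele.
#' @param missingRate per-genotype missing probability in [0, 1].
#' @param seed integer seed; generation is fully deterministic given it.
#' @param chrom chromosome label.
#' @param bpStart,bpSpacing positions are \code{bpStart + (0:(M-1)) * bpSpacing}.
#' @param traitMode trait mode stamped on the panel (phenotypes are NA until
#'   a phenotype generator fills them).
#' @return A \linkS4class{GenotypePanel}.
#' @export
genGenotypes <- function(nIndividuals, mafs, missingRate = 0, seed = 1,
                         chrom = "1", bpStart = 100000L, bpSpacing = 5000L,
                         traitMode = c("binary", "quantitative")) {
    traitMode <- match.arg(traitMode)
    stopifnot(all(mafs >= 0), all(mafs <= 0.5),
              missingRate >= 0, missingRate <= 1)
    m <- length(mafs)
    withSeed(seed, {
        pair <- replicate(m, sample(c("A", "C", "G", "T"), 2))
        major <- pair[1, ]; minor <- pair[2, ]
        draw <- function() {
            hit <- matrix(stats::rbinom(m * nIndividuals, 1,
                                        rep(mafs, nIndividuals)),
                          nrow = m)
            matrix(ifelse(hit == 1, minor, major), nrow = m)
        }
        a1 <- draw(); a2 <- draw()
        if (missingRate > 0) {
            miss <- matrix(stats::runif(m * nIndividuals) < missingRate,
                           nrow = m)
            a1[miss] <- "0"; a2[miss] <- "0"
        }
        markers <- data.frame(
            name = sprintf("SNP%d", seq_len(m)), chrom = chrom,
            bp = as.integer(bpStart + (seq_len(m) - 1) * bpSpacing),
            geneticPos = NA_real_)
        ind <- data.frame(
            pedID = as.character(seq_len(nIndividuals)),
            indivID = as.character(seq_len(nIndividuals)),
            fatherID = "0", motherID = "0",
            sex = sample(1:2, nIndividuals, replace = TRUE),
            phenotype = NA_real_)
        genotypePanel(markers, ind, a1, a2, traitMode)
    })
}

# Carrier indicator ignoring phenotype (used before phenotypes exist).
carrierIndicator <- function(panel, rareIdx, mafs) {
    n <- nIndividuals(panel)
    carrier <- rep(0L, n)
    if (!length(rareIdx)) return(carrier)
    a1 <- SummarizedExperiment::assay(panel, "allele1")[rareIdx, , drop = FALSE]
    a2 <- SummarizedExperiment::assay(panel, "allele2")[rareIdx, , drop = FALSE]
    minor <- mafs$minorAllele[rareIdx]
    miss <- a1 == "0" | a2 == "0"
    hasMinor <- (!miss) & (a1 == minor | a2 == minor)
    carrier[colSums(hasMinor) > 0] <- 1L
    carrier[colSums(!miss) == 0 & colSums(hasMinor) == 0] <- NA_integer_
    carrier
}

simCarrier <- function(panel, region, mafCutoff) {
    mafs <- computeMaf(panel, group = "all")
    rare <- selectRare(mafs, mafCutoff)
    if (!is.null(region))
        rare <- intersect(assignMarkers(panelMarkers(panel), region)[[1]],
                          rare)
    carrierIndicator(panel, rare, mafs)
}

#' Plant a binary phenotype with a carrier odds ratio
#'
#' Affection status is sampled from a logistic model on the region's carrier
#' indicator: logit P(case) = alpha + log(oddsRatio) * carrier, with alpha
#' solved so the expected case fraction matches \code{caseFraction}. An odds
#' ratio of 1 makes labels independent of genotype (the null).
#'
#' @param panel a \linkS4class{GenotypePanel} from [genGenotypes()].
#' @param region optional one-element \code{GRanges} restricting the causal
#'   rare set; NULL uses every rare marker on the panel.
#' @param mafCutoff MAF threshold defining the causal rare set (computed over
#'   all individuals, since no phenotype exists yet).
#' @param oddsRatio carrier odds ratio (1 = null).
#' @param caseFraction expected fraction of cases.
#' @param seed integer seed.
#' @return the panel with a binary phenotype (1 control / 2 case) filled in.
#' @export
genCCPhenotypes <- function(panel, region = NULL, mafCutoff = 0.05,
                            oddsRatio = 1, caseFraction = 0.5, seed = 1) {
    stopifnot(oddsRatio > 0, caseFraction > 0, caseFraction < 1)
    carrier <- simCarrier(panel, region, mafCutoff)
    z <- ifelse(is.na(carrier), 0, carrier)
    beta <- log(oddsRatio)
    alpha <- stats::uniroot(
        function(a) mean(stats::plogis(a + beta * z)) - caseFraction,
        lower = -30, upper = 30)$root
    ph <- withSeed(seed,
        1 + stats::rbinom(length(z), 1, stats::plogis(alpha + beta * z)))
    cd <- SummarizedExperiment::colData(panel)
    cd$phenotype <- as.numeric(ph)
    SummarizedExperiment::colData(panel) <- cd
    S4Vectors::metadata(panel)$traitMode <- "binary"
    panel
}

#' Plant a quantitative trait with a carrier mean shift
#'
#' trait = delta * carrier + Normal(0, sigma) noise.
#'
#' @inheritParams genCCPhenotypes
#' @param delta carrier mean shift in trait units (0 = null).
#' @param sigma residual standard deviation (> 0).
#' @return the panel with a quantitative phenotype filled in.
#' @export
genQTPhenotypes <- function(panel, region = NULL, mafCutoff = 0.05,
                            delta = 0, sigma = 1, seed = 1) {
    stopifnot(sigma > 0)
    carrier <- simCarrier(panel, region, mafCutoff)
    z <- ifelse(is.na(carrier), 0, carrier)
    tr <- withSeed(seed, delta * z + stats::rnorm(length(z), 0, sigma))
    cd <- SummarizedExperiment::colData(panel)
    cd$phenotype <- tr
    SummarizedExperiment::colData(panel) <- cd
    S4Vectors::metadata(panel)$traitMode <- "quantitative"
    panel
}

#' Write a panel as MAP + PED (+ gene) fixture files
#'
#' Emits files that round-trip through [readMap()] and [readPed()]. Binary
#' phenotypes write their missing sentinel as \code{"0"}, quantitative as
#' \code{"-9"}; quantitative values are written with full precision so the
#' round trip is exact.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param dir output directory (created if needed).
#' @param stem file stem; writes \code{<stem>.map} and \code{<stem>.ped}.
#' @param mapColumns 3 or 4 (PLINK-style adds a genetic-position column,
#'   0 when the panel has none).
#' @param genes optional gene data.frame (as [readGeneFile()] returns)
#'   written to \code{<stem>_genes.txt}.
#' @return named character vector of the written paths.
#' @export
writeFixture <- function(panel, dir, stem = "chr1", mapColumns = 3,
                         genes = NULL) {
    stopifnot(mapColumns %in% c(3, 4))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    mk <- panelMarkers(panel)
    mapPath <- file.path(dir, paste0(stem, ".map"))
    gp <- ifelse(is.na(mk$geneticPos), "0",
                 sprintf("%.17g", mk$geneticPos))
    lines <- if (mapColumns == 3)
        sprintf("%s %s %d", mk$chrom, mk$name, mk$bp)
    else
        sprintf("%s %s %s %d", mk$chrom, mk$name, gp, mk$bp)
    writeLines(lines, mapPath)

    pedPath <- file.path(dir, paste0(stem, ".ped"))
    ind <- panelIndividuals(panel)
    ph <- phenotypes(panel)
    phTok <- if (traitMode(panel) == "binary")
        ifelse(is.na(ph), "0", sprintf("%d", as.integer(ph)))
    else ifelse(is.na(ph), "-9", sprintf("%.17g", ph))
    a1 <- SummarizedExperiment::assay(panel, "allele1")
    a2 <- SummarizedExperiment::assay(panel, "allele2")
    geno <- vapply(seq_len(ncol(a1)), function(i)
        paste(rbind(a1[, i], a2[, i]), collapse = " "), character(1))
    lead <- sprintf("%s %s %s %s %d %s", ind$pedID, ind$indivID,
                    ind$fatherID, ind$motherID, ind$sex, phTok)
    writeLines(if (nrow(a1)) paste(lead, geno) else lead, pedPath)

    out <- c(map = mapPath, ped = pedPath)
    if (!is.null(genes)) {
        gPath <- file.path(dir, paste0(stem, "_genes.txt"))
        writeLines(sprintf("%s %s %s %d %d", genes$geneID, genes$geneName,
                           genes$chrom, genes$startBp, genes$stopBp), gPath)
        out <- c(out, genes = gPath)
    }
    out
}

#' Simulate a ready-to-analyse study directory
#'
#' Convenience wrapper: draws a panel, plants the requested effect in the
#' first gene's region, and writes MAP/PED/gene files an end-to-end run can
#' consume.
#'
#' @param dir output directory.
#' @param nIndividuals,nMarkers panel dimensions.
#' @param mafRange minor allele frequencies are drawn uniformly from this
#'   range.
#' @param effect \code{"none"}, \code{"cc"} (carrier odds ratio) or
#'   \code{"qt"} (carrier mean shift).
#' @param oddsRatio,caseFraction binary-effect parameters.
#' @param delta,sigma quantitative-effect parameters.
#' @param missingRate per-genotype missing probability.
#' @param nGenes number of (tiled, non-overlapping) gene records to emit.
#' @param seed integer seed.
#' @param chrom chromosome label.
#' @return named character vector of written paths.
#' @export
simulateStudy <- function(dir, nIndividuals = 500, nMarkers = 50,
                          mafRange = c(0.005, 0.3),
                          effect = c("none", "cc", "qt"), oddsRatio = 2,
                          caseFraction = 0.5, delta = 0.5, sigma = 1,
                          missingRate = 0.01, nGenes = 5, seed = 1,
                          chrom = "1") {
    effect <- match.arg(effect)
    mafs <- withSeed(seed,
                     stats::runif(nMarkers, mafRange[1], mafRange[2]))
    panel <- genGenotypes(nIndividuals, mafs, missingRate = missingRate,
                          seed = seed + 1, chrom = chrom,
                          traitMode = if (effect == "qt") "quantitative"
                                      else "binary")
    mk <- panelMarkers(panel)
    span <- range(mk$bp)
    bounds <- round(seq(span[1], span[2] + 1, length.out = nGenes + 1))
    genes <- data.frame(
        geneID = as.character(1000 + seq_len(nGenes)),
        geneName = sprintf("GENE%d", seq_len(nGenes)), chrom = chrom,
        startBp = as.integer(bounds[-(nGenes + 1)]),
        stopBp = as.integer(bounds[-1] - 1))
    causal <- buildGeneRegions(genes[1, , drop = FALSE])
    panel <- switch(effect,
        none = genCCPhenotypes(panel, oddsRatio = 1,
                               caseFraction = caseFraction, seed = seed + 2),
        cc = genCCPhenotypes(panel, region = causal, oddsRatio = oddsRatio,
                             caseFraction = caseFraction, seed = seed + 2),
        qt = genQTPhenotypes(panel, region = causal, delta = delta,
                             sigma = sigma, seed = seed + 2))
    writeFixture(panel, dir, stem = paste0("chr", chrom), genes = genes)
}
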