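# Fixtures are built in code at test time: the marker map / pedigree / gene
# tables used by the format tests, a toy-panel builder with explicit
# genotypes, and independent brute-force oracles for the statistics.

writeLinesTmp <- function(lines) {
    f <- tempfile()
    writeLines(lines, f)
    f
}

map3Fixture <- function() writeLinesTmp(c(
    "1 SNP1 1111", "1 SNP2 2111", "1 SNP3 3111", "1 SNP4 4111"))

map4Fixture <- function() writeLinesTmp(c(
    "1 SNP1 0 1111", "1 SNP2 1 2111", "1 SNP3 2 3111", "1 SNP4 3 4111"))

# four individuals, three markers
pedFixture <- function() writeLinesTmp(c(
    "1 1 0 0 1 1 A A A C T G",
    "2 2 0 0 2 1 A G A A G G",
    "3 3 0 0 2 2 G G C C T T",
    "4 4 0 0 1 2 A G A C T G"))

geneFixture <- function() writeLinesTmp(c(
    "7293 TNFRSF4 1 1136569 1139375",
    "51150 SDF4 1 1142151 1157274",
    "126792 B3GALT6 1 1157508 1160281"))

# Build a panel directly from a genotype string matrix: one row per marker,
# entries like "AA", "AG", "00" (missing), "0A" (half-missing).
toyPanel <- function(genoRows, phenotype, traitMode = "binary",
                     bp = NULL, chrom = "1") {
    g <- do.call(rbind, lapply(genoRows, function(r) unlist(strsplit(r, " "))))
    m <- nrow(g); n <- ncol(g)
    a1 <- substr(g, 1, 1); dim(a1) <- dim(g)
    a2 <- substr(g, 2, 2); dim(a2) <- dim(g)
    if (is.null(bp)) bp <- seq_len(m) * 1000L
    markers <- data.frame(name = sprintf("M%d", seq_len(m)), chrom = chrom,
                          bp = as.integer(bp), geneticPos = NA_real_)
    ind <- data.frame(pedID = as.character(seq_len(n)),
                      indivID = as.character(seq_len(n)),
                      fatherID = "0", motherID = "0", sex = 1L,
                      phenotype = phenotype)
    genotypePanel(markers, ind, a1, a2, traitMode)
}

regionOf <- function(start, end, chrom = "1", name = "R") {
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start = start, end = end))
    S4Vectors::mcols(gr)$name <- name
    gr
}

# --- independent oracles ------------------------------------------------

# Closed-form Pearson statistic for a 2x2 table.
oracleChi2 <- function(a, b, c, d) {
    a <- as.numeric(a); b <- as.numeric(b)
    c <- as.numeric(c); d <- as.numeric(d)
    n <- a + b + c + d
    den <- (a + b) * (c + d) * (a + c) * (b + d)
    if (den == 0) return(0)
    n * (a * d - b * c)^2 / den
}

# Two-sided Fisher p by full enumeration over all tables with the observed
# margins, summing hypergeometric probabilities <= that of the observed
# table (with a small relative tolerance for float ties).
oracleFisher <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    ks <- max(0, c1 - (n - r1)):min(r1, c1)
    probs <- dhyper(ks, r1, n - r1, c1)
    pObs <- dhyper(a, r1, n - r1, c1)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Per-individual brute-force carrier scan over the rare genotypes.
oracleCarrier <- function(panel, rareIdx, mafs, strictMissing = FALSE) {
    ph <- phenotypes(panel)
    a1 <- SummarizedExperiment::assay(panel, "allele1")
    a2 <- SummarizedExperiment::assay(panel, "allele2")
    out <- integer(nIndividuals(panel))
    for (i in seq_len(nIndividuals(panel))) {
        if (is.na(ph[i])) { out[i] <- NA_integer_; next }
        seen <- FALSE; nCalled <- 0L; nMiss <- 0L
        for (j in rareIdx) {
            al <- c(a1[j, i], a2[j, i])
            if (any(al == "0")) { nMiss <- nMiss + 1L; next }
            nCalled <- nCalled + 1L
            if (mafs$minorAllele[j] %in% al) seen <- TRUE
        }
        out[i] <- if (seen) 1L
                  else if (length(rareIdx) && nCalled == 0L) NA_integer_
                  else if (strictMissing && nMiss > 0L) NA_integer_
                  else 0L
    }
    out
}

# Closed-form two-group OLS of y on a 0/1 indicator.
oracleTwoGroupOLS <- function(y1, y0) {
    n1 <- length(y1); n0 <- length(y0); n <- n1 + n0
    beta <- mean(y1) - mean(y0)
    rss <- sum((y1 - mean(y1))^2) + sum((y0 - mean(y0))^2)
    s2 <- rss / (n - 2)
    se <- sqrt(s2 * (1 / n1 + 1 / n0))
    t <- beta / se
    list(beta = beta, se = se, t = t,
         p = 2 * pt(abs(t), n - 2, lower.tail = FALSE))
}
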