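test_that("map reader auto-detects the 3- and 4-column dialects", {
    m3 <- readMap(map3Fixture())
    expect_equal(m3$name, c("SNP1", "SNP2", "SNP3", "SNP4"))
    expect_equal(m3$chrom, rep("1", 4))
    expect_equal(m3$bp, c(1111L, 2111L, 3111L, 4111L))
    expect_true(all(is.na(m3$geneticPos)))

    m4 <- readMap(map4Fixture())
    expect_equal(m4$bp, c(1111L, 2111L, 3111L, 4111L))
    expect_equal(m4$geneticPos, c(0, 1, 2, 3))
    expect_equal(m4[, c("name", "chrom", "bp")], m3[, c("name", "chrom", "bp")])

    expect_equal(nrow(readMap(writeLinesTmp(character()))), 0)
})

test_that("map reader rejects malformed files with informative errors", {
    expect_error(readMap(writeLinesTmp(c("1 SNP1 1111", "1 SNP2 1 2111"))),
                 "mixed")
    expect_error(readMap(writeLinesTmp("1 SNP1 11x1")), "line 1.*non-integer")
    expect_error(readMap(writeLinesTmp("1 SNP1")), "line 1")
    expect_error(readMap(writeLinesTmp(c("1 SNP1 1111", "2 SNP2 2111"))),
                 "chromosome")
})

test_that("pedigree reader parses genotypes, sexes and binary phenotypes", {
    markers <- readMap(writeLinesTmp(c("1 M1 100", "1 M2 200", "1 M3 300")))
    p <- readPed(pedFixture(), markers, "binary")
    expect_s4_class(p, "GenotypePanel")
    expect_equal(nIndividuals(p), 4)
    expect_equal(nMarkers(p), 3)
    ind <- panelIndividuals(p)
    expect_equal(ind$indivID, as.character(1:4))
    expect_equal(ind$sex, c(1L, 2L, 2L, 1L))
    expect_equal(phenotypes(p), c(1, 1, 2, 2))
    a1 <- SummarizedExperiment::assay(p, "allele1")
    a2 <- SummarizedExperiment::assay(p, "allele2")
    expect_equal(unname(a1[, 1]), c("A", "A", "T"))
    expect_equal(unname(a2[, 1]), c("A", "C", "G"))
    expect_equal(unname(a1[, 3]), c("G", "C", "T"))
})

test_that("phenotype sentinels and mode-specific parsing behave", {
    markers <- readMap(writeLinesTmp("1 M1 100"))
    # binary: both 0 and -9 missing by default
    p <- readPed(writeLinesTmp(c("1 1 0 0 1 0 A A", "2 2 0 0 1 -9 A G",
                                 "3 3 0 0 1 2 G G")), markers, "binary")
    expect_equal(phenotypes(p), c(NA, NA, 2))
    # quantitative: 0 is a legal trait value, only -9 missing
    q <- readPed(writeLinesTmp(c("1 1 0 0 1 0 A A", "2 2 0 0 1 -9 A G",
                                 "3 3 0 0 1 1.25 G G")),
                 markers, "quantitative")
    expect_equal(phenotypes(q), c(0, NA, 1.25))
    expect_error(readPed(writeLinesTmp("1 1 0 0 1 abc A A"), markers,
                         "quantitative"), "non-numeric trait")
    expect_error(readPed(writeLinesTmp("1 1 0 0 1 3 A A"), markers,
                         "binary"), "affection status")
    # genotype column count must match the map
    expect_error(readPed(pedFixture(), readMap(map3Fixture()), "binary"),
                 "genotype fields")
})

test_that("half-missing genotypes are treated as fully missing", {
    markers <- readMap(writeLinesTmp("1 M1 100"))
    p <- readPed(writeLinesTmp(c("1 1 0 0 1 2 0 A", "2 2 0 0 1 1 A G")),
                 markers, "binary")
    expect_equal(unname(missingGenotypes(p)[1, ]), c(TRUE, FALSE))
    mafs <- computeMaf(p)
    expect_equal(mafs$nCalled, 1L)
})

test_that("gene file reader returns records in order and checks spans", {
    g <- readGeneFile(geneFixture())
    expect_equal(g$geneName, c("TNFRSF4", "SDF4", "B3GALT6"))
    expect_equal(g$geneID[1], "7293")
    expect_equal(g$startBp, c(1136569L, 1142151L, 1157508L))
    expect_equal(g$stopBp[2], 1157274L)
    expect_error(readGeneFile(writeLinesTmp("1 BAD 1 500 100")),
                 "'BAD' has start 500 > stop 100")
})

test_that("fixture writer round-trips through the readers", {
    p <- genGenotypes(30, c(0.05, 0.2, 0.4), missingRate = 0.1, seed = 11)
    p <- genQTPhenotypes(p, delta = 0.5, seed = 12)
    d <- tempfile()
    for (cols in c(3, 4)) {
        paths <- writeFixture(p, d, stem = paste0("c", cols),
                              mapColumns = cols)
        mk <- readMap(paths[["map"]])
        q <- readPed(paths[["ped"]], mk, "quantitative")
        expect_equal(panelMarkers(q)[, c("name", "chrom", "bp")],
                     panelMarkers(p)[, c("name", "chrom", "bp")])
        expect_equal(panelIndividuals(q), panelIndividuals(p))
        expect_equal(SummarizedExperiment::assay(q, "allele1"),
                     SummarizedExperiment::assay(p, "allele1"))
        expect_equal(SummarizedExperiment::assay(q, "allele2"),
                     SummarizedExperiment::assay(p, "allele2"))
    }
})

test_that("case-control writers: SNP counts, sentinel, threshold filtering", {
    p <- genGenotypes(300, c(0.02, 0.3, 0.02, 0.01), seed = 21)
    p <- genCCPhenotypes(p, oddsRatio = 6, caseFraction = 0.5, seed = 22)
    regions <- buildSlidingWindows(panelMarkers(p), 20000, 20000)
    res <- analyzeCC(p, regions, minCell = 30)
    d <- tempfile(); dir.create(d)
    sumPath <- file.path(d, "sum.txt"); chrPath <- file.path(d, "chr.txt")
    writeCCSummary(res, sumPath, sigThreshold = 0.5, minCell = 30)
    writeCCChromosome(res, chrPath, minCell = 30)
    sumTab <- read.delim(sumPath, check.names = FALSE)
    chrTab <- read.delim(chrPath, check.names = FALSE)
    # chromosome file carries every region; summary only p <= threshold
    expect_equal(nrow(chrTab), nrow(res))
    expect_setequal(sumTab[["Gene/Wind"]],
                    res$region[!is.na(res$pPearson) & res$pPearson <= 0.5])
    expect_true(all(sumTab[["Gene/Wind"]] %in% chrTab[["Gene/Wind"]]))
    # "(total/rare)" column
    expect_equal(chrTab$N_SNPs,
                 sprintf("(%d/%d)", res$nSNPs, res$nRare))
    # margins: carriers + non-carriers = phenotyped individuals with
    # callable carrier status
    expect_equal(chrTab$CaseRV + chrTab$CaseNoRV, res$caseRV + res$caseNoRV)
    # Fisher sentinel appears exactly where the min-cell rule skipped
    expect_equal(grepl("^No < 30$", chrTab$FisherExPval),
                 res$fisherSkipped)
    # empty results give a header-only file
    writeCCSummary(res[0, ], sumPath, 0.5)
    expect_equal(length(readLines(sumPath)), 1)
})

test_that("quantitative writers format CI fields and keep degenerate rows", {
    res <- data.frame(region = c("A", "B"), chrom = "1", start = 1L,
                      end = 10L, nSNPs = c(3L, 2L), nRare = c(1L, 0L),
                      nCarrier = c(10L, 0L), nNonCarrier = c(90L, 100L),
                      meanCarrier = c(0.5, NA), meanNonCarrier = c(0.1, 0.2),
                      pReg = c(0.001, 1), beta = c(0.404, NA),
                      se = c(0.101, NA), ciLow = c(0.206, NA),
                      ciHigh = c(0.602, NA), tStat = c(-3.975, NA),
                      pT = c(3.72e-5, 1), undefined = c(FALSE, TRUE))
    d <- tempfile(); dir.create(d)
    writeQTChromosome(res, file.path(d, "chr.txt"))
    lines <- readLines(file.path(d, "chr.txt"))
    expect_length(lines, 3)
    expect_match(lines[2], "\\[0\\.206 - 0\\.602\\]", all = FALSE)
    expect_match(lines[2], "3\\.72E-05")
    # degenerate region emitted with empty statistics and p = 1
    fB <- strsplit(lines[3], "\t")[[1]]
    expect_equal(fB[6:7], c("0", "100"))
    expect_equal(fB[10], "1")
    expect_equal(fB[11], "")
    # summary keeps exactly the single row at/below threshold
    writeQTSummary(res, file.path(d, "sum.txt"), sigThreshold = 0.01)
    expect_equal(length(readLines(file.path(d, "sum.txt"))), 2)
})

test_that("region SNP list reports all member markers with their MAF", {
    p <- toyPanel(c("AA AG GG AG", "AA AA AA AG", "CC CC CC CT"),
                  phenotype = c(1, 1, 2, 2))
    mafs <- computeMaf(p)
    path <- tempfile()
    writeRegionSnplist(panelMarkers(p), c(1L, 2L, 3L), mafs, path)
    tab <- read.delim(path, check.names = FALSE)
    expect_equal(nrow(tab), 3)       # common markers listed too
    expect_equal(tab$Marker, c("M1", "M2", "M3"))
    expect_equal(tab$MAF, c(0.5, 0.125, 0.125))
    writeRegionSnplist(panelMarkers(p), integer(), mafs, path)
    expect_equal(length(readLines(path)), 1)
})

test_that("p-value and permutation formatting match the reporting style", {
    expect_equal(formatPval(c(0.0000594, 0.12, 1, NA)),
                 c("5.94E-05", "0.12", "1", ""))
    expect_equal(formatPerm(c(1, 0), c(10, 10)),
                 c("Perm: 1/10 = 0.1", "Perm: 0/10 = 0"))
})
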