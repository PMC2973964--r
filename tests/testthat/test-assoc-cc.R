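test_that("Pearson chi-squared is uncorrected and handles degeneracy", {
    r <- pearsonChi2(c(26, 1877, 7, 2906))
    expect_equal(round(r$chi2, 2), 21.44)
    expect_equal(r$p, 3.64e-6, tolerance = 1e-3)
    expect_equal(round(pearsonChi2(c(2, 1909, 31, 2903))$chi2, 1), 15.5)
    # identical proportions
    expect_equal(pearsonChi2(c(10, 90, 10, 90)), list(chi2 = 0, p = 1))
    # zero margins: the empty-region convention
    expect_equal(pearsonChi2(c(0, 1924, 0, 2938)), list(chi2 = 0, p = 1))
    expect_equal(pearsonChi2(c(0, 0, 0, 0)), list(chi2 = 0, p = 1))
})

test_that("chi-squared matches the closed form and its symmetries", {
    withr::with_seed(11, {
        tabs <- matrix(rpois(4 * 500, lambda = 25), ncol = 4)
        for (i in seq_len(nrow(tabs))) {
            tb <- tabs[i, ]
            got <- pearsonChi2(tb)$chi2
            expect_equal(got, oracleChi2(tb[1], tb[2], tb[3], tb[4]))
            # invariant under swapping rows and swapping columns
            expect_equal(pearsonChi2(tb[c(3, 4, 1, 2)])$chi2, got)
            expect_equal(pearsonChi2(tb[c(2, 1, 4, 3)])$chi2, got)
        }
    })
})

test_that("Fisher's exact p matches full enumeration on small margins", {
    expect_equal(fisherExact(c(1, 1921, 7, 2926)), 0.158, tolerance = 5e-3)
    expect_equal(fisherExact(c(26, 1877, 7, 2906)), 5.94e-6,
                 tolerance = 5e-3)
    expect_equal(fisherExact(c(0, 0, 5, 5)), 1)
    withr::with_seed(12, {
        for (rep in 1:200) {
            tb <- sample.int(13, 4, replace = TRUE) - 1   # margins <= 48
            expect_equal(fisherExact(tb),
                         oracleFisher(tb[1], tb[2], tb[3], tb[4]),
                         tolerance = 1e-10)
            # transposition invariance
            expect_equal(fisherExact(tb), fisherExact(tb[c(1, 3, 2, 4)]))
        }
    })
})

test_that("the minimum-cell rule fires on observed counts", {
    expect_false(minCellRule(c(62, 1859, 44, 2885), 30))  # min cell 44
    expect_true(minCellRule(c(26, 1877, 7, 2906), 30))    # min cell 7
    expect_false(minCellRule(c(1, 2, 3, 4), 0))           # nothing below 0
    expect_true(minCellRule(c(29, 100, 100, 100), 30))
    expect_error(minCellRule(c(1, 1, 1, 1), -1))
})

test_that("permutation bookkeeping: exceedances over replicates, no pseudocount", {
    carrier <- c(rep(1L, 10), rep(0L, 90))
    pheno <- rep(c(2, 1), 50)
    pm <- permuteEmpiricalP(carrier, pheno, 10, seed = 3)
    expect_equal(pm$pEmp, pm$nExceed / 10)
    # a null table is exceeded by every replicate
    nullP <- permuteEmpiricalP(rep(0L, 100), pheno, 10, seed = 3)
    expect_equal(nullP$pEmp, 1)
    expect_error(permuteEmpiricalP(carrier, pheno, 0, seed = 1), "nPerm")
})

test_that("permutation draws match an explicit label-shuffle oracle", {
    withr::with_seed(5, {
        carrier <- rbinom(300, 1, 0.15)
        pheno <- sample(rep(c(1, 2), c(180, 120)))
        got <- permuteEmpiricalP(carrier, pheno, 4000, seed = 99)
        obs <- pearsonChi2(carrierTable(carrier, pheno))$chi2
        # independent oracle: literally permute the labels
        exceed <- 0L
        for (b in 1:4000) {
            sh <- sample(pheno)
            if (pearsonChi2(carrierTable(carrier, sh))$chi2 >= obs - 1e-12)
                exceed <- exceed + 1L
        }
        se <- sqrt(got$pEmp * (1 - got$pEmp) / 4000 * 2)
        expect_lt(abs(got$pEmp - exceed / 4000), max(4 * se, 0.02))
    })
})

test_that("empirical p matches the exact permutation-null distribution", {
    withr::with_seed(8, {
        carrier <- rbinom(2000, 1, 0.05)
        pheno <- sample(rep(c(1, 2), 1000))
        tab <- carrierTable(carrier, pheno)
        obs <- pearsonChi2(tab)$chi2
        got <- permuteEmpiricalP(carrier, pheno, 2000, seed = 17)
        # exact law of the permuted table: hypergeometric over the
        # case-carrier cell with the observed margins
        nCase <- tab[["caseRV"]] + tab[["caseNoRV"]]
        nRV <- tab[["caseRV"]] + tab[["contRV"]]
        nTot <- sum(tab)
        ks <- max(0, nCase + nRV - nTot):min(nCase, nRV)
        stat <- vapply(ks, function(a)
            oracleChi2(a, nCase - a, nRV - a, nTot - nCase - nRV + a),
            numeric(1))
        exact <- sum(dhyper(ks, nRV, nTot - nRV, nCase)[stat >= obs - 1e-12])
        se <- sqrt(exact * (1 - exact) / 2000)
        expect_lt(abs(got$pEmp - exact), 4 * se)
        # and it tracks the asymptotic p up to discreteness
        expect_lt(abs(got$pEmp - pearsonChi2(tab)$p), 0.1)
    })
})

test_that("per-region streams are reproducible and order-independent", {
    carrier <- c(rep(1L, 15), rep(0L, 185))
    pheno <- rep(c(2, 1), 100)
    s1 <- permuteEmpiricalP(carrier, pheno, 50, seed = 7)
    s2 <- permuteEmpiricalP(carrier, pheno, 50, seed = 7)
    expect_identical(s1, s2)
    # per-region results do not depend on region processing order
    p <- genGenotypes(250, c(0.03, 0.25, 0.02, 0.04), seed = 91)
    p <- genCCPhenotypes(p, oddsRatio = 4, seed = 92)
    r1 <- regionOf(90000, 105000, name = "LEFT")
    r2 <- regionOf(105001, 200000, name = "RIGHT")
    fwd <- analyzeCC(p, c(r1, r2), nPerm = 200, permTrigger = 1, seed = 6)
    rev <- analyzeCC(p, c(r2, r1), nPerm = 200, permTrigger = 1, seed = 6)
    expect_identical(fwd[order(fwd$region), ]$pEmp,
                     rev[order(rev$region), ]$pEmp)
})

test_that("region analysis composes collapse, tests, gating and permutation", {
    # engineered panel: 1 rare marker, carriers concentrated in cases
    p <- toyPanel(c(paste(c(rep("AG", 6), rep("AA", 44)), collapse = " "),
                    paste(rep(c("CT", "CC"), 25), collapse = " ")),
                  phenotype = c(rep(2, 25), rep(1, 25)))
    mafs <- computeMaf(p)
    region <- regionOf(500, 3000, name = "TOY")
    members <- assignMarkers(panelMarkers(p), region)[[1]]
    rare <- intersect(members, selectRare(mafs, 0.1))
    res <- analyzeRegionCC(p, region, members, rare, mafs,
                           nPerm = 100, permTrigger = 1, seed = 4)
    expect_equal(res$caseRV, 6)
    expect_equal(res$caseRV + res$caseNoRV, 25)
    expect_equal(res$nSNPs, 2)
    expect_equal(res$nRare, 1)
    expect_false(is.na(res$pEmp))
    # permutation gated off for insignificant regions
    res2 <- analyzeRegionCC(p, region, members, rare, mafs,
                            nPerm = 100, permTrigger = 1e-6, seed = 4)
    expect_true(is.na(res2$pEmp))
    # no rare markers: empty-table convention
    res3 <- analyzeRegionCC(p, region, members, integer(), mafs)
    expect_equal(unlist(res3[c("caseRV", "contRV")]), c(caseRV = 0, contRV = 0))
    expect_equal(res3$caseNoRV, 25)
    expect_equal(res3$chi2, 0)
    expect_equal(res3$pPearson, 1)
})

test_that("type-I error of the collapsing test sits at the nominal level", {
    # modest screening version of the null calibration (the acceptance
    # suite runs the full-scale one)
    withr::with_seed(23, {
        rej <- 0L; nSim <- 200
        for (s in 1:nSim) {
            carrier <- rbinom(400, 1, 0.08)
            pheno <- sample(rep(c(1, 2), 200))
            if (pearsonChi2(carrierTable(carrier, pheno))$p <= 0.05)
                rej <- rej + 1L
        }
        expect_lt(abs(rej / nSim - 0.05), 3 * sqrt(0.05 * 0.95 / nSim))
    })
})
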