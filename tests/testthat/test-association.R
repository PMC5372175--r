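test_that("genotype tables tally the fixture groups exactly", {
    calls <- studyVariantGenotypes()
    pat <- genotypeTable(calls[calls$group == "patients", ], "patients")
    expect_equal(c(pat@nNN, pat@nNV, pat@nVV), c(14L, 15L, 8L))
    fam <- genotypeTable(calls[calls$group != "controls", ], "family_cohort")
    expect_equal(c(fam@nNN, fam@nNV, fam@nVV), c(32L, 44L, 30L))
    expect_equal(nSamples(fam), 106L)
    empty <- genotypeTable(character(), "none")
    expect_equal(nSamples(empty), 0L)
    ## MISSING calls are excluded with a message
    expect_message(t2 <- genotypeTable(c("NN", "MISSING", "NV"), "g"),
                   "1 MISSING")
    expect_equal(nSamples(t2), 2L)
    expect_error(genotypeTable(c("NN", "XX"), "g"), "XX")
})

test_that("allele frequencies derive from genotype counts", {
    pat <- GenotypeTable(group = "patients", nNN = 14L, nNV = 15L, nVV = 8L)
    af <- alleleFreqs(pat)
    expect_equal(af[["freqV"]], 31 / 74)
    expect_equal(round(af[["freqV"]], 2), 0.42)
    expect_equal(af[["freqN"]] + af[["freqV"]], 1)
    fam <- GenotypeTable(group = "fam", nNN = 32L, nNV = 44L, nVV = 30L)
    expect_equal(alleleFreqs(fam)[["freqV"]], 104 / 212)
    mono <- GenotypeTable(group = "m", nNN = 9L, nNV = 0L, nVV = 0L)
    expect_equal(alleleFreqs(mono)[["freqV"]], 0)
    empty <- GenotypeTable(group = "e", nNN = 0L, nNV = 0L, nVV = 0L)
    expect_error(alleleFreqs(empty), "empty")
})

test_that("carrier counts are heterozygotes plus homozygotes", {
    pat <- GenotypeTable(group = "patients", nNN = 14L, nNV = 15L, nVV = 8L)
    expect_equal(carrierCount(pat), 23L)
    none <- GenotypeTable(group = "g", nNN = 5L, nNV = 0L, nVV = 0L)
    expect_equal(carrierCount(none), 0L)
    ## carriers never exceed the group size
    set.seed(61)
    for (i in 1:20) {
        x <- GenotypeTable(group = "g", nNN = sample(0:50, 1),
                           nNV = sample(0:50, 1), nVV = sample(0:50, 1))
        expect_lte(carrierCount(x), nSamples(x))
    }
})

test_that("allele count matrices conserve 2n alleles", {
    fam <- GenotypeTable(group = "family_cohort", nNN = 32L, nNV = 44L,
                         nVV = 30L)
    ctl <- GenotypeTable(group = "controls", nNN = 34L, nNV = 50L, nVV = 16L)
    am <- alleleCountMatrix(fam, ctl)
    expect_equal(unname(am[, "family_cohort"]), c(108L, 104L))
    expect_equal(unname(am[, "controls"]), c(118L, 82L))
    expect_equal(unname(colSums(am)), 2L * c(nSamples(fam), nSamples(ctl)))
})

test_that("the Pearson chi-square matches an independent implementation", {
    obs <- matrix(c(32, 34, 44, 50, 30, 16), nrow = 3, byrow = TRUE)
    res <- pearsonChi2(obs)
    expect_equal(res$df, 2L)
    ## cross-check against the stock test without continuity correction
    ref <- suppressWarnings(stats::chisq.test(obs, correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p.value, ref$p.value, tolerance = 1e-12)

    ## identical group distributions: statistic 0, p 1
    flat <- pearsonChi2(matrix(c(10, 10, 10, 10), nrow = 2))
    expect_equal(flat$statistic, 0)
    expect_equal(flat$p.value, 1)

    ## permutation invariance
    perm <- pearsonChi2(obs[c(3, 1, 2), c(2, 1)])
    expect_equal(perm$statistic, res$statistic, tolerance = 1e-12)

    ## random tables against the stock implementation
    set.seed(62)
    for (i in 1:20) {
        m <- matrix(sample(1:60, 6), nrow = sample(c(2L, 3L), 1))
        ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
        got <- pearsonChi2(m)
        expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
        expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
    }

    expect_error(pearsonChi2(matrix(c(0, 0, 5, 5), nrow = 2, byrow = TRUE)),
                 "row margin")
    expect_error(pearsonChi2(matrix(c(0, 0, 5, 5), nrow = 2)),
                 "column margin")
    small <- pearsonChi2(matrix(c(2, 3, 4, 5), nrow = 2))
    expect_true(small$smallExpectedWarning)
})

test_that("upper-tail p-values agree with closed forms", {
    x <- seq(0, 50, by = 0.25)
    ## df = 2: exp(-x/2)
    for (xi in x)
        expect_equal(pearsonChi2FromStat(xi, 2L), exp(-xi / 2),
                     tolerance = 1e-12)
    ## df = 4 and 6: exp(-x/2) * sum_{j<k} (x/2)^j / j!
    series <- function(xi, k) exp(-xi / 2) * sum((xi / 2)^(0:(k - 1)) /
                                                 factorial(0:(k - 1)))
    for (xi in x) {
        expect_equal(pearsonChi2FromStat(xi, 4L), series(xi, 2),
                     tolerance = 1e-10)
        expect_equal(pearsonChi2FromStat(xi, 6L), series(xi, 3),
                     tolerance = 1e-10)
    }
    ## df = 1: 2 * (1 - Phi(sqrt(x)))
    for (xi in x)
        expect_equal(pearsonChi2FromStat(xi, 1L),
                     2 * stats::pnorm(sqrt(xi), lower.tail = FALSE),
                     tolerance = 1e-10)
})

test_that("the Hardy-Weinberg diagnostic is calibrated", {
    ## exact HW proportions give statistic ~ 0
    hw <- GenotypeTable(group = "hw", nNN = 25L, nNV = 50L, nVV = 25L)
    expect_lt(hweTest(hw)$statistic, 1e-10)
    ## gross heterozygote deficit is detected
    bad <- GenotypeTable(group = "bad", nNN = 50L, nNV = 0L, nVV = 50L)
    expect_lt(hweTest(bad)$p.value, 1e-6)
})
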