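test_that("noise-free planted segments are fully homozygous", {
    cfg <- SimConfig(nFamilies = 1L, nMarkers = 1500L, nChroms = 1L,
                     plantedSegmentsPerAffected = 1L,
                     plantedLengthSampler = function(n) rep(2e6, n),
                     hetErrorRate = 0, missingRate = 0,
                     backgroundRohRate = 0, seed = 5L)
    sim <- simulateCohort(cfg)
    tr <- sim$truth[sim$truth$type == "planted_unique"]
    expect_equal(length(tr), 1L)
    mm <- markers(sim$cohort)
    idx <- which(start(mm) >= start(tr) & start(mm) < end(tr))
    g <- calls(sim$cohort)[idx, tr$sampleId]
    expect_true(all(g %in% c(0L, 2L)))
    ## one coin flip per segment: the whole run carries one allele
    expect_equal(length(unique(g)), 1L)
})

test_that("the seed fully determines the simulated cohort", {
    a <- simulateCohort(smallSimConfig(99))
    b <- simulateCohort(smallSimConfig(99))
    expect_identical(calls(a$cohort), calls(b$cohort))
    expect_identical(start(markers(a$cohort)), start(markers(b$cohort)))
    expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
    c <- simulateCohort(smallSimConfig(100))
    expect_false(identical(calls(a$cohort), calls(c$cohort)))
})

test_that("background genotypes follow Hardy-Weinberg proportions", {
    ## at freqB = 0.5 the expected heterozygote fraction is 2pq = 0.5
    cfg <- SimConfig(nFamilies = 10L, nMarkers = 1000L, nChroms = 1L,
                     freqBSampler = function(n) rep(0.5, n),
                     plantedSegmentsPerAffected = 0L,
                     hetErrorRate = 0, missingRate = 0,
                     backgroundRohRate = 0, seed = 17L)
    sim <- simulateCohort(cfg)
    cm <- calls(sim$cohort)
    n <- length(cm)
    se <- sqrt(0.5 * 0.5 / n)
    expect_lt(abs(mean(cm == 1L) - 0.5), 3 * se)

    ## per-marker chi-square goodness of fit against p^2 / 2pq / q^2 at the
    ## marker's own freqB: non-significant at alpha = 0.001 for >= 95%
    cfg2 <- SimConfig(nFamilies = 25L, nMarkers = 400L, nChroms = 1L,
                      plantedSegmentsPerAffected = 0L,
                      hetErrorRate = 0, missingRate = 0,
                      backgroundRohRate = 0, seed = 18L)
    sim2 <- simulateCohort(cfg2)
    cm2 <- calls(sim2$cohort)
    q <- mcols(markers(sim2$cohort))$freqB
    S <- ncol(cm2)
    pvals <- vapply(seq_len(nrow(cm2)), function(i) {
        obs <- tabulate(cm2[i, ] + 1L, 3L)
        exp <- S * c((1 - q[i])^2, 2 * q[i] * (1 - q[i]), q[i]^2)
        stats::pchisq(sum((obs - exp)^2 / exp), df = 2,
                      lower.tail = FALSE)
    }, numeric(1))
    expect_gt(mean(pvals > 0.001), 0.95)
})

test_that("planting respects family structure and bounds", {
    cfg <- SimConfig(nFamilies = 1L, nMarkers = 1500L, nChroms = 1L,
                     plantedSegmentsPerAffected = 0L,
                     hetErrorRate = 0, missingRate = 0,
                     backgroundRohRate = 0, seed = 21L)
    sim <- simulateCohort(cfg)
    cohort <- sim$cohort
    ped <- pedigree(cohort)
    aff <- ped$sampleId[ped$phenotype == "affected"][1]
    fam <- ped$familyId[ped$sampleId == aff]
    iv <- genomicIntervals("chr1", 1000000, 3000000)

    ## empty interval set leaves the cohort unchanged
    expect_identical(calls(plantUniqueSegment(cohort, fam, GRanges())),
                     calls(cohort))

    planted <- plantUniqueSegment(cohort, fam, iv)
    mm <- markers(planted)
    idx <- which(start(mm) >= 1000000 & start(mm) < 3000000)
    expect_true(all(calls(planted)[idx, aff] %in% c(0L, 2L)))
    ## every relative carries at least one heterozygous call inside
    for (s in setdiff(ped$sampleId, aff))
        expect_gte(sum(calls(planted)[idx, s] == 1L, na.rm = TRUE), 1L)

    ## a family without affected members is a hard error
    ped2 <- ped
    ped2$phenotype[ped2$sampleId == aff] <- "unaffected"
    cohort2 <- GenotypeCohort(markers(cohort), ped2, calls(cohort))
    expect_error(plantUniqueSegment(cohort2, fam, iv), "no affected")

    ## a planted segment longer than any chromosome is a hard error
    cfgBig <- SimConfig(nFamilies = 1L, nMarkers = 200L, nChroms = 1L,
                        plantedLengthSampler = function(n) rep(5e9, n),
                        seed = 22L)
    expect_error(simulateCohort(cfgBig), "exceeds chromosome")
})

test_that("segments planted in child only survive the filter; shared ones do not", {
    cfg <- SimConfig(nFamilies = 1L, nMarkers = 2000L, nChroms = 1L,
                     plantedSegmentsPerAffected = 0L,
                     hetErrorRate = 0, missingRate = 0,
                     backgroundRohRate = 0, seed = 31L)
    sim <- simulateCohort(cfg)
    ped <- pedigree(sim$cohort)
    aff <- ped$sampleId[ped$phenotype == "affected"][1]
    fam <- ped$familyId[ped$sampleId == aff]
    mum <- ped$motherId[ped$sampleId == aff]
    ivA <- genomicIntervals("chr1", 1000000, 3000000)
    ivB <- genomicIntervals("chr1", 5000000, 7000000)

    cohort <- plantUniqueSegment(sim$cohort, fam, ivA, aff)   # unique
    cohort <- plantSegment(cohort, aff, ivB)                  # shared:
    cohort <- plantSegment(cohort, mum, ivB)                  # also in mother

    roh <- callRohCohort(cohort)
    uniq <- uniqueRoh(roh, ped)
    expect_gt(bestJaccard(seg(aff, "chr1", 1000000, 3000000), uniq), 0.9)
    hitB <- findOverlapsHalfOpen(ivB, uniq[uniq$sampleId == aff])
    expect_equal(length(hitB), 0L)
})
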