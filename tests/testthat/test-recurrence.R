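test_that("the shared core of five overlapping segments is reported exactly", {
    ## five ROH all covering chr8:110,051,909-110,185,293, each extending
    ## beyond a different side: their intersection is the reported region
    lo <- 110051909; hi <- 110185293
    segs <- c(seg("F4-015",  "chr8", lo - 500000, hi + 10000),
              seg("F6-024",  "chr8", lo - 200000, hi + 300000),
              seg("F7-029",  "chr8", lo,          hi + 150000),
              seg("F9-038",  "chr8", lo - 50000,  hi),
              seg("F40-186", "chr8", lo - 800000, hi + 900000))
    reg <- recurrentRegions(segs, k = 5)
    expect_equal(length(reg), 1L)
    expect_equal(start(reg), lo)
    expect_equal(end(reg), hi)
    expect_equal(reg$supportIndividuals, 5)
    expect_setequal(unlist(reg$supportSamples),
                    c("F4-015", "F6-024", "F7-029", "F9-038", "F40-186"))
    expect_equal(reg$lengthKb, 133L)  # floor((hi - lo) / 1000)
})

test_that("disjoint segments and low k produce no regions; k < 2 errors", {
    segs <- c(seg("s1", "chr1", 100, 200),
              seg("s2", "chr1", 300, 400),
              seg("s3", "chr1", 500, 600))
    expect_equal(length(recurrentRegions(segs, k = 2)), 0L)
    expect_error(recurrentRegions(segs, k = 1), "k must be >= 2")
})

test_that("sweep-line equals the per-basepair coverage oracle", {
    set.seed(77)
    for (i in 1:100) {
        L <- 300L
        nSeg <- sample(5:50, 1)
        k <- sample(2:4, 1)
        df <- randomSegments(nSeg, nSamples = sample(3:8, 1), L = L,
                             minLen = 3L)
        got <- recurrentRegions(segmentsToGRanges(df), k = k)
        want <- bruteForceRegions(df, k, L)
        expect_equal(length(got), length(want), info = paste("instance", i))
        if (length(want)) {
            expect_equal(start(got), vapply(want, `[[`, integer(1), "start"),
                         info = paste("instance", i))
            expect_equal(end(got), vapply(want, `[[`, integer(1), "end"),
                         info = paste("instance", i))
            for (j in seq_along(want))
                expect_equal(sort(unlist(got$supportSamples[j])),
                             want[[j]]$support,
                             info = paste("instance", i, "region", j))
        }
    }
})

test_that("regions for k nest inside regions for k - 1 and ignore input order", {
    set.seed(78)
    df <- randomSegments(40, nSamples = 6, L = 500, minLen = 5L)
    gr <- segmentsToGRanges(df)
    r3 <- recurrentRegions(gr, k = 3)
    r2 <- recurrentRegions(gr, k = 2)
    if (length(r3)) {
        hits <- findOverlapsHalfOpen(r3, r2)
        covered <- vapply(seq_along(r3), function(i) {
            js <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
            any(start(r2)[js] <= start(r3)[i] & end(r2)[js] >= end(r3)[i])
        }, logical(1))
        expect_true(all(covered))
    }
    perm <- sample(length(gr))
    expect_equal(as.data.frame(recurrentRegions(gr[perm], k = 3)),
                 as.data.frame(r3))
})

test_that("overlapping segments of one sample are merged before counting", {
    segs <- c(seg("s1", "chr1", 100, 300),
              seg("s1", "chr1", 250, 500),   # same individual, overlapping
              seg("s2", "chr1", 100, 500))
    reg <- recurrentRegions(segs, k = 2)
    expect_equal(max(reg$supportIndividuals), 2)
})

test_that("kilobase lengths are truncated, not rounded", {
    expect_equal(lengthKb(157813799, 158331136), 517L)
    expect_equal(lengthKb(38790327, 39664219), 873L)   # floor of 873.892
    expect_equal(lengthKb(29687013, 30278521), 591L)
    expect_equal(lengthKb(1000, 1999), 0L)
    gi <- genomicIntervals(c("chr3", "chr2"), c(157813799, 38790327),
                           c(158331136, 39664219))
    expect_equal(lengthKb(gi), c(517L, 873L))
})

test_that("support counting distinguishes individuals from families", {
    ped <- studyPedigree()
    sc <- supportCounts(c("F19-088", "F19-089", "F1-001"), ped)
    expect_equal(sc[["individuals"]], 3L)
    expect_equal(sc[["families"]], 2L)
    expect_equal(supportCounts(character(), ped),
                 c(individuals = 0L, families = 0L))
    expect_error(supportCounts("NOPE-1", ped), "NOPE-1")
    ## pigeonhole: individuals >= families on random support sets
    set.seed(79)
    for (i in 1:10) {
        ids <- sample(ped$sampleId, sample(2:20, 1))
        sc <- supportCounts(ids, ped)
        expect_gte(sc[["individuals"]], sc[["families"]])
    }
})

test_that("family counting treats an affected sibling pair as one family", {
    lo <- 38790327; hi <- 39664219
    ped <- studyPedigree()
    ids <- c("F1-001", "F3-010", "F6-024", "F18-083", "F19-088", "F19-089",
             "F29-133")
    segs <- do.call(c, lapply(ids, function(s) seg(s, "chr2", lo, hi)))
    byInd <- recurrentRegions(segs, k = 7, countBy = "individuals", ped = ped)
    expect_equal(byInd$supportIndividuals, 7)
    expect_equal(byInd$supportFamilies, 6)
    ## requiring 7 distinct families fails: the sibling pair collapses
    byFam <- recurrentRegions(segs, k = 7, countBy = "families", ped = ped)
    expect_equal(length(byFam), 0L)
    expect_equal(
        recurrentRegions(segs, k = 6, countBy = "families",
                         ped = ped)$supportFamilies, 6)
})
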