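test_that("pedigree parsing handles a trio+sibling family and bad input", {
    f <- withr::local_tempfile(fileext = ".ped")
    writeLines(c("FAM1 DAD 0 0 1 1",
                 "FAM1 MUM 0 0 2 1",
                 "FAM1 KID1 DAD MUM 1 2",
                 "FAM1 KID2 DAD MUM 2 1"), f)
    ped <- readPedigree(f)
    expect_equal(nrow(ped), 4L)
    expect_equal(sum(ped$phenotype == "affected"), 1L)
    expect_equal(ped$sampleId, c("DAD", "MUM", "KID1", "KID2"))
    expect_true(is.na(ped$fatherId[1]))
    expect_equal(ped$fatherId[3], "DAD")

    dup <- withr::local_tempfile(fileext = ".ped")
    writeLines(c("FAM1 KID1 0 0 1 2", "FAM1 KID1 0 0 1 2"), dup)
    expect_error(readPedigree(dup), "KID1")

    dangling <- withr::local_tempfile(fileext = ".ped")
    writeLines("FAM1 KID1 GHOST 0 1 2", dangling)
    expect_error(readPedigree(dangling), "GHOST")
})

test_that("pedigree write/read round trip is the identity", {
    ped <- trioPed()
    f <- withr::local_tempfile(fileext = ".ped")
    writePedigree(ped, f)
    expect_equal(readPedigree(f), ped)
})

test_that("the packaged cohort pedigree has the study's composition", {
    ped <- studyPedigree()
    expect_equal(nrow(ped), 106L)
    expect_equal(sum(ped$phenotype == "affected"), 37L)
    expect_equal(length(unique(ped$familyId)), 36L)
    expect_equal(sum(ped$phenotype == "unaffected" &
                     is.na(ped$fatherId)), 36L)  # genotyped parents
    expect_equal(sum(ped$phenotype == "unaffected" &
                     !is.na(ped$fatherId)), 33L) # unaffected siblings
    ## the family with two affected children
    expect_equal(sum(ped$familyId == "F19" & ped$phenotype == "affected"), 2L)
})

test_that("PED/MAP genotypes map to HOM_A/HET/HOM_B/MISSING", {
    mapf <- withr::local_tempfile(fileext = ".map")
    pedf <- withr::local_tempfile(fileext = ".ped")
    writeLines(c("chr1 m1 0 1000", "chr1 m2 0 2000", "chr1 m3 0 3000"), mapf)
    writeLines("FAM1 S1 0 0 1 2 A A A G 0 0", pedf)
    gc <- readGenotypes(pedf, mapf)
    expect_equal(unname(calls(gc)[, "S1"]), c(0L, 1L, NA))
    expect_equal(mcols(markers(gc))$markerId, c("m1", "m2", "m3"))

    bad <- withr::local_tempfile(fileext = ".ped")
    writeLines(c("FAM1 S1 0 0 1 2 A A A G 0 0",
                 "FAM1 S2 0 0 1 2 A C T G 0 0"), bad)
    expect_error(readGenotypes(bad, mapf), "more than 2 alleles")
})

test_that("an unsorted MAP is sorted with a warning", {
    mapf <- withr::local_tempfile(fileext = ".map")
    pedf <- withr::local_tempfile(fileext = ".ped")
    writeLines(c("chr1 m2 0 2000", "chr1 m1 0 1000"), mapf)
    writeLines("FAM1 S1 0 0 1 2 A G A A", pedf)
    expect_warning(gc <- readGenotypes(pedf, mapf), "not sorted")
    expect_equal(mcols(markers(gc))$markerId, c("m1", "m2"))
    ## m1 carried "A A", m2 carried "A G"
    expect_equal(unname(calls(gc)[, "S1"]), c(0L, 1L))
})

test_that("genotype write/read round trip preserves every call", {
    sim <- simulateCohort(smallSimConfig(301))
    pedf <- withr::local_tempfile(fileext = ".ped")
    mapf <- withr::local_tempfile(fileext = ".map")
    writeGenotypes(sim$cohort, pedf, mapf)
    back <- readGenotypes(pedf, mapf)
    expect_identical(unname(calls(back)), unname(calls(sim$cohort)))
    expect_equal(start(markers(back)), start(markers(sim$cohort)))
    expect_equal(pedigree(back), pedigree(sim$cohort))
})

test_that("variant genotypes read from VCF and tabular input", {
    vcf <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3\tS4",
        "chr7\t148106477\t.\tC\tCTTCTG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t./."),
        vcf)
    calls <- readVariantGenotypes(vcf)
    expect_equal(calls$genotype, c("NN", "NV", "VV", "MISSING"))

    multi <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
        "chr7\t148106477\t.\tC\tCTTCTG,CT\t.\tPASS\t.\tGT\t0/1"), multi)
    expect_error(readVariantGenotypes(multi), "multiallelic")

    tab <- studyVariantGenotypes()
    expect_equal(nrow(tab), 206L)
    expect_equal(sum(tab$group == "controls"), 100L)
    expect_equal(sum(tab$group != "controls"), 106L)
})

test_that("interval BED export shifts starts by one and round trips", {
    gi <- genomicIntervals("chr2", 38790327, 39664219)
    f <- withr::local_tempfile(fileext = ".bed")
    writeIntervals(gi, f)
    lines <- readLines(f)
    expect_match(lines[1], "^#")
    expect_equal(lines[2], "chr2\t38790326\t39664219")
    back <- readIntervals(f)
    expect_equal(start(back), start(gi))
    expect_equal(end(back), end(gi))
    expect_equal(lengthBp(back), lengthBp(gi))

    ## empty set: header-only file, empty read-back
    writeIntervals(GRanges(), f)
    expect_equal(length(readLines(f)), 1L)
    expect_equal(length(readIntervals(f)), 0L)

    ## name/score survive the round trip
    mcols(gi)$name <- "S1"
    mcols(gi)$score <- 357
    writeIntervals(gi, f)
    back <- readIntervals(f)
    expect_equal(back$name, "S1")
    expect_equal(back$score, 357)
})
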