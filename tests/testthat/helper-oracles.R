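## Independent brute-force oracles and small generators shared across tests.
## These deliberately re-derive results by direct enumeration, never by
## calling the implementation they check.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
})

## Window oracle: enumerate every window explicitly and apply the
## definition of the sliding-window caller literally.
bruteForceFlags <- function(geno, positions, params) {
    M <- length(geno)
    W <- params@windowMarkers
    isHet <- !is.na(geno) & geno == 1L
    isMiss <- is.na(geno)
    if (M < W) {
        hetAllow <- floor(params@maxHetPerWindow * M / W)
        missAllow <- floor(params@maxMissingPerWindow * M / W)
        return(rep(sum(isHet) <= hetAllow && sum(isMiss) <= missAllow, M))
    }
    pass <- logical(M - W + 1L)
    for (j in seq_along(pass)) {
        win <- j:(j + W - 1L)
        pass[j] <- sum(isHet[win]) <= params@maxHetPerWindow &&
            sum(isMiss[win]) <= params@maxMissingPerWindow
    }
    flags <- logical(M)
    for (i in seq_len(M)) {
        js <- max(1L, i - W + 1L):min(i, length(pass))
        flags[i] <- mean(pass[js]) >= params@hitFraction
    }
    flags
}

## Coverage oracle: per-basepair support computation on a small toy
## chromosome, then maximal constant-support runs with support >= k.
## segments: data.frame(sampleId, start, end) with half-open [start, end)
## on one chromosome of length L.
bruteForceRegions <- function(segments, k, L) {
    supportAt <- vector("list", L)
    for (p in seq_len(L)) {
        cover <- unique(segments$sampleId[segments$start <= p &
                                          p < segments$end])
        supportAt[[p]] <- sort(cover)
    }
    out <- list()
    p <- 1L
    while (p <= L) {
        sup <- supportAt[[p]]
        if (length(sup) < k) { p <- p + 1L; next }
        q <- p
        while (q + 1L <= L && identical(supportAt[[q + 1L]], sup))
            q <- q + 1L
        out[[length(out) + 1L]] <- list(start = p, end = q + 1L,
                                        support = sup)
        p <- q + 1L
    }
    out
}

## Random ROH-like instance on one toy chromosome.
randomSegments <- function(nSeg, nSamples, L, minLen = 5L) {
    starts <- sample.int(L - minLen, nSeg, replace = TRUE)
    lens <- minLen + sample.int(max(1L, L %/% 3L), nSeg, replace = TRUE)
    data.frame(sampleId = paste0("s", sample.int(nSamples, nSeg,
                                                 replace = TRUE)),
               start = starts,
               end = pmin(starts + lens, L + 1L))
}

segmentsToGRanges <- function(df, chrom = "chrT") {
    gr <- GRanges(chrom, IRanges(df$start, df$end))
    mcols(gr)$sampleId <- df$sampleId
    gr
}

## Small standard pedigree: trio plus unaffected sibling.
trioPed <- function(familyId = "FAM1") {
    data.frame(
        familyId = familyId,
        sampleId = paste0(familyId, c("-F", "-M", "-A", "-S")),
        fatherId = c(NA, NA, paste0(familyId, "-F"), paste0(familyId, "-F")),
        motherId = c(NA, NA, paste0(familyId, "-M"), paste0(familyId, "-M")),
        sex = c("male", "female", "male", "female"),
        phenotype = c("unaffected", "unaffected", "affected", "unaffected"),
        stringsAsFactors = FALSE)
}

## One-sample segment GRanges shorthand on a fixed seqlevel universe so
## that segments on different chromosomes combine silently.
.SEG_LEVELS <- c(paste0("chr", 1:22), "chrT", "chrZ")
seg <- function(sampleId, chrom, start, end) {
    gr <- GRanges(factor(chrom, levels = .SEG_LEVELS),
                  IRanges(start, end))
    mcols(gr)$sampleId <- sampleId
    gr
}

## Deterministic small simulation shared by several tests.
smallSimConfig <- function(seed, ...) {
    SimConfig(nFamilies = 3L, nMarkers = 1500L, nChroms = 2L,
              seed = as.integer(seed), ...)
}

## Best Jaccard overlap of a truth interval among a sample's called runs.
bestJaccard <- function(truthIv, called) {
    mine <- called[called$sampleId == truthIv$sampleId]
    if (!length(mine))
        return(0)
    max(vapply(seq_along(mine), function(j) jaccardBp(truthIv, mine[j]),
               numeric(1)))
}
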