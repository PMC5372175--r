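#' @include AllClasses.R genotype-io.R
NULL

## Draw a random interval of the given length on one simulated chromosome,
## avoiding overlap with intervals already occupied in the same sample.
## Plain-vector arithmetic: this sits in a rejection loop where GRanges
## construction costs would dominate the whole simulation.
.drawInterval <- function(seqlens, len, existing, maxTries = 100L,
                          strict = TRUE) {
    for (i in seq_len(maxTries)) {
        chrom <- sample(names(seqlens), 1L)
        if (len > seqlens[[chrom]])
            stop("planted segment of ", len, " bp exceeds chromosome ",
                 chrom, " (", seqlens[[chrom]], " bp)")
        start <- sample.int(seqlens[[chrom]] - len, 1L)
        end <- start + len
        clash <- !is.null(existing) && nrow(existing) > 0L &&
            any(existing$chrom == chrom & existing$start < end &
                start < existing$end)
        if (!clash)
            return(data.frame(chrom = chrom, start = start, end = end,
                              stringsAsFactors = FALSE))
    }
    if (strict)
        stop("could not place a non-overlapping segment after ", maxTries,
             " attempts")
    NULL
}

.markerIdxRaw <- function(chromOf, pos, chrom, start, end) {
    which(chromOf == chrom & pos >= start & pos < end)
}

.markerIdx <- function(markerMap, interval) {
    stopifnot(length(interval) == 1L)
    .markerIdxRaw(as.character(seqnames(markerMap)), start(markerMap),
                  as.character(seqnames(interval)), start(interval),
                  end(interval))
}

## Make `sampleId` fully homozygous over the marker index set; force up to
## three evenly spaced heterozygous calls in `spoilSamples` so the segment
## cannot be called as ROH in them. Operates on the raw call matrix.
.plantRaw <- function(cm, idx, sampleId, spoilSamples = character()) {
    if (length(idx) == 0L)
        return(cm)
    allele <- if (stats::runif(1) < 0.5) CALL_HOM_A else CALL_HOM_B
    cm[idx, sampleId] <- allele
    if (length(spoilSamples)) {
        at <- unique(round(seq(1L, length(idx),
                               length.out = min(3L, length(idx)))))
        cm[idx[at], spoilSamples] <- CALL_HET
    }
    cm
}

#' Plant a homozygous segment in one sample
#'
#' Overwrites every genotype call of `sampleId` inside the half-open
#' `interval` with the same homozygous state (allele chosen by one coin
#' flip per segment). This is the low-level primitive behind both planted
#' autozygosity in affected children and incidental background ROH.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param sampleId sample to modify.
#' @param interval single half-open `GRanges` interval.
#' @return the modified `GenotypeCohort`.
#' @export
plantSegment <- function(cohort, sampleId, interval) {
    idx <- .markerIdx(markers(cohort), interval)
    cm <- .plantRaw(assay(cohort, "calls"), idx, sampleId)
    SummarizedExperiment::assay(cohort, "calls", withDimnames = FALSE) <- cm
    cohort
}

#' Plant segments unique to an affected child
#'
#' For each interval, makes the designated affected child fully homozygous
#' over the interval and forces every other member of the family to carry
#' heterozygous calls at up to three markers inside it, so the segment
#' cannot be called as ROH in any relative: the planted segment is unique
#' to the affected child by construction. An empty interval set leaves the
#' cohort unchanged. A family without an affected member is a hard error.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param familyId family to modify.
#' @param intervals `GRanges` of half-open intervals (may be empty).
#' @param sampleId affected child receiving the segments; defaults to the
#'   family's first affected member.
#' @return the modified `GenotypeCohort`.
#' @export
plantUniqueSegment <- function(cohort, familyId, intervals, sampleId = NULL) {
    ped <- pedigree(cohort)
    fam <- ped[ped$familyId == familyId, , drop = FALSE]
    if (nrow(fam) == 0L)
        stop("no such family: ", familyId)
    affected <- fam$sampleId[fam$phenotype == "affected"]
    if (length(affected) == 0L)
        stop("family ", familyId, " has no affected member")
    if (is.null(sampleId))
        sampleId <- affected[1L]
    if (!sampleId %in% affected)
        stop("sample ", sampleId, " is not an affected member of ", familyId)
    if (length(intervals) == 0L)
        return(cohort)
    others <- setdiff(fam$sampleId, sampleId)
    cm <- assay(cohort, "calls")
    for (i in seq_along(intervals)) {
        idx <- .markerIdx(markers(cohort), intervals[i])
        cm <- .plantRaw(cm, idx, sampleId, others)
    }
    SummarizedExperiment::assay(cohort, "calls", withDimnames = FALSE) <- cm
    cohort
}

#' Simulate a consanguineous nuclear-family cohort
#'
#' Generates an array-like biallelic marker grid, a cohort of nuclear
#' families (two parents plus children, the configured number affected),
#' Hardy-Weinberg background genotypes, autozygous segments planted in the
#' affected children (unique to them by construction, see
#' [plantUniqueSegment()]), incidental homozygous segments in unaffected
#' members, and genotyping noise (homozygous-to-heterozygous error and
#' missingness). Incidental segments are drawn away from the family's
#' planted intervals, which would otherwise contradict the constructed
#' truth; on a crowded toy genome an incidental segment that cannot be
#' placed is silently skipped. The configuration seed fully determines the
#' output.
#'
#' @param config a [SimConfig-class].
#' @return a list with elements `cohort` (a [GenotypeCohort-class]) and
#'   `truth` (a half-open `GRanges` of planted segments with metadata
#'   columns `sampleId`, `familyId` and `type`, where type
#'   `"planted_unique"` marks autozygosity unique to an affected child and
#'   `"incidental"` background ROH in unaffected members).
#' @examples
#' sim <- simulateCohort(SimConfig(nFamilies = 2L, nMarkers = 500L,
#'                                 nChroms = 1L, seed = 7L))
#' sim$cohort
#' @export
simulateCohort <- function(config = SimConfig()) {
    validObject(config)
    set.seed(config@seed)
    M <- config@nMarkers
    ## marker grid with exponentially jittered spacing
    chroms <- sprintf("chr%d", seq_len(config@nChroms))
    posL <- lapply(chroms, function(ch)
        cumsum(pmax(1, round(stats::rexp(M, 1 / config@markerSpacingBp)))))
    chromOf <- rep(chroms, each = M)
    pos <- unlist(posL)
    seqlens <- stats::setNames(
        vapply(posL, function(p) max(p) + round(config@markerSpacingBp),
               numeric(1)), chroms)
    freqB <- pmin(0.95, pmax(0.05, config@freqBSampler(length(pos))))
    markerMap <- GRanges(factor(chromOf, levels = chroms),
                         IRanges(pos, pos),
                         markerId = sprintf("%s_m%05d", chromOf,
                                            rep(seq_len(M), config@nChroms)),
                         alleleA = "A", alleleB = "B", freqB = freqB)
    GenomeInfoDb::seqlengths(markerMap) <- seqlens

    ## pedigree: two parents + children, first `affectedPerFamily` affected
    fams <- lapply(seq_len(config@nFamilies), function(f) {
        fid <- sprintf("SF%02d", f)
        kids <- seq_len(config@childrenPerFamily)
        data.frame(
            familyId = fid,
            sampleId = c(sprintf("%s-P1", fid), sprintf("%s-P2", fid),
                         sprintf("%s-C%d", fid, kids)),
            fatherId = c(NA, NA, rep(sprintf("%s-P1", fid), length(kids))),
            motherId = c(NA, NA, rep(sprintf("%s-P2", fid), length(kids))),
            sex = c("male", "female",
                    sample(c("male", "female"), length(kids), replace = TRUE)),
            phenotype = c("unaffected", "unaffected",
                          ifelse(kids <= config@affectedPerFamily,
                                 "affected", "unaffected")),
            stringsAsFactors = FALSE)
    })
    ped <- do.call(rbind, fams)
    S <- nrow(ped)

    ## Hardy-Weinberg background, drawn marker-wise at freqB
    p0 <- (1 - freqB)^2          # HOM_A
    p01 <- p0 + 2 * freqB * (1 - freqB)
    U <- matrix(stats::runif(length(pos) * S), nrow = length(pos))
    cm <- (U >= p0) + (U >= p01)
    storage.mode(cm) <- "integer"
    dimnames(cm) <- list(NULL, ped$sampleId)

    ## planted autozygosity in affected children, unique by construction
    truthRows <- list()
    for (sid in ped$sampleId[ped$phenotype == "affected"]) {
        fid <- ped$familyId[ped$sampleId == sid]
        others <- ped$sampleId[ped$familyId == fid & ped$sampleId != sid]
        planted <- NULL
        for (k in seq_len(config@plantedSegmentsPerAffected)) {
            len <- round(config@plantedLengthSampler(1L))
            iv <- .drawInterval(seqlens, len, planted)
            planted <- rbind(planted, iv)
            idx <- .markerIdxRaw(chromOf, pos, iv$chrom, iv$start, iv$end)
            cm <- .plantRaw(cm, idx, sid, others)
            truthRows[[length(truthRows) + 1L]] <-
                cbind(iv, sampleId = sid, familyId = fid,
                      type = "planted_unique")
        }
    }
    truthDf <- if (length(truthRows)) do.call(rbind, truthRows) else NULL

    ## incidental background ROH in unaffected members, drawn away from the
    ## family's planted intervals
    for (sid in ped$sampleId[ped$phenotype == "unaffected"]) {
        fid <- ped$familyId[ped$sampleId == sid]
        mine <- if (is.null(truthDf)) NULL else
            truthDf[truthDf$familyId == fid, c("chrom", "start", "end")]
        nInc <- stats::rpois(1L, config@backgroundRohRate)
        for (k in seq_len(nInc)) {
            len <- round(config@plantedLengthSampler(1L))
            iv <- .drawInterval(seqlens, len, mine, strict = FALSE)
            if (is.null(iv))
                next
            mine <- rbind(mine, iv)
            idx <- .markerIdxRaw(chromOf, pos, iv$chrom, iv$start, iv$end)
            cm <- .plantRaw(cm, idx, sid)
            truthRows[[length(truthRows) + 1L]] <-
                cbind(iv, sampleId = sid, familyId = fid,
                      type = "incidental")
        }
    }

    ## genotyping noise: hom -> HET errors, then missingness
    if (config@hetErrorRate > 0) {
        hom <- which(cm != CALL_HET)
        flip <- hom[stats::runif(length(hom)) < config@hetErrorRate]
        cm[flip] <- CALL_HET
    }
    if (config@missingRate > 0) {
        drop <- which(stats::runif(length(cm)) < config@missingRate)
        cm[drop] <- NA_integer_
    }

    truthDf <- if (length(truthRows)) do.call(rbind, truthRows) else
        data.frame(chrom = character(), start = integer(),
                   end = integer(), sampleId = character(),
                   familyId = character(), type = character())
    truth <- GRanges(factor(truthDf$chrom, levels = chroms),
                     IRanges(truthDf$start, truthDf$end),
                     sampleId = truthDf$sampleId,
                     familyId = truthDf$familyId, type = truthDf$type)
    GenomeInfoDb::seqlengths(truth) <- seqlens
    list(cohort = GenotypeCohort(markerMap, ped, cm), truth = truth)
}
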