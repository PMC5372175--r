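#' @include AllClasses.R coordinates.R
NULL

#' Flag homozygous markers with a sliding window
#'
#' First stage of the ROH caller, applied per sample and per chromosome.
#' Every window of `windowMarkers` consecutive markers is evaluated; a
#' window passes when it contains at most `maxHetPerWindow` heterozygous
#' and at most `maxMissingPerWindow` missing calls. A marker is flagged
#' homozygous when the fraction of passing windows among all windows
#' containing it is at least `hitFraction`. Chromosomes shorter than one
#' window are evaluated as a single whole-chromosome window with the
#' per-window allowances scaled down proportionally (floor).
#'
#' @param geno integer calls (0/1/2/NA) for one sample on one chromosome,
#'   ordered by position.
#' @param positions marker positions in bp, strictly increasing.
#' @param params a [RohParams-class].
#' @return logical vector, one flag per marker.
#' @export
markHomozygousSites <- function(geno, positions, params = RohParams()) {
    stopifnot(length(geno) == length(positions))
    if (is.unsorted(positions, strictly = TRUE))
        stop("marker positions must be strictly increasing")
    M <- length(geno)
    W <- params@windowMarkers
    isHet <- !is.na(geno) & geno == CALL_HET
    isMiss <- is.na(geno)
    if (M < W) {
        ## whole-chromosome fallback with proportionally scaled allowances
        hetAllow <- floor(params@maxHetPerWindow * M / W)
        missAllow <- floor(params@maxMissingPerWindow * M / W)
        pass <- sum(isHet) <= hetAllow && sum(isMiss) <= missAllow
        return(rep(pass, M))
    }
    nWin <- M - W + 1L
    cumHet <- c(0L, cumsum(isHet))
    cumMiss <- c(0L, cumsum(isMiss))
    j <- seq_len(nWin)
    pass <- (cumHet[j + W] - cumHet[j]) <= params@maxHetPerWindow &
        (cumMiss[j + W] - cumMiss[j]) <= params@maxMissingPerWindow
    cumPass <- c(0L, cumsum(pass))
    i <- seq_len(M)
    lo <- pmax(1L, i - W + 1L)
    hi <- pmin(i, nWin)
    frac <- (cumPass[hi + 1L] - cumPass[lo]) / (hi - lo + 1L)
    frac >= params@hitFraction
}

#' Assemble flagged markers into ROH segments
#'
#' Second stage of the ROH caller. Maximal stretches of consecutive flagged
#' markers become candidate runs; a run is split wherever the physical gap
#' between consecutive flagged markers exceeds `maxInternalGapBp`. Runs are
#' kept when they contain at least `minRunMarkers` markers and span at
#' least `minRunLengthBp`. A run's interval reaches from its first to one
#' past its last flagged marker (half-open); boundaries are never extended
#' into unflagged territory. Missing calls inside a run count toward
#' `nMissing` but do not break it.
#'
#' @param flags logical vector from [markHomozygousSites()].
#' @param geno,positions the calls and positions the flags refer to.
#' @param chrom chromosome name for the emitted segments.
#' @param params a [RohParams-class].
#' @param sampleId sample label attached to the segments.
#' @return a half-open `GRanges` with metadata columns `sampleId`,
#'   `nMarkers`, `nHet`, `nMissing`.
#' @export
assembleRuns <- function(flags, geno, positions, chrom,
                         params = RohParams(), sampleId = "sample") {
    stopifnot(length(flags) == length(geno),
              length(flags) == length(positions))
    out <- GRanges()
    if (!any(flags))
        return(.emptyRoh())
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segs <- list()
    for (b in which(r$values)) {
        idx <- starts[b]:ends[b]
        ## split at large physical gaps between consecutive flagged markers
        gaps <- diff(positions[idx])
        cut <- c(0L, which(gaps > params@maxInternalGapBp), length(idx))
        for (p in seq_len(length(cut) - 1L)) {
            sub <- idx[(cut[p] + 1L):cut[p + 1L]]
            nm <- length(sub)
            lenBp <- positions[sub[nm]] + 1L - positions[sub[1L]]
            if (nm < params@minRunMarkers || lenBp < params@minRunLengthBp)
                next
            g <- geno[sub]
            segs[[length(segs) + 1L]] <- data.frame(
                start = positions[sub[1L]],
                end = positions[sub[nm]] + 1L,
                nMarkers = nm,
                nHet = sum(!is.na(g) & g == CALL_HET),
                nMissing = sum(is.na(g)))
        }
    }
    if (!length(segs))
        return(.emptyRoh())
    df <- do.call(rbind, segs)
    genomicIntervals(chrom, df$start, df$end, sampleId = sampleId,
                     nMarkers = df$nMarkers, nHet = df$nHet,
                     nMissing = df$nMissing)
}

.emptyRoh <- function() {
    GRanges(sampleId = character(), nMarkers = integer(),
            nHet = integer(), nMissing = integer())
}

#' Call runs of homozygosity across a cohort
#'
#' Applies [markHomozygousSites()] and [assembleRuns()] per sample and per
#' chromosome. The result is deterministic and invariant to sample and
#' chromosome processing order.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param params a [RohParams-class].
#' @return a half-open `GRanges` of ROH segments for the whole cohort, with
#'   metadata columns `sampleId`, `nMarkers`, `nHet`, `nMissing`; split by
#'   `sampleId` for a per-sample view.
#' @examples
#' sim <- simulateCohort(SimConfig(nFamilies = 1L, nMarkers = 800L,
#'                                 nChroms = 1L, seed = 11L))
#' roh <- callRohCohort(sim$cohort)
#' split(roh, roh$sampleId)
#' @export
callRohCohort <- function(cohort, params = RohParams()) {
    validObject(params)
    mm <- markers(cohort)
    cm <- calls(cohort)
    chromOf <- as.character(seqnames(mm))
    pos <- start(mm)
    pieces <- list()
    for (sid in sort(colnames(cohort))) {
        for (ch in sort(unique(chromOf))) {
            sel <- chromOf == ch
            g <- cm[sel, sid]
            flags <- markHomozygousSites(g, pos[sel], params)
            seg <- assembleRuns(flags, g, pos[sel], ch, params, sid)
            if (length(seg))
                pieces[[length(pieces) + 1L]] <- seg
        }
    }
    if (!length(pieces))
        return(.emptyRoh())
    suppressWarnings(do.call(c, pieces))
}
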