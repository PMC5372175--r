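#' @include AllClasses.R coordinates.R
NULL

#' Recurrent ROH regions across affected individuals
#'
#' Sweep-line discovery of maximal genomic intervals covered by the ROH of
#' at least `k` distinct affected individuals (or families). Overlapping
#' segments from one sample are merged first, so each sample contributes at
#' most one segment per locus. All segment endpoints on a chromosome become
#' breakpoints; each atomic interval between consecutive breakpoints
#' carries a constant support set, atomic intervals whose support reaches
#' `k` are kept, and adjacent atomic intervals with identical support sets
#' are merged. Emitted regions are therefore maximal: extending either
#' endpoint would change the support set or drop it below `k`. For a given
#' `k` every region is nested within a region for `k - 1`.
#'
#' Because a single coordinate pair with an explicit support list only
#' makes sense over an interval where the support is constant, regions are
#' reported as maximal constant-support intervals rather than as unions of
#' all positions with coverage at least `k`.
#'
#' @param segments half-open `GRanges` of unique ROH with a `sampleId`
#'   metadata column.
#' @param k minimum support; must be at least 2.
#' @param countBy count support by `"individuals"` (default) or by
#'   `"families"` (two affected siblings count once); family counting
#'   requires `ped`.
#' @param ped optional pedigree `data.frame`, used to attach family counts
#'   (see [supportCounts()]).
#' @return a half-open `GRanges` with metadata columns `supportSamples`
#'   (a `CharacterList`), `supportIndividuals`, `supportFamilies` (NA
#'   without a pedigree) and `lengthKb` (floor of bp length / 1000).
#' @export
recurrentRegions <- function(segments, k, countBy = c("individuals", "families"),
                             ped = NULL) {
    countBy <- match.arg(countBy)
    if (k < 2)
        stop("recurrence threshold k must be >= 2, got ", k)
    if (countBy == "families" && is.null(ped))
        stop("countBy = 'families' requires a pedigree")
    famOf <- NULL
    if (!is.null(ped))
        famOf <- stats::setNames(ped$familyId, ped$sampleId)
    out <- list()
    for (ch in sort(unique(as.character(seqnames(segments))))) {
        seg <- segments[as.character(seqnames(segments)) == ch]
        ## one counted segment per sample per locus: merge within sample
        merged <- lapply(split(seg, seg$sampleId), function(s) {
            r <- IRanges::reduce(IRanges(start(s), end(s) - 1L))
            data.frame(sampleId = unique(s$sampleId)[1L],
                       start = IRanges::start(r), end = IRanges::end(r) + 1L)
        })
        df <- do.call(rbind, merged)
        if (is.null(df) || nrow(df) == 0L)
            next
        bp <- sort(unique(c(df$start, df$end)))
        if (length(bp) < 2L)
            next
        aStart <- bp[-length(bp)]
        aEnd <- bp[-1L]
        supports <- lapply(seq_along(aStart), function(i) {
            sort(df$sampleId[df$start <= aStart[i] & df$end >= aEnd[i]])
        })
        cnt <- vapply(supports, function(s) {
            if (countBy == "families")
                length(unique(famOf[s]))
            else length(s)
        }, integer(1))
        ok <- cnt >= k
        if (!any(ok))
            next
        ## merge adjacent atomic intervals with identical support sets
        i <- 1L
        while (i <= length(aStart)) {
            if (!ok[i]) { i <- i + 1L; next }
            j <- i
            while (j + 1L <= length(aStart) && ok[j + 1L] &&
                   aEnd[j] == aStart[j + 1L] &&
                   identical(supports[[j]], supports[[j + 1L]]))
                j <- j + 1L
            sup <- supports[[i]]
            out[[length(out) + 1L]] <- list(chrom = ch, start = aStart[i],
                                            end = aEnd[j], support = sup)
            i <- j + 1L
        }
    }
    if (!length(out))
        return(GRanges(supportSamples = IRanges::CharacterList(),
                       supportIndividuals = integer(),
                       supportFamilies = integer(),
                       lengthKb = integer()))
    gr <- genomicIntervals(vapply(out, `[[`, character(1), "chrom"),
                           vapply(out, `[[`, numeric(1), "start"),
                           vapply(out, `[[`, numeric(1), "end"))
    mcols(gr)$supportSamples <- IRanges::CharacterList(lapply(out, `[[`, "support"))
    sc <- lapply(out, function(o) {
        if (is.null(famOf))
            c(length(o$support), NA_integer_)
        else c(length(o$support), length(unique(famOf[o$support])))
    })
    mcols(gr)$supportIndividuals <- vapply(sc, `[`, numeric(1), 1L)
    mcols(gr)$supportFamilies <- vapply(sc, `[`, numeric(1), 2L)
    mcols(gr)$lengthKb <- lengthKb(gr)
    gr
}

#' Support of a recurrent region in individuals and families
#'
#' Counts distinct affected individuals and distinct families backing a
#' recurrent region; two affected siblings count as two individuals but one
#' family, so the individual count is never below the family count.
#'
#' @param supportSamples character vector of supporting sample ids.
#' @param ped pedigree `data.frame` containing those samples.
#' @return named integer vector `c(individuals, families)`.
#' @export
supportCounts <- function(supportSamples, ped) {
    supportSamples <- unique(supportSamples)
    if (length(supportSamples) == 0L)
        return(c(individuals = 0L, families = 0L))
    missing <- setdiff(supportSamples, ped$sampleId)
    if (length(missing))
        stop("support sample(s) absent from pedigree: ",
             paste(missing, collapse = ", "))
    fams <- ped$familyId[match(supportSamples, ped$sampleId)]
    c(individuals = length(supportSamples),
      families = length(unique(fams)))
}
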