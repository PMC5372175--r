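#' @include AllClasses.R coordinates.R
NULL

.masks <- function(affSeg, compSeg, policy) {
    hits <- findOverlapsHalfOpen(affSeg, compSeg)
    if (policy@overlapRule == "reciprocal_fraction" && length(hits)) {
        ow <- overlapWidthBp(affSeg, compSeg, hits)
        la <- lengthBp(affSeg)[S4Vectors::queryHits(hits)]
        lb <- lengthBp(compSeg)[S4Vectors::subjectHits(hits)]
        keep <- ow >= policy@reciprocalFraction * la &
            ow >= policy@reciprocalFraction * lb
        hits <- hits[keep]
    }
    unique(S4Vectors::queryHits(hits))
}

#' Autosomal-recessive filter: ROH unique to affected individuals
#'
#' Under an autosomal-recessive, highly penetrant model the disease locus is
#' homozygous in affected individuals and not in their unaffected relatives.
#' For each affected individual this filter drops every ROH that overlaps
#' (per the [FilterPolicy-class]) an ROH of any comparator in the same
#' family: all unaffected relatives by default, or the unaffected parents
#' only. Individuals in different families never mask each other, and two
#' affected siblings never mask each other. Filtering is idempotent and its
#' output is always a subset of its input.
#'
#' @param segments half-open `GRanges` of ROH segments with a `sampleId`
#'   metadata column (as produced by [callRohCohort()]); every sample must
#'   appear in the pedigree.
#' @param ped pedigree `data.frame` (see [readPedigree()]).
#' @param policy a [FilterPolicy-class].
#' @return the subset of `segments` belonging to affected individuals and
#'   unique to them under the policy.
#' @export
uniqueRoh <- function(segments, ped, policy = FilterPolicy()) {
    validObject(policy)
    missing <- setdiff(unique(segments$sampleId), ped$sampleId)
    if (length(missing))
        stop("segment sample(s) absent from pedigree: ",
             paste(missing, collapse = ", "))
    affected <- ped$sampleId[ped$phenotype == "affected"]
    keep <- logical(length(segments))
    for (sid in intersect(affected, unique(segments$sampleId))) {
        idx <- which(segments$sampleId == sid)
        rec <- ped[ped$sampleId == sid, ]
        famUnaff <- ped$sampleId[ped$familyId == rec$familyId &
                                 ped$phenotype == "unaffected"]
        comps <- if (policy@excludeAgainst == "parents_only")
            intersect(famUnaff, c(rec$fatherId, rec$motherId))
        else famUnaff
        compSeg <- segments[segments$sampleId %in% comps]
        drop <- if (length(compSeg))
            .masks(segments[idx], compSeg, policy)
        else integer()
        keepIdx <- setdiff(seq_along(idx), drop)
        keep[idx[keepIdx]] <- TRUE
    }
    segments[keep]
}

#' Count unique ROH per affected individual
#'
#' Tallies the output of [uniqueRoh()] per affected individual. When a
#' pedigree is supplied, affected individuals without any unique ROH are
#' reported with a count of zero and rows are ordered by family then
#' sample; the count is invariant to segment order.
#'
#' @param filtered output of [uniqueRoh()].
#' @param ped optional pedigree `data.frame`.
#' @return a `data.frame` with columns `familyId` (when `ped` given),
#'   `sampleId` and `nRoh`.
#' @export
countUniqueRoh <- function(filtered, ped = NULL) {
    tab <- table(filtered$sampleId)
    if (is.null(ped)) {
        ids <- sort(names(tab))
        return(data.frame(sampleId = ids, nRoh = as.integer(tab[ids]),
                          row.names = NULL))
    }
    aff <- ped[ped$phenotype == "affected", ]
    aff <- aff[order(aff$familyId, aff$sampleId), ]
    n <- as.integer(tab[aff$sampleId])
    n[is.na(n)] <- 0L
    data.frame(familyId = aff$familyId, sampleId = aff$sampleId,
               nRoh = n, row.names = NULL)
}
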