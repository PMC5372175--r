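#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData
#'   assay assays
NULL

## Genotype calls are stored as an integer matrix (markers x samples):
## 0 = HOM_A, 1 = HET, 2 = HOM_B, NA = MISSING.
CALL_HOM_A <- 0L
CALL_HET <- 1L
CALL_HOM_B <- 2L

#' Cohort genotypes with marker map and pedigree
#'
#' `GenotypeCohort` extends `RangedSummarizedExperiment`. Rows are biallelic
#' markers (a point `GRanges` carrying `markerId`, `alleleA`, `alleleB` and
#' the population B-allele frequency `freqB`); columns are samples, with the
#' pedigree (family, parents, sex, affection status) in `colData`. The single
#' assay `"calls"` holds integer-coded genotypes: 0 = homozygous A, 1 =
#' heterozygous, 2 = homozygous B, `NA` = missing. Missing calls are never
#' treated as homozygous or heterozygous by any downstream stage.
#'
#' @section Accessors:
#' `markers(x)` returns the marker `GRanges`; `calls(x)` the integer call
#' matrix; `pedigree(x)` the pedigree as a `data.frame` with columns
#' `familyId`, `sampleId`, `fatherId`, `motherId`, `sex`, `phenotype`.
#'
#' @param x a `GenotypeCohort`.
#' @name GenotypeCohort-class
#' @aliases GenotypeCohort markers calls pedigree
#' @exportClass GenotypeCohort
setClass("GenotypeCohort", contains = "RangedSummarizedExperiment")

setValidity("GenotypeCohort", function(object) {
    msg <- character()
    if (!"calls" %in% names(assays(object)))
        msg <- c(msg, "assay 'calls' is required")
    else {
        cm <- assay(object, "calls")
        if (!is.integer(cm) && !all(is.na(cm)))
            msg <- c(msg, "assay 'calls' must be an integer matrix")
        bad <- cm[!is.na(cm)]
        if (length(bad) && !all(bad %in% 0:2))
            msg <- c(msg, "calls must be 0 (HOM_A), 1 (HET), 2 (HOM_B) or NA")
    }
    rr <- rowRanges(object)
    need <- c("markerId", "alleleA", "alleleB", "freqB")
    miss <- setdiff(need, colnames(mcols(rr)))
    if (length(miss))
        msg <- c(msg, paste0("marker columns missing: ",
                             paste(miss, collapse = ", ")))
    else {
        if (anyDuplicated(mcols(rr)$markerId))
            msg <- c(msg, "markerId must be unique")
        fb <- mcols(rr)$freqB
        if (any(fb < 0 | fb > 1, na.rm = TRUE))
            msg <- c(msg, "freqB must lie in [0,1]")
        ## strictly increasing positions within each chromosome
        pos <- split(start(rr), as.character(seqnames(rr)))
        if (any(vapply(pos, function(p) any(diff(p) <= 0), logical(1))))
            msg <- c(msg, "marker positions must be strictly increasing per chromosome")
    }
    cd <- colData(object)
    needc <- c("familyId", "fatherId", "motherId", "sex", "phenotype")
    missc <- setdiff(needc, colnames(cd))
    if (length(missc))
        msg <- c(msg, paste0("pedigree columns missing: ",
                             paste(missc, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Parameters of the sliding-window ROH caller
#'
#' Windows of `windowMarkers` consecutive markers slide along each
#' chromosome; a window passes when it contains at most `maxHetPerWindow`
#' heterozygous and at most `maxMissingPerWindow` missing calls. A marker is
#' flagged homozygous when at least a fraction `hitFraction` of the windows
#' containing it pass. Maximal flagged stretches become runs, split at
#' physical gaps above `maxInternalGapBp`, and kept when they contain at
#' least `minRunMarkers` markers and span at least `minRunLengthBp`.
#'
#' Defaults follow the sliding-window heuristic popularised by genome-wide
#' association toolkits, with the minimum run length set to 500 kb so that
#' candidate loci below one megabase remain resolvable on array-density data.
#'
#' @slot windowMarkers integer, markers per window (50).
#' @slot maxHetPerWindow integer, heterozygous calls tolerated per window (1).
#' @slot maxMissingPerWindow integer, missing calls tolerated per window (5).
#' @slot hitFraction numeric in \[0,1\], fraction of passing windows needed
#'   to flag a marker (0.05).
#' @slot minRunMarkers integer, minimum markers per emitted run (25).
#' @slot minRunLengthBp integer, minimum physical run length (500,000).
#' @slot maxInternalGapBp integer, marker gap that splits a run (1,000,000).
#' @export RohParams
#' @exportClass RohParams
RohParams <- setClass("RohParams",
    representation(windowMarkers = "integer",
                   maxHetPerWindow = "integer",
                   maxMissingPerWindow = "integer",
                   hitFraction = "numeric",
                   minRunMarkers = "integer",
                   minRunLengthBp = "integer",
                   maxInternalGapBp = "integer"),
    prototype(windowMarkers = 50L,
              maxHetPerWindow = 1L,
              maxMissingPerWindow = 5L,
              hitFraction = 0.05,
              minRunMarkers = 25L,
              minRunLengthBp = 500000L,
              maxInternalGapBp = 1000000L))

setValidity("RohParams", function(object) {
    msg <- character()
    if (object@windowMarkers < max(object@maxHetPerWindow, 1L) + 1L)
        msg <- c(msg, "windowMarkers too small for maxHetPerWindow")
    if (object@hitFraction < 0 || object@hitFraction > 1)
        msg <- c(msg, "hitFraction must lie in [0,1]")
    pos <- c(window = object@windowMarkers, minMarkers = object@minRunMarkers,
             minLen = object@minRunLengthBp, maxGap = object@maxInternalGapBp)
    if (any(pos <= 0))
        msg <- c(msg, "window and run thresholds must be positive")
    if (object@maxHetPerWindow < 0 || object@maxMissingPerWindow < 0)
        msg <- c(msg, "per-window allowances must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Policy of the autosomal-recessive family filter
#'
#' Under a recessive, highly penetrant model only ROH unique to the affected
#' individual(s) of a family are candidate disease loci. `excludeAgainst`
#' selects the comparator set used to establish uniqueness:
#' `"all_unaffected_relatives"` (default, the stricter reading: parents and
#' unaffected siblings) or `"parents_only"`. `overlapRule` decides when a
#' comparator's ROH masks an affected ROH: `"any_overlap"` (default, one
#' shared base pair suffices) or `"reciprocal_fraction"`, which requires a
#' reciprocal overlap of at least `reciprocalFraction` in both segments.
#'
#' @slot excludeAgainst character, comparator set.
#' @slot overlapRule character, masking rule.
#' @slot reciprocalFraction numeric in (0,1], used only when
#'   `overlapRule == "reciprocal_fraction"`.
#' @export FilterPolicy
#' @exportClass FilterPolicy
FilterPolicy <- setClass("FilterPolicy",
    representation(excludeAgainst = "character",
                   overlapRule = "character",
                   reciprocalFraction = "numeric"),
    prototype(excludeAgainst = "all_unaffected_relatives",
              overlapRule = "any_overlap",
              reciprocalFraction = NA_real_))

setValidity("FilterPolicy", function(object) {
    msg <- character()
    if (!object@excludeAgainst %in%
        c("all_unaffected_relatives", "parents_only"))
        msg <- c(msg, "excludeAgainst must be 'all_unaffected_relatives' or 'parents_only'")
    if (!object@overlapRule %in% c("any_overlap", "reciprocal_fraction"))
        msg <- c(msg, "overlapRule must be 'any_overlap' or 'reciprocal_fraction'")
    rf <- object@reciprocalFraction
    if (object@overlapRule == "reciprocal_fraction" &&
        (is.na(rf) || rf <= 0 || rf > 1))
        msg <- c(msg, "reciprocalFraction must lie in (0,1] under reciprocal_fraction")
    if (object@overlapRule == "any_overlap" && !is.na(rf))
        msg <- c(msg, "reciprocalFraction is only meaningful under reciprocal_fraction")
    if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic consanguineous-cohort generator
#'
#' Describes a cohort of nuclear families genotyped on an array-like grid of
#' biallelic markers. Background genotypes are drawn marker-wise from
#' Hardy-Weinberg proportions at the marker's B-allele frequency; affected
#' children additionally receive planted autozygous (fully homozygous)
#' segments, the truth set against which caller recovery is scored.
#' Genotyping noise renders truly homozygous calls heterozygous with
#' probability `hetErrorRate` and any call missing with probability
#' `missingRate`. Unaffected members receive on average `backgroundRohRate`
#' incidental homozygous segments each, drawn from the same length sampler.
#'
#' Defaults emulate a consanguineous autism cohort of 36 nuclear families
#' (two parents, two children, one affected) on a scaled-down genome of four
#' autosomes with ~5 kb marker spacing; see the package vignette for the
#' rationale behind each value.
#'
#' @slot nFamilies integer, number of nuclear families (36).
#' @slot childrenPerFamily integer, children per family (2).
#' @slot affectedPerFamily integer, affected children per family (1).
#' @slot nMarkers integer, markers per chromosome (3000).
#' @slot nChroms integer, number of autosomes (4).
#' @slot markerSpacingBp numeric, mean inter-marker gap in bp (5000);
#'   gaps are exponentially jittered around this mean.
#' @slot freqBSampler function(n) drawing B-allele frequencies in
#'   \[0.05, 0.95\].
#' @slot plantedSegmentsPerAffected integer, autozygous segments planted per
#'   affected child (2).
#' @slot plantedLengthSampler function(n) drawing planted segment lengths in
#'   bp (uniform on \[1, 3\] Mb).
#' @slot hetErrorRate numeric, probability a truly homozygous call is
#'   rendered heterozygous (0.001).
#' @slot missingRate numeric, probability any call is rendered missing (0.01).
#' @slot backgroundRohRate numeric, expected incidental homozygous segments
#'   per unaffected sample (1).
#' @slot seed integer; the seed fully determines the output.
#' @export SimConfig
#' @exportClass SimConfig
SimConfig <- setClass("SimConfig",
    representation(nFamilies = "integer",
                   childrenPerFamily = "integer",
                   affectedPerFamily = "integer",
                   nMarkers = "integer",
                   nChroms = "integer",
                   markerSpacingBp = "numeric",
                   freqBSampler = "function",
                   plantedSegmentsPerAffected = "integer",
                   plantedLengthSampler = "function",
                   hetErrorRate = "numeric",
                   missingRate = "numeric",
                   backgroundRohRate = "numeric",
                   seed = "integer"),
    prototype(nFamilies = 36L,
              childrenPerFamily = 2L,
              affectedPerFamily = 1L,
              nMarkers = 3000L,
              nChroms = 4L,
              markerSpacingBp = 5000,
              freqBSampler = function(n) stats::runif(n, 0.05, 0.95),
              plantedSegmentsPerAffected = 2L,
              plantedLengthSampler = function(n) stats::runif(n, 1e6, 3e6),
              hetErrorRate = 0.001,
              missingRate = 0.01,
              backgroundRohRate = 1,
              seed = 1L))

setValidity("SimConfig", function(object) {
    msg <- character()
    pr <- c(object@hetErrorRate, object@missingRate)
    if (any(pr < 0 | pr > 1))
        msg <- c(msg, "hetErrorRate and missingRate must lie in [0,1]")
    if (object@backgroundRohRate < 0)
        msg <- c(msg, "backgroundRohRate must be non-negative")
    if (object@affectedPerFamily > object@childrenPerFamily)
        msg <- c(msg, "affectedPerFamily cannot exceed childrenPerFamily")
    cnt <- c(object@nFamilies, object@childrenPerFamily, object@nMarkers,
             object@nChroms)
    if (any(cnt < 1))
        msg <- c(msg, "family, child, marker and chromosome counts must be >= 1")
    if (object@markerSpacingBp <= 0)
        msg <- c(msg, "markerSpacingBp must be positive")
    if (length(msg)) msg else TRUE
})

#' Genotype counts for one group at one biallelic variant
#'
#' Tallies of NN (homozygous reference), NV (heterozygous) and VV
#' (homozygous alternate) genotypes for one group of individuals at a single
#' variant, with the derived allele frequencies and carrier count.
#'
#' @section Accessors:
#' `nSamples(x)` returns NN+NV+VV. `alleleFreqs(x)` returns
#' `c(freqN, freqV)` with `freqV = (NV + 2 VV) / (2 n)`; the two frequencies
#' sum to one exactly. `carrierCount(x)` returns NV+VV, the number of
#' individuals with at least one alternate allele.
#'
#' @slot group character label of the group.
#' @slot nNN,nNV,nVV integer genotype counts.
#' @param x a `GenotypeTable`.
#' @export GenotypeTable
#' @exportClass GenotypeTable
#' @aliases alleleFreqs carrierCount nSamples
GenotypeTable <- setClass("GenotypeTable",
    representation(group = "character",
                   nNN = "integer", nNV = "integer", nVV = "integer"))

setValidity("GenotypeTable", function(object) {
    cnt <- c(object@nNN, object@nNV, object@nVV)
    if (any(is.na(cnt)) || any(cnt < 0))
        "genotype counts must be non-negative integers"
    else if (length(object@group) != 1L)
        "group must be a single label"
    else TRUE
})
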