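#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname GenotypeCohort-class
#' @export
setMethod("markers", "GenotypeCohort", function(x) rowRanges(x))

#' @rdname GenotypeCohort-class
#' @export
setMethod("calls", "GenotypeCohort", function(x) assay(x, "calls"))

#' @rdname GenotypeCohort-class
#' @export
setMethod("pedigree", "GenotypeCohort", function(x) {
    cd <- as.data.frame(colData(x))
    data.frame(familyId = cd$familyId,
               sampleId = colnames(x),
               fatherId = cd$fatherId,
               motherId = cd$motherId,
               sex = cd$sex,
               phenotype = cd$phenotype,
               stringsAsFactors = FALSE)
})

setMethod("show", "GenotypeCohort", function(object) {
    ped <- pedigree(object)
    cat("GenotypeCohort:", nrow(object), "markers x", ncol(object),
        "samples\n")
    cat("  chromosomes:", paste(GenomeInfoDb::seqlevels(rowRanges(object)),
                                collapse = " "), "\n")
    cat("  families:", length(unique(ped$familyId)),
        "| affected:", sum(ped$phenotype == "affected"),
        "| unaffected:", sum(ped$phenotype == "unaffected"), "\n")
    cat("  missing call rate:",
        sprintf("%.4f", mean(is.na(assay(object, "calls")))), "\n")
})

setMethod("show", "RohParams", function(object) {
    cat("RohParams\n")
    cat("  window:", object@windowMarkers, "markers, <=",
        object@maxHetPerWindow, "HET, <=", object@maxMissingPerWindow,
        "MISSING; hit fraction", object@hitFraction, "\n")
    cat("  runs: >=", object@minRunMarkers, "markers, >=",
        object@minRunLengthBp, "bp, split at gaps >",
        object@maxInternalGapBp, "bp\n")
})

setMethod("show", "FilterPolicy", function(object) {
    cat("FilterPolicy: exclude against", object@excludeAgainst,
        "| overlap rule", object@overlapRule)
    if (object@overlapRule == "reciprocal_fraction")
        cat(" (fraction", object@reciprocalFraction, ")")
    cat("\n")
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nFamilies, "families,",
        object@childrenPerFamily, "children each (",
        object@affectedPerFamily, "affected );",
        object@nChroms, "chromosomes x", object@nMarkers, "markers @ ~",
        object@markerSpacingBp, "bp\n")
    cat("  planted/affected:", object@plantedSegmentsPerAffected,
        "| hetError:", object@hetErrorRate,
        "| missing:", object@missingRate,
        "| bgROH:", object@backgroundRohRate,
        "| seed:", object@seed, "\n")
})

#' @rdname GenotypeTable-class
#' @export
setMethod("nSamples", "GenotypeTable",
          function(x) x@nNN + x@nNV + x@nVV)

#' @rdname GenotypeTable-class
#' @export
setMethod("alleleFreqs", "GenotypeTable", function(x) {
    n <- nSamples(x)
    if (n == 0L)
        stop("allele frequencies undefined for an empty genotype table")
    freqV <- (x@nNV + 2 * x@nVV) / (2 * n)
    c(freqN = 1 - freqV, freqV = freqV)
})

#' @rdname GenotypeTable-class
#' @export
setMethod("carrierCount", "GenotypeTable", function(x) x@nNV + x@nVV)

setMethod("show", "GenotypeTable", function(object) {
    n <- nSamples(object)
    cat("GenotypeTable '", object@group, "' (n = ", n, ")\n", sep = "")
    cat("  NN:", object@nNN, " NV:", object@nNV, " VV:", object@nVV, "\n")
    if (n > 0) {
        af <- alleleFreqs(object)
        cat(sprintf("  freq N: %.2f  freq V: %.2f  carriers: %d\n",
                    af["freqN"], af["freqV"], carrierCount(object)))
    }
})
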