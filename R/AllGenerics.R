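#' @include AllClasses.R
NULL

#' Physical length of half-open intervals
#'
#' All intervals in this package follow a 1-based half-open convention
#' `[start, end)`: the `end` coordinate is excluded, so the physical length
#' is `end - start`. Because the exclusive end is stored in the `end` slot
#' of a `GRanges`, `width()` overstates the length by one base; use these
#' accessors instead.
#'
#' `lengthKb()` truncates (floor), it does not round: a 873,892 bp interval
#' is reported as 873 kb.
#'
#' @param x a `GRanges` of half-open intervals, or a numeric vector of
#'   start coordinates.
#' @param end numeric vector of exclusive end coordinates (only when `x`
#'   is numeric).
#' @return integer vector of lengths in bp (`lengthBp`) or truncated
#'   kilobases (`lengthKb`).
#' @examples
#' lengthKb(157813799, 158331136)  # 517
#' @export
setGeneric("lengthBp", function(x, end) standardGeneric("lengthBp"))

#' @rdname lengthBp
#' @export
setGeneric("lengthKb", function(x, end) standardGeneric("lengthKb"))

#' @rdname GenotypeCohort-class
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname GenotypeCohort-class
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname GenotypeCohort-class
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("alleleFreqs", function(x) standardGeneric("alleleFreqs"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("carrierCount", function(x) standardGeneric("carrierCount"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
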