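#' @include AllGenerics.R
NULL

#' Construct half-open genomic intervals
#'
#' Builds a `GRanges` under the package-wide convention: coordinates are
#' 1-based and half-open, `[start, end)`, so `end` is the first position
#' *not* covered and the physical length is `end - start`. The exclusive end
#' is stored verbatim in the `end` slot.
#'
#' @param chrom character chromosome names.
#' @param start integer 1-based start positions (included).
#' @param end integer end positions (excluded); must exceed `start`.
#' @param ... metadata columns passed to [GenomicRanges::GRanges()].
#' @return a `GRanges` of half-open intervals.
#' @examples
#' gi <- genomicIntervals("chr2", 38790327, 39664219)
#' lengthKb(gi)  # 873
#' @export
genomicIntervals <- function(chrom, start, end, ...) {
    if (any(end <= start))
        stop("half-open intervals require end > start")
    GRanges(chrom, IRanges(start = start, end = end), ...)
}

#' @rdname lengthBp
#' @export
setMethod("lengthBp", signature(x = "GRanges", end = "missing"),
          function(x, end) BiocGenerics::end(x) - BiocGenerics::start(x))

#' @rdname lengthBp
#' @export
setMethod("lengthBp", signature(x = "numeric", end = "numeric"),
          function(x, end) as.integer(end - x))

#' @rdname lengthBp
#' @export
setMethod("lengthKb", signature(x = "GRanges", end = "missing"),
          function(x, end)
              as.integer(floor((BiocGenerics::end(x) -
                                BiocGenerics::start(x)) / 1000)))

#' @rdname lengthBp
#' @export
setMethod("lengthKb", signature(x = "numeric", end = "numeric"),
          function(x, end) as.integer(floor((end - x) / 1000)))

## Overlap machinery under half-open semantics: [s1,e1) and [s2,e2) overlap
## iff s1 < e2 and s2 < e1. Shrinking the stored (exclusive) ends by 1 bp
## turns this into the closed-interval test that IRanges implements, so
## touching intervals ([1,5) and [5,9)) do not overlap. A shared seqlevel
## universe avoids spurious seqinfo-merge warnings.
.closed <- function(gr, levels = GenomeInfoDb::seqlevels(gr)) {
    GRanges(factor(as.character(seqnames(gr)), levels = levels),
            IRanges(BiocGenerics::start(gr), BiocGenerics::end(gr) - 1L))
}

#' Overlaps between half-open interval sets
#'
#' `findOverlapsHalfOpen()` wraps [GenomicRanges::findOverlaps()] with the
#' package's half-open semantics: intervals sharing only a boundary point do
#' not overlap. `overlapWidthBp()` returns the pairwise intersection widths
#' in bp for a `Hits` object.
#'
#' @param query,subject `GRanges` of half-open intervals.
#' @return a `S4Vectors::Hits` object.
#' @export
findOverlapsHalfOpen <- function(query, subject) {
    lv <- union(GenomeInfoDb::seqlevels(query),
                GenomeInfoDb::seqlevels(subject))
    GenomicRanges::findOverlaps(.closed(query, lv), .closed(subject, lv))
}

#' @rdname findOverlapsHalfOpen
#' @param hits a `Hits` from `findOverlapsHalfOpen()`.
#' @export
overlapWidthBp <- function(query, subject, hits) {
    q <- query[S4Vectors::queryHits(hits)]
    s <- subject[S4Vectors::subjectHits(hits)]
    pmin(end(q), end(s)) - pmax(start(q), start(s))
}

#' Jaccard overlap of two half-open intervals
#'
#' `|A intersect B| / |A union B|` on the bp scale, the score used to judge
#' recovery of planted autozygous segments. Intervals on different
#' chromosomes score 0.
#'
#' @param a,b single-interval `GRanges`.
#' @return numeric in \[0,1\].
#' @export
jaccardBp <- function(a, b) {
    stopifnot(length(a) == 1L, length(b) == 1L)
    if (as.character(seqnames(a)) != as.character(seqnames(b)))
        return(0)
    inter <- max(0L, min(end(a), end(b)) - max(start(a), start(b)))
    if (inter == 0L)
        return(0)
    uni <- max(end(a), end(b)) - min(start(a), start(b))
    inter / uni
}

#' Write and read intervals as BED
#'
#' Writes half-open intervals to BED: the BED start column is `start - 1`
#' (0-based) and the BED end column is the exclusive end unchanged, so a
#' write/read round trip restores coordinates exactly and lengths are
#' invariant. A `#` header records the coordinate convention. Optional
#' `name` and `score` metadata columns become BED columns 4-5.
#'
#' @param intervals a `GRanges` of half-open intervals; metadata columns
#'   `name` and `score` are written when present.
#' @param path output (input) file path.
#' @return `readIntervals()` returns a `GRanges` with any `name`/`score`
#'   columns restored.
#' @examples
#' gi <- genomicIntervals("chr2", 38790327, 39664219)
#' f <- tempfile(fileext = ".bed")
#' writeIntervals(gi, f)   # "chr2\t38790326\t39664219"
#' readIntervals(f)
#' @export
writeIntervals <- function(intervals, path) {
    header <- "# coordinates: 1-based half-open [start, end); BED columns are 0-based starts"
    lines <- header
    if (length(intervals)) {
        cols <- list(as.character(seqnames(intervals)),
                     format(start(intervals) - 1L, scientific = FALSE, trim = TRUE),
                     format(end(intervals), scientific = FALSE, trim = TRUE))
        mc <- mcols(intervals)
        if ("name" %in% colnames(mc)) {
            cols <- c(cols, list(as.character(mc$name)))
            if ("score" %in% colnames(mc))
                cols <- c(cols, list(as.character(mc$score)))
        }
        lines <- c(lines, do.call(paste, c(cols, sep = "\t")))
    }
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeIntervals
#' @export
readIntervals <- function(path) {
    tab <- tryCatch(
        utils::read.table(path, sep = "\t", comment.char = "#",
                          colClasses = "character"),
        error = function(e) NULL)
    if (is.null(tab))
        return(GRanges())
    gr <- genomicIntervals(tab[[1L]], as.integer(tab[[2L]]) + 1L,
                           as.integer(tab[[3L]]))
    if (ncol(tab) >= 4L)
        mcols(gr)$name <- tab[[4L]]
    if (ncol(tab) >= 5L)
        mcols(gr)$score <- as.numeric(tab[[5L]])
    gr
}
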