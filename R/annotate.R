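#' @include AllClasses.R coordinates.R
NULL

#' Load a gene coordinate set
#'
#' Reads gene records from BED (column 4 as the symbol) or GFF3 (features
#' of type `gene`, symbol from the `Name` or `gene_name` attribute; a file
#' without `gene` features yields an empty set with a warning). Records are
#' returned sorted by (chromosome, start) under the package's half-open
#' convention.
#'
#' @param path BED or GFF3 file.
#' @param format `"auto"` (from the extension), `"BED"` or `"GFF3"`.
#' @return a half-open `GRanges` with a `symbol` metadata column.
#' @export
loadGenes <- function(path, format = c("auto", "BED", "GFF3")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
            "GFF3" else "BED"
    gr <- tryCatch(
        rtracklayer::import(path, format = if (format == "BED") "BED" else "GFF3"),
        error = function(e) stop("malformed ", format, " file '", path,
                                 "': ", conditionMessage(e)))
    if (format == "GFF3") {
        gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
        if (length(gr) == 0L) {
            warning("no 'gene' features in ", path)
            return(GRanges(symbol = character()))
        }
        sym <- as.character(gr$Name)
        if (all(is.na(sym)) && "gene_name" %in% colnames(mcols(gr)))
            sym <- as.character(gr$gene_name)
        ## GFF3 ends are 1-based inclusive; store the exclusive end
        out <- genomicIntervals(as.character(seqnames(gr)), start(gr),
                                end(gr) + 1L, symbol = sym,
                                strand = strand(gr))
    } else {
        if (length(gr) == 0L)
            return(GRanges(symbol = character()))
        sym <- if ("name" %in% colnames(mcols(gr)))
            as.character(gr$name) else paste0("gene", seq_along(gr))
        ## rtracklayer maps BED [s0, e0) to start = s0 + 1, end = e0: under
        ## the half-open storage convention the end slot is already the
        ## exclusive end.
        out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                       symbol = sym, strand = strand(gr))
    }
    if (any(is.na(out$symbol) | out$symbol == ""))
        stop("gene record(s) without a symbol in ", path)
    BiocGenerics::sort(GenomeInfoDb::sortSeqlevels(out), ignore.strand = TRUE)
}

#' Genes overlapping a region
#'
#' Any base-pair overlap qualifies: genes straddling a region boundary are
#' included. Output follows genomic order with duplicate symbols collapsed.
#' Annotation is a pure function of the region and the gene set, and
#' shrinking a region can never add genes.
#'
#' @param region a half-open `GRanges` (one or more regions).
#' @param genes gene set from [loadGenes()].
#' @return for a single region, a character vector of symbols; for several,
#'   a `CharacterList` parallel to `region`.
#' @export
genesInRegion <- function(region, genes) {
    hits <- findOverlapsHalfOpen(region, genes)
    per <- lapply(seq_along(region), function(i) {
        g <- genes[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]]
        unique(g$symbol[order(as.character(seqnames(g)), start(g))])
    })
    if (length(region) == 1L)
        per[[1L]]
    else IRanges::CharacterList(per)
}
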