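#' @include AllClasses.R genotype-io.R annotate.R
NULL

.extdata <- function(file) {
    path <- system.file("extdata", file, package = "rohmap",
                        mustWork = FALSE)
    if (!nzchar(path) || !file.exists(path))
        stop("packaged fixture not found: ", file)
    path
}

#' Packaged study fixtures
#'
#' Small plain-text tables bundled with the package, encoding the summary
#' results of a homozygosity-mapping study of autism spectrum disorder in a
#' consanguineous cohort of 36 nuclear families (37 affected children, 36
#' genotyped parents, 33 unaffected siblings) plus 100 unaffected
#' population controls screened for a 5 bp intronic insertion (TTCTG) at
#' the exon-23 intron junction of *CNTNAP2*:
#'
#' * `studyLoci()` — the four recurrent ROH loci: half-open hg19
#'   coordinates, the length in kb as originally printed, gene content and
#'   the list of supporting affected individuals per locus. (For one locus,
#'   8q23.1, the printed kb length is inconsistent with its coordinates;
#'   the table preserves the printed value, the coordinates are
#'   authoritative.)
#' * `studyGenotypeCounts()` — NN/NV/VV counts per group at the *CNTNAP2*
#'   insertion, as [GenotypeTable-class] objects.
#' * `studyVariantGenotypes()` — an individual-level genotype table for all
#'   206 screened individuals, reconstructed to match the group counts
#'   exactly (individual assignments are synthetic: the study published
#'   only group totals).
#' * `studyPedigree()` — a 106-member cohort pedigree over the published
#'   family/patient identifiers (parent and sibling records are synthetic
#'   placeholders consistent with the published family sizes).
#' * `studyGenes()` — an hg19 gene coordinate set covering the four loci
#'   and *CNTNAP2* (synthetic stand-in coordinates placed within the
#'   printed loci; gene membership follows the published locus tables).
#'
#' @return `studyLoci()`: a `data.frame`; `studyGenotypeCounts()`: a named
#'   list of [GenotypeTable-class]; `studyVariantGenotypes()`: a
#'   `data.frame` (`sampleId`, `genotype`, `group`); `studyPedigree()`: a
#'   pedigree `data.frame`; `studyGenes()`: a half-open `GRanges` with a
#'   `symbol` column.
#' @examples
#' studyLoci()
#' alleleFreqs(studyGenotypeCounts()$patients)
#' @name studyFixtures
NULL

#' @rdname studyFixtures
#' @export
studyLoci <- function() {
    utils::read.table(.extdata("asd_recurrent_loci.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname studyFixtures
#' @export
studyGenotypeCounts <- function() {
    tab <- utils::read.table(.extdata("cntnap2_genotype_counts.tsv"),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    out <- lapply(seq_len(nrow(tab)), function(i)
        GenotypeTable(group = tab$group[i], nNN = tab$nNN[i],
                      nNV = tab$nNV[i], nVV = tab$nVV[i]))
    stats::setNames(out, tab$group)
}

#' @rdname studyFixtures
#' @export
studyVariantGenotypes <- function() {
    readVariantGenotypes(.extdata("cntnap2_genotypes_synthetic.tsv"))
}

#' @rdname studyFixtures
#' @export
studyPedigree <- function() {
    readPedigree(.extdata("asd_cohort_pedigree_synthetic.ped"))
}

#' @rdname studyFixtures
#' @export
studyGenes <- function() {
    loadGenes(.extdata("hg19_genes_synthetic.bed"), format = "BED")
}
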