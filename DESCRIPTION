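Package: rohmap
Title: Homozygosity Mapping in Consanguineous Pedigrees
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of runs of homozygosity (ROH) from SNP-array-like
    biallelic genotype calls, autosomal-recessive family filtering of ROH
    against unaffected relatives, sweep-line discovery of genomic regions
    where ROH from several affected individuals recur, gene annotation of
    candidate regions, and case-control genotype/allele association for a
    single variant. Includes a deterministic simulator of consanguineous
    nuclear-family cohorts with planted autozygous segments so that every
    stage of the pipeline can be validated against a known truth set, and
    packaged summary tables from a homozygosity-mapping study of autism
    spectrum disorder in a consanguineous cohort for a worked end-to-end
    example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    GenomeInfoDb,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: SNP, GenomeWideAssociation, VariantDetection, Genetics,
    HomozygosityMapping
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'coordinates.R'
    'annotate.R'
    'association.R'
    'genotype-io.R'
    'methods.R'
    'pedigree-filter.R'
    'roh-caller.R'
    'simulate.R'
    'pipeline.R'
    'recurrence.R'
    'rohmap-package.R'
    'study-fixtures.R'
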