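#' @include AllClasses.R simulate.R roh-caller.R pedigree-filter.R
#'   recurrence.R annotate.R association.R study-fixtures.R
NULL

#' Pipeline configuration
#'
#' A flat, file-serialisable set of parameters driving [runPipeline()].
#' Either a PED/MAP pair is named as input, or a cohort is simulated from
#' the scalar simulation settings. The configuration round-trips through
#' JSON losslessly ([readPipelineConfig()] / [writePipelineConfig()]).
#'
#' @param pedPath,mapPath optional PED/MAP input; when `NULL` a cohort is
#'   simulated.
#' @param genesPath optional BED/GFF3 gene set for region annotation;
#'   `NULL` skips annotation.
#' @param variantPath optional single-variant genotype table/VCF for the
#'   association stage; requires a `group` column with exactly two groups
#'   or the `groups` pair below.
#' @param groups character pair naming the two groups to compare at the
#'   variant (default `c("family_cohort", "controls")` style labels are
#'   taken from the variant table).
#' @param seed integer seed controlling simulation.
#' @param nFamilies,childrenPerFamily,affectedPerFamily,nMarkers,nChroms,
#'   markerSpacingBp,plantedSegmentsPerAffected,plantedLengthMinBp,
#'   plantedLengthMaxBp,hetErrorRate,missingRate,backgroundRohRate scalar
#'   simulation settings (see [SimConfig-class]).
#' @param rohParams a [RohParams-class].
#' @param filterPolicy a [FilterPolicy-class].
#' @param k,countBy recurrence threshold and counting unit
#'   (see [recurrentRegions()]).
#' @return a named list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(pedPath = NULL, mapPath = NULL, genesPath = NULL,
                           variantPath = NULL, groups = NULL, seed = 1L,
                           nFamilies = 36L, childrenPerFamily = 2L,
                           affectedPerFamily = 1L, nMarkers = 3000L,
                           nChroms = 4L, markerSpacingBp = 5000,
                           plantedSegmentsPerAffected = 2L,
                           plantedLengthMinBp = 1e6, plantedLengthMaxBp = 3e6,
                           hetErrorRate = 0.001, missingRate = 0.01,
                           backgroundRohRate = 1,
                           rohParams = RohParams(),
                           filterPolicy = FilterPolicy(),
                           k = 5L, countBy = "individuals") {
    cfg <- list(pedPath = pedPath, mapPath = mapPath, genesPath = genesPath,
                variantPath = variantPath, groups = groups,
                seed = as.integer(seed),
                nFamilies = as.integer(nFamilies),
                childrenPerFamily = as.integer(childrenPerFamily),
                affectedPerFamily = as.integer(affectedPerFamily),
                nMarkers = as.integer(nMarkers),
                nChroms = as.integer(nChroms),
                markerSpacingBp = markerSpacingBp,
                plantedSegmentsPerAffected = as.integer(plantedSegmentsPerAffected),
                plantedLengthMinBp = plantedLengthMinBp,
                plantedLengthMaxBp = plantedLengthMaxBp,
                hetErrorRate = hetErrorRate, missingRate = missingRate,
                backgroundRohRate = backgroundRohRate,
                windowMarkers = rohParams@windowMarkers,
                maxHetPerWindow = rohParams@maxHetPerWindow,
                maxMissingPerWindow = rohParams@maxMissingPerWindow,
                hitFraction = rohParams@hitFraction,
                minRunMarkers = rohParams@minRunMarkers,
                minRunLengthBp = rohParams@minRunLengthBp,
                maxInternalGapBp = rohParams@maxInternalGapBp,
                excludeAgainst = filterPolicy@excludeAgainst,
                overlapRule = filterPolicy@overlapRule,
                reciprocalFraction = filterPolicy@reciprocalFraction,
                k = as.integer(k), countBy = countBy)
    class(cfg) <- c("PipelineConfig", "list")
    cfg
}

#' @rdname pipelineConfig
#' @param path JSON file path.
#' @export
writePipelineConfig <- function(config, path) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null",
                         pretty = TRUE)
    invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    fields <- c("pedPath", "mapPath", "genesPath", "variantPath", "groups",
                "seed", "nFamilies", "childrenPerFamily",
                "affectedPerFamily", "nMarkers", "nChroms",
                "markerSpacingBp", "plantedSegmentsPerAffected",
                "plantedLengthMinBp", "plantedLengthMaxBp", "hetErrorRate",
                "missingRate", "backgroundRohRate", "k", "countBy")
    given <- stats::setNames(lapply(fields, function(f) raw[[f]]), fields)
    given <- given[!vapply(given, is.null, logical(1))]
    do.call(pipelineConfig, c(
        given,
        list(rohParams = RohParams(
                 windowMarkers = as.integer(raw$windowMarkers),
                 maxHetPerWindow = as.integer(raw$maxHetPerWindow),
                 maxMissingPerWindow = as.integer(raw$maxMissingPerWindow),
                 hitFraction = raw$hitFraction,
                 minRunMarkers = as.integer(raw$minRunMarkers),
                 minRunLengthBp = as.integer(raw$minRunLengthBp),
                 maxInternalGapBp = as.integer(raw$maxInternalGapBp)),
             filterPolicy = FilterPolicy(
                 excludeAgainst = raw$excludeAgainst,
                 overlapRule = raw$overlapRule,
                 reciprocalFraction = if (is.null(raw$reciprocalFraction))
                     NA_real_ else raw$reciprocalFraction))))
}

.simConfigFrom <- function(cfg) {
    lo <- cfg$plantedLengthMinBp
    hi <- cfg$plantedLengthMaxBp
    SimConfig(nFamilies = cfg$nFamilies,
              childrenPerFamily = cfg$childrenPerFamily,
              affectedPerFamily = cfg$affectedPerFamily,
              nMarkers = cfg$nMarkers, nChroms = cfg$nChroms,
              markerSpacingBp = cfg$markerSpacingBp,
              plantedSegmentsPerAffected = cfg$plantedSegmentsPerAffected,
              plantedLengthSampler = function(n) stats::runif(n, lo, hi),
              hetErrorRate = cfg$hetErrorRate,
              missingRate = cfg$missingRate,
              backgroundRohRate = cfg$backgroundRohRate,
              seed = cfg$seed)
}

.rohParamsFrom <- function(cfg) {
    RohParams(windowMarkers = as.integer(cfg$windowMarkers),
              maxHetPerWindow = as.integer(cfg$maxHetPerWindow),
              maxMissingPerWindow = as.integer(cfg$maxMissingPerWindow),
              hitFraction = cfg$hitFraction,
              minRunMarkers = as.integer(cfg$minRunMarkers),
              minRunLengthBp = as.integer(cfg$minRunLengthBp),
              maxInternalGapBp = as.integer(cfg$maxInternalGapBp))
}

.policyFrom <- function(cfg) {
    FilterPolicy(excludeAgainst = cfg$excludeAgainst,
                 overlapRule = cfg$overlapRule,
                 reciprocalFraction = if (is.null(cfg$reciprocalFraction))
                     NA_real_ else cfg$reciprocalFraction)
}

.stageFail <- function(stage, ...) {
    stop("stage '", stage, "': ", ..., call. = FALSE)
}

#' Run the homozygosity-mapping pipeline end to end
#'
#' Orchestrates simulate (or load) -> call ROH -> recessive family filter
#' -> recurrent regions -> gene annotation -> single-variant association,
#' writing each stage's output plus a JSON manifest (input checksums,
#' parameters, package version) to `outDir`. With an identical
#' configuration and seed, a rerun reproduces byte-identical outputs. A
#' failing stage aborts with an error naming the stage.
#'
#' @param config a `"PipelineConfig"` from [pipelineConfig()].
#' @param outDir output directory, created if needed.
#' @param quiet suppress stage progress messages.
#' @return invisibly, a list with the in-memory stage results (`cohort`,
#'   `truth`, `segments`, `unique`, `regions`, `association`) and the
#'   manifest.
#' @export
runPipeline <- function(config, outDir, quiet = FALSE) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    note <- function(...) if (!quiet) message("[rohmap] ", ...)
    inputs <- character()

    ## stage: input
    truth <- NULL
    if (!is.null(config$pedPath)) {
        for (p in c(config$pedPath, config$mapPath))
            if (is.null(p) || !file.exists(p))
                .stageFail("input", "missing input file: ",
                           if (is.null(p)) "(mapPath unset)" else p)
        note("input: reading ", config$pedPath)
        cohort <- tryCatch(readGenotypes(config$pedPath, config$mapPath),
                           error = function(e)
                               .stageFail("input", conditionMessage(e)))
        inputs <- c(inputs, config$pedPath, config$mapPath)
    } else {
        note("input: simulating cohort (seed ", config$seed, ")")
        sim <- simulateCohort(.simConfigFrom(config))
        cohort <- sim$cohort
        truth <- sim$truth
        writeGenotypes(cohort, file.path(outDir, "cohort.ped"),
                       file.path(outDir, "cohort.map"))
        tb <- truth
        mcols(tb) <- NULL
        mcols(tb)$name <- truth$sampleId
        writeIntervals(tb, file.path(outDir, "truth.bed"))
    }
    ped <- pedigree(cohort)

    ## stage: call-roh
    note("call-roh: ", ncol(cohort), " samples")
    params <- .rohParamsFrom(config)
    segments <- tryCatch(callRohCohort(cohort, params),
                         error = function(e)
                             .stageFail("call-roh", conditionMessage(e)))
    segBed <- segments
    mcols(segBed) <- NULL
    mcols(segBed)$name <- segments$sampleId
    mcols(segBed)$score <- segments$nMarkers
    writeIntervals(segBed, file.path(outDir, "segments.bed"))

    ## stage: filter
    policy <- .policyFrom(config)
    uniq <- tryCatch(uniqueRoh(segments, ped, policy),
                     error = function(e)
                         .stageFail("filter", conditionMessage(e)))
    note("filter: ", length(uniq), " of ", length(segments),
         " segments unique to affecteds")
    uqBed <- uniq
    mcols(uqBed) <- NULL
    mcols(uqBed)$name <- uniq$sampleId
    mcols(uqBed)$score <- uniq$nMarkers
    writeIntervals(uqBed, file.path(outDir, "unique.bed"))

    ## stage: recur
    regions <- tryCatch(
        recurrentRegions(uniq, k = config$k, countBy = config$countBy,
                         ped = ped),
        error = function(e) .stageFail("recur", conditionMessage(e)))
    note("recur: ", length(regions), " regions with support >= ", config$k)

    ## stage: annotate
    geneCol <- rep("", length(regions))
    if (!is.null(config$genesPath)) {
        if (!file.exists(config$genesPath))
            .stageFail("annotate", "missing gene file: ", config$genesPath)
        genes <- tryCatch(loadGenes(config$genesPath),
                          error = function(e)
                              .stageFail("annotate", conditionMessage(e)))
        inputs <- c(inputs, config$genesPath)
        if (length(regions))
            geneCol <- vapply(seq_along(regions), function(i)
                paste(genesInRegion(regions[i], genes), collapse = ","),
                character(1))
    }
    regTab <- data.frame(
        chrom = as.character(seqnames(regions)),
        start_bp = start(regions), end_bp = end(regions),
        length_kb = if (length(regions)) regions$lengthKb else integer(),
        support_individuals = if (length(regions))
            regions$supportIndividuals else integer(),
        support_families = if (length(regions))
            regions$supportFamilies else integer(),
        samples = if (length(regions))
            vapply(regions$supportSamples, paste, character(1),
                   collapse = ",") else character(),
        genes = if (length(regions)) geneCol else character())
    utils::write.table(regTab, file.path(outDir, "regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    ## stage: assoc
    assoc <- NULL
    if (!is.null(config$variantPath)) {
        if (!file.exists(config$variantPath))
            .stageFail("assoc", "missing variant file: ", config$variantPath)
        calls <- tryCatch(readVariantGenotypes(config$variantPath),
                          error = function(e)
                              .stageFail("assoc", conditionMessage(e)))
        inputs <- c(inputs, config$variantPath)
        if (!"group" %in% colnames(calls))
            .stageFail("assoc", "variant table lacks a 'group' column")
        grp <- config$groups
        if (is.null(grp))
            grp <- utils::head(unique(calls$group), 2L)
        if (length(grp) != 2L || !all(grp %in% calls$group))
            .stageFail("assoc", "need two groups present in the table")
        ta <- genotypeTable(calls[calls$group == grp[1L], ], grp[1L])
        tb <- genotypeTable(calls[calls$group == grp[2L], ], grp[2L])
        gChi <- pearsonChi2(genotypeCountMatrix(ta, tb))
        aChi <- pearsonChi2(alleleCountMatrix(ta, tb))
        assoc <- data.frame(
            group = c(grp, "genotype_test", "allele_test"),
            nNN = c(ta@nNN, tb@nNN, NA, NA),
            nNV = c(ta@nNV, tb@nNV, NA, NA),
            nVV = c(ta@nVV, tb@nVV, NA, NA),
            freqV = c(alleleFreqs(ta)[["freqV"]], alleleFreqs(tb)[["freqV"]],
                      NA, NA),
            carriers = c(carrierCount(ta), carrierCount(tb), NA, NA),
            chi2 = c(NA, NA, gChi$statistic, aChi$statistic),
            df = c(NA, NA, gChi$df, aChi$df),
            p = c(NA, NA, gChi$p.value, aChi$p.value))
        utils::write.table(assoc, file.path(outDir, "association.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        note("assoc: genotype chi2 = ", sprintf("%.4f", gChi$statistic))
    }

    ## manifest: parameters + checksums (no timestamps, for reproducibility)
    outFiles <- sort(list.files(outDir, full.names = FALSE))
    outFiles <- setdiff(outFiles, "manifest.json")
    manifest <- list(
        package = "rohmap",
        version = as.character(utils::packageVersion("rohmap")),
        config = unclass(config),
        inputMd5 = as.list(tools::md5sum(unique(inputs))),
        outputMd5 = as.list(tools::md5sum(file.path(outDir, outFiles))))
    names(manifest$outputMd5) <- outFiles
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    invisible(list(cohort = cohort, truth = truth, segments = segments,
                   unique = uniq, regions = regions, association = assoc,
                   manifest = manifest))
}

#' Recompute the packaged study tables
#'
#' Recomputes, from the packaged fixtures alone, every summary quantity the
#' package's methods can derive: per-locus kb lengths from the half-open
#' coordinates, support in individuals and families from the patient lists
#' and cohort pedigree, gene content from the packaged gene set, group
#' genotype tables with allele frequencies and carrier counts from the
#' individual-level genotype fixture, and the genotype- and allele-level
#' chi-square comparisons of the 106-member family cohort against the 100
#' controls. Printed values carried by the fixtures sit side by side with
#' the recomputed ones.
#'
#' @return a list of data.frames: `loci` (per-locus lengths, support,
#'   genes), `genotypes` (per-group counts, frequencies, carriers) and
#'   `tests` (chi-square statistics, df, p).
#' @examples
#' recomputeStudyTables()$loci
#' @export
recomputeStudyTables <- function() {
    loci <- studyLoci()
    ped <- studyPedigree()
    genes <- studyGenes()
    sup <- t(vapply(loci$patients, function(p)
        supportCounts(strsplit(p, ",")[[1L]], ped),
        c(individuals = 0L, families = 0L)))
    regions <- genomicIntervals(loci$chrom, loci$start_bp, loci$end_bp)
    lociOut <- data.frame(
        locus = loci$locus,
        length_kb = lengthKb(regions),
        printed_length_kb = loci$printed_length_kb,
        support_individuals = sup[, "individuals"],
        support_families = sup[, "families"],
        genes = vapply(seq_along(regions), function(i)
            paste(genesInRegion(regions[i], genes), collapse = ","),
            character(1)),
        listed_genes = loci$genes,
        row.names = NULL)

    calls <- studyVariantGenotypes()
    groups <- c("patients", "parents", "siblings", "controls")
    tabs <- lapply(groups, function(g)
        genotypeTable(calls[calls$group == g, ], g))
    names(tabs) <- groups
    fam <- calls$group %in% c("patients", "parents", "siblings")
    tabs$family_cohort <- genotypeTable(calls[fam, ], "family_cohort")
    printed <- studyGenotypeCounts()
    genoOut <- do.call(rbind, lapply(names(tabs), function(g) {
        tt <- tabs[[g]]
        af <- alleleFreqs(tt)
        data.frame(group = g, n = nSamples(tt), nNN = tt@nNN, nNV = tt@nNV,
                   nVV = tt@nVV, freqN = af[["freqN"]],
                   freqV = af[["freqV"]], carriers = carrierCount(tt),
                   pctVV = 100 * tt@nVV / nSamples(tt),
                   counts_match_printed = identical(
                       c(tt@nNN, tt@nNV, tt@nVV),
                       c(printed[[g]]@nNN, printed[[g]]@nNV,
                         printed[[g]]@nVV)),
                   row.names = NULL)
    }))

    gChi <- pearsonChi2(genotypeCountMatrix(tabs$family_cohort,
                                            tabs$controls))
    aChi <- pearsonChi2(alleleCountMatrix(tabs$family_cohort,
                                          tabs$controls))
    tests <- data.frame(
        test = c("genotype_3x2", "allele_2x2"),
        chi2 = c(gChi$statistic, aChi$statistic),
        df = c(gChi$df, aChi$df),
        p = c(gChi$p.value, aChi$p.value))
    list(loci = lociOut, genotypes = genoOut, tests = tests)
}
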