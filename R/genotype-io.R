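#' @include AllClasses.R coordinates.R
NULL

.SEX_CODES <- c("0" = "unknown", "1" = "male", "2" = "female")
.PHENO_CODES <- c("0" = "unknown", "-9" = "unknown",
                  "1" = "unaffected", "2" = "affected")

.validatePedigree <- function(ped) {
    dup <- ped$sampleId[duplicated(ped$sampleId)]
    if (length(dup))
        stop("duplicate sample id in pedigree: ", paste(unique(dup), collapse = ", "))
    for (i in seq_len(nrow(ped))) {
        for (par in c(ped$fatherId[i], ped$motherId[i])) {
            if (is.na(par))
                next
            hit <- ped$sampleId == par & ped$familyId == ped$familyId[i]
            if (!any(hit))
                stop("pedigree parent '", par, "' of sample '",
                     ped$sampleId[i], "' not found in family '",
                     ped$familyId[i], "'")
        }
    }
    invisible(ped)
}

#' Read and write pedigree files
#'
#' Reads the whitespace-delimited six-column pedigree dialect
#' (family, sample, father, mother, sex, phenotype) shared by PED files;
#' extra columns (genotypes) are ignored. `"0"` denotes an absent parent;
#' sex is coded 1 = male, 2 = female, 0 = unknown; phenotype 2 = affected,
#' 1 = unaffected, 0 or -9 = unknown. Parse order is preserved. Duplicate
#' sample ids and parent ids that do not resolve within the same family are
#' hard errors.
#'
#' @param path pedigree file path.
#' @return a `data.frame` with columns `familyId`, `sampleId`, `fatherId`,
#'   `motherId` (NA when absent), `sex` and `phenotype` as factors-free
#'   character columns.
#' @export
readPedigree <- function(path) {
    tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                             colClasses = "character")
    if (ncol(tab) < 6L)
        stop("pedigree file must have at least 6 columns: ", path)
    ped <- data.frame(familyId = tab[[1L]], sampleId = tab[[2L]],
                      fatherId = ifelse(tab[[3L]] == "0", NA, tab[[3L]]),
                      motherId = ifelse(tab[[4L]] == "0", NA, tab[[4L]]),
                      sex = unname(.SEX_CODES[tab[[5L]]]),
                      phenotype = unname(.PHENO_CODES[tab[[6L]]]),
                      stringsAsFactors = FALSE)
    if (anyNA(ped$sex))
        stop("unrecognised sex code in ", path)
    if (anyNA(ped$phenotype))
        stop("unrecognised phenotype code in ", path)
    .validatePedigree(ped)
}

#' @rdname readPedigree
#' @param ped a pedigree `data.frame` as returned by `readPedigree()`.
#' @export
writePedigree <- function(ped, path) {
    .validatePedigree(ped)
    sex <- c(unknown = "0", male = "1", female = "2")[ped$sex]
    phe <- c(unknown = "0", unaffected = "1", affected = "2")[ped$phenotype]
    lines <- paste(ped$familyId, ped$sampleId,
                   ifelse(is.na(ped$fatherId), "0", ped$fatherId),
                   ifelse(is.na(ped$motherId), "0", ped$motherId),
                   sex, phe, sep = "\t")
    writeLines(lines, path)
    invisible(path)
}

.pedToColData <- function(ped) {
    DataFrame(familyId = ped$familyId, fatherId = ped$fatherId,
              motherId = ped$motherId, sex = ped$sex,
              phenotype = ped$phenotype, row.names = ped$sampleId)
}

#' Assemble a GenotypeCohort from its parts
#'
#' @param markerMap a point `GRanges` with metadata columns `markerId`,
#'   `alleleA`, `alleleB`, `freqB`, ordered by (chromosome, position).
#' @param ped pedigree `data.frame` (see [readPedigree()]).
#' @param callMatrix integer matrix, markers x samples, coded
#'   0/1/2/NA for HOM_A/HET/HOM_B/MISSING.
#' @return a [GenotypeCohort-class] object.
#' @export
GenotypeCohort <- function(markerMap, ped, callMatrix) {
    .validatePedigree(ped)
    stopifnot(nrow(callMatrix) == length(markerMap),
              ncol(callMatrix) == nrow(ped))
    storage.mode(callMatrix) <- "integer"
    dimnames(callMatrix) <- list(mcols(markerMap)$markerId, ped$sampleId)
    se <- SummarizedExperiment(assays = list(calls = callMatrix),
                               rowRanges = markerMap,
                               colData = .pedToColData(ped))
    new("GenotypeCohort", se)
}

#' Read and write PED/MAP genotype files
#'
#' `readGenotypes()` parses a matching PED/MAP pair into a
#' [GenotypeCohort-class]. The MAP file has either the classical four
#' columns (chrom, marker, cM, bp) — in which case the A/B allele labels
#' are taken as the alphabetically first/second allele observed in the data
#' and `freqB` as the observed B-allele frequency — or six columns with
#' explicit `alleleA`/`alleleB` labels (the dialect `writeGenotypes()`
#' emits, which makes a write/read round trip the identity on every call).
#' Genotypes `0 0` map to MISSING; a marker showing more than two distinct
#' alleles is a hard error. Markers arriving out of (chrom, position) order
#' are sorted with a warning.
#'
#' @param pedPath,mapPath paths to the PED and MAP files.
#' @return `readGenotypes()` returns a `GenotypeCohort`.
#' @export
readGenotypes <- function(pedPath, mapPath) {
    map <- utils::read.table(mapPath, header = FALSE, comment.char = "#",
                             colClasses = "character")
    if (!ncol(map) %in% c(4L, 6L))
        stop("MAP file must have 4 or 6 columns: ", mapPath)
    ord <- order(map[[1L]], as.integer(map[[4L]]))
    sortedIn <- identical(ord, seq_along(ord))
    if (!sortedIn) {
        warning("MAP markers not sorted by (chrom, pos); sorting")
        map <- map[ord, , drop = FALSE]
    }
    chrom <- map[[1L]]
    markerId <- map[[2L]]
    pos <- as.integer(map[[4L]])
    ped <- readPedigree(pedPath)
    tab <- utils::read.table(pedPath, header = FALSE, comment.char = "#",
                             colClasses = "character")
    nmark <- nrow(map)
    if (ncol(tab) != 6L + 2L * nmark)
        stop("PED file has ", ncol(tab) - 6L, " allele columns; expected ",
             2L * nmark)
    a1 <- as.matrix(tab[, 6L + 2L * seq_len(nmark) - 1L, drop = FALSE])
    a2 <- as.matrix(tab[, 6L + 2L * seq_len(nmark), drop = FALSE])
    if (!sortedIn) {
        a1 <- a1[, ord, drop = FALSE]
        a2 <- a2[, ord, drop = FALSE]
    }
    callMat <- matrix(NA_integer_, nrow = nmark, ncol = nrow(ped))
    alleleA <- character(nmark)
    alleleB <- character(nmark)
    freqB <- numeric(nmark)
    for (j in seq_len(nmark)) {
        g1 <- a1[, j]; g2 <- a2[, j]
        miss <- g1 == "0" | g2 == "0"
        obs <- sort(unique(c(g1[!miss], g2[!miss])))
        if (length(obs) > 2L)
            stop("marker ", markerId[j], " has more than 2 alleles: ",
                 paste(obs, collapse = ","))
        if (ncol(map) == 6L) {
            A <- map[[5L]][j]; B <- map[[6L]][j]
            if (length(setdiff(obs, c(A, B))))
                stop("marker ", markerId[j],
                     " has alleles absent from MAP columns 5-6")
        } else {
            A <- if (length(obs) >= 1L) obs[1L] else "A"
            B <- if (length(obs) == 2L) obs[2L] else "B"
        }
        dose <- (g1 == B) + (g2 == B)
        dose[miss] <- NA_integer_
        callMat[j, ] <- as.integer(dose)
        alleleA[j] <- A
        alleleB[j] <- B
        nb <- sum(dose, na.rm = TRUE)
        nn <- 2L * sum(!is.na(dose))
        freqB[j] <- if (nn > 0L) nb / nn else NA_real_
    }
    mm <- GRanges(chrom, IRanges(pos, pos),
                  markerId = markerId, alleleA = alleleA,
                  alleleB = alleleB, freqB = freqB)
    GenotypeCohort(mm, ped, callMat)
}

#' @rdname readGenotypes
#' @param cohort a `GenotypeCohort` to serialise.
#' @export
writeGenotypes <- function(cohort, pedPath, mapPath) {
    mm <- markers(cohort)
    mc <- mcols(mm)
    map <- paste(as.character(seqnames(mm)), mc$markerId, "0",
                 format(start(mm), scientific = FALSE, trim = TRUE),
                 mc$alleleA, mc$alleleB, sep = "\t")
    writeLines(map, mapPath)
    ped <- pedigree(cohort)
    cm <- calls(cohort)
    sex <- c(unknown = "0", male = "1", female = "2")[ped$sex]
    phe <- c(unknown = "0", unaffected = "1", affected = "2")[ped$phenotype]
    lines <- vapply(seq_len(nrow(ped)), function(i) {
        g <- cm[, i]
        g1 <- ifelse(is.na(g), "0", ifelse(g == 2L, mc$alleleB, mc$alleleA))
        g2 <- ifelse(is.na(g), "0", ifelse(g >= 1L, mc$alleleB, mc$alleleA))
        paste(c(ped$familyId[i], ped$sampleId[i],
                ifelse(is.na(ped$fatherId[i]), "0", ped$fatherId[i]),
                ifelse(is.na(ped$motherId[i]), "0", ped$motherId[i]),
                sex[i], phe[i], rbind(g1, g2)), collapse = "\t")
    }, character(1))
    writeLines(lines, pedPath)
    invisible(c(ped = pedPath, map = mapPath))
}

.GT_MAP <- c("0/0" = "NN", "0|0" = "NN",
             "0/1" = "NV", "1/0" = "NV", "0|1" = "NV", "1|0" = "NV",
             "1/1" = "VV", "1|1" = "VV",
             "./." = "MISSING", ".|." = "MISSING", "." = "MISSING")

#' Read single-variant genotype calls
#'
#' Reads per-sample genotypes at one biallelic variant, either from a VCF
#' holding exactly one record (GT fields `0/0`, `0/1`, `1/1`, `./.` map to
#' NN, NV, VV, MISSING; N is the reference allele, V the alternate) or from
#' a whitespace/tab table whose first two columns are sample id and genotype
#' symbol, with an optional third `group` column. Multiallelic VCF records
#' are a hard error.
#'
#' @param path a `.vcf` file or a genotype table.
#' @return a `data.frame` with columns `sampleId`, `genotype`
#'   (NN/NV/VV/MISSING) and, when present in the input, `group`.
#' @export
readVariantGenotypes <- function(path) {
    if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
        vcf <- vcfR::read.vcfR(path, verbose = FALSE)
        if (nrow(vcf@gt) != 1L)
            stop("expected exactly one variant record, found ", nrow(vcf@gt))
        alt <- vcf@fix[1L, "ALT"]
        if (grepl(",", alt))
            stop("multiallelic record (ALT = ", alt, ") is not supported")
        gt <- vcfR::extract.gt(vcf, element = "GT")
        sym <- unname(.GT_MAP[gt[1L, ]])
        sym[is.na(sym)] <- "MISSING"
        data.frame(sampleId = colnames(gt), genotype = sym,
                   stringsAsFactors = FALSE)
    } else {
        tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                                 colClasses = "character")
        if (ncol(tab) < 2L)
            stop("genotype table needs columns sample, genotype: ", path)
        bad <- setdiff(unique(tab[[2L]]), c("NN", "NV", "VV", "MISSING"))
        if (length(bad))
            stop("unrecognised genotype symbol(s): ",
                 paste(bad, collapse = ", "))
        out <- data.frame(sampleId = tab[[1L]], genotype = tab[[2L]],
                          stringsAsFactors = FALSE)
        if ("group" %in% colnames(tab))
            out$group <- tab$group
        out
    }
}

#' @rdname readVariantGenotypes
#' @param callsDf a `data.frame` as returned by `readVariantGenotypes()`.
#' @export
writeVariantGenotypes <- function(callsDf, path) {
    utils::write.table(callsDf, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
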