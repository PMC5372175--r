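#' @include AllClasses.R
NULL

#' Tally single-variant genotypes for one group
#'
#' Counts NN, NV and VV calls into a [GenotypeTable-class]. MISSING calls
#' are excluded from the tally; their number is reported via `message()`.
#'
#' @param calls a character vector of genotype symbols
#'   (NN/NV/VV/MISSING), or a `data.frame` from [readVariantGenotypes()].
#' @param group label for the group.
#' @return a [GenotypeTable-class].
#' @examples
#' genotypeTable(c("NN", "NV", "VV", "NV"), "demo")
#' @export
genotypeTable <- function(calls, group = "group") {
    if (is.data.frame(calls))
        calls <- calls$genotype
    bad <- setdiff(unique(calls), c("NN", "NV", "VV", "MISSING"))
    if (length(bad))
        stop("unrecognised genotype symbol(s): ", paste(bad, collapse = ", "))
    nMiss <- sum(calls == "MISSING")
    if (nMiss > 0L)
        message(nMiss, " MISSING call(s) excluded from group '", group, "'")
    GenotypeTable(group = group,
                  nNN = sum(calls == "NN"),
                  nNV = sum(calls == "NV"),
                  nVV = sum(calls == "VV"))
}

#' Genotype and allele contingency matrices for two groups
#'
#' `genotypeCountMatrix()` stacks the NN/NV/VV counts of two groups into a
#' 3x2 matrix (rows genotypes, columns groups). `alleleCountMatrix()`
#' collapses genotypes to allele counts: per group the N count is
#' `2 nNN + nNV` and the V count `nNV + 2 nVV`, so each column sums to
#' twice the group size.
#'
#' @param a,b [GenotypeTable-class] objects; both groups must be non-empty.
#' @return an integer matrix suitable for [pearsonChi2()].
#' @export
genotypeCountMatrix <- function(a, b) {
    if (nSamples(a) == 0L || nSamples(b) == 0L)
        stop("both groups must be non-empty")
    m <- cbind(c(a@nNN, a@nNV, a@nVV), c(b@nNN, b@nNV, b@nVV))
    dimnames(m) <- list(c("NN", "NV", "VV"), c(a@group, b@group))
    m
}

#' @rdname genotypeCountMatrix
#' @export
alleleCountMatrix <- function(a, b) {
    if (nSamples(a) == 0L || nSamples(b) == 0L)
        stop("both groups must be non-empty")
    m <- cbind(c(2L * a@nNN + a@nNV, a@nNV + 2L * a@nVV),
               c(2L * b@nNN + b@nNV, b@nNV + 2L * b@nVV))
    dimnames(m) <- list(c("N", "V"), c(a@group, b@group))
    m
}

#' Pearson chi-square test of independence
#'
#' The classical test on an r x c contingency table, without continuity
#' correction: expected counts are `rowSum * colSum / total`, the statistic
#' is `sum((O - E)^2 / E)` with `(r-1)(c-1)` degrees of freedom, and the
#' p-value is the upper tail of the chi-square distribution (the
#' regularised upper incomplete gamma function; for df = 2 it reduces to
#' the closed form `exp(-x/2)`). A zero row or column margin is a hard
#' error naming the offending margin. Expected cells below 5 set
#' `smallExpectedWarning`.
#'
#' @param observed numeric matrix of counts (at least 2x2).
#' @return an object of class `"ChiSquareResult"`: a list with elements
#'   `statistic`, `df`, `p.value`, `expected`, `observed` and
#'   `smallExpectedWarning`.
#' @examples
#' pearsonChi2(matrix(c(32, 44, 30, 34, 50, 16), nrow = 3))
#' @export
pearsonChi2 <- function(observed) {
    observed <- as.matrix(observed)
    if (nrow(observed) < 2L || ncol(observed) < 2L)
        stop("contingency table must be at least 2x2")
    if (any(observed < 0))
        stop("counts must be non-negative")
    rs <- rowSums(observed)
    cs <- colSums(observed)
    if (any(rs == 0))
        stop("zero row margin: ",
             paste(which(rs == 0), collapse = ", "))
    if (any(cs == 0))
        stop("zero column margin: ",
             paste(which(cs == 0), collapse = ", "))
    expected <- outer(rs, cs) / sum(observed)
    stat <- sum((observed - expected)^2 / expected)
    df <- (nrow(observed) - 1L) * (ncol(observed) - 1L)
    structure(list(statistic = stat,
                   df = df,
                   p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                   expected = expected,
                   observed = observed,
                   smallExpectedWarning = any(expected < 5)),
              class = "ChiSquareResult")
}

#' @rdname pearsonChi2
#' @param statistic chi-square statistic value(s).
#' @param df degrees of freedom.
#' @details `pearsonChi2FromStat()` exposes the upper-tail function used
#'   for the p-value — the regularised upper incomplete gamma function
#'   `Q(df/2, x/2)` — so it can be checked directly against closed forms
#'   (for df = 2, `exp(-x/2)`).
#' @export
pearsonChi2FromStat <- function(statistic, df) {
    stats::pchisq(statistic, df, lower.tail = FALSE)
}

#' @export
print.ChiSquareResult <- function(x, ...) {
    cat(sprintf("Pearson chi-square: X^2 = %.4f, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p.value))
    if (x$smallExpectedWarning)
        cat("  note: at least one expected cell < 5\n")
    invisible(x)
}

#' Hardy-Weinberg equilibrium goodness of fit (auxiliary)
#'
#' A one-degree-of-freedom chi-square goodness-of-fit of a group's NN/NV/VV
#' counts against the Hardy-Weinberg proportions implied by its own allele
#' frequencies. This is an auxiliary diagnostic offered alongside the
#' case-control comparison, not part of it.
#'
#' @param x a [GenotypeTable-class].
#' @return a `"ChiSquareResult"` (df = 1).
#' @export
hweTest <- function(x) {
    n <- nSamples(x)
    if (n == 0L)
        stop("empty genotype table")
    q <- alleleFreqs(x)[["freqV"]]
    expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    observed <- c(x@nNN, x@nNV, x@nVV)
    stat <- sum((observed - expected)^2 / expected)
    structure(list(statistic = stat,
                   df = 1L,
                   p.value = stats::pchisq(stat, 1L, lower.tail = FALSE),
                   expected = matrix(expected, nrow = 1,
                                     dimnames = list(NULL, c("NN", "NV", "VV"))),
                   observed = matrix(observed, nrow = 1,
                                     dimnames = list(NULL, c("NN", "NV", "VV"))),
                   smallExpectedWarning = any(expected < 5)),
              class = "ChiSquareResult")
}
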