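#' Accessors for haplorisk classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `sampleIds()` returns sample identifiers, `variantInfo()` the variant
#' descriptor table, `nVariants()`/`nSamplesOf()` dimensions,
#' `alleleMatrix()` one of the two haploid allele matrices, `haplotypeNames()`
#' the haplotype labels, `frequencies()` the frequency table,
#' `majorHaplotype()` the control-group major haplotype, and
#' `marginalPosteriors()` the per-variant causal posteriors.
#'
#' @param x a haplorisk object.
#' @param which for `alleleMatrix()`, `"A"` or `"B"` (left/right of `|`).
#' @return The requested component (vector, matrix or data.frame).
#' @name accessors
#' @aliases sampleIds variantInfo nVariants nSamplesOf alleleMatrix
#'   haplotypeNames frequencies majorHaplotype marginalPosteriors
#' @examples
#' pool <- HaplotypePool(
#'   variants = data.frame(id = "v1", chrom = "19", pos = 1L,
#'                         ref = "A", alt = "C"),
#'   haplotypes = c(H1 = "0", H2 = "1"),
#'   frequencies = c(H1 = 0.7, H2 = 0.3))
#' haplotypeNames(pool)
#' frequencies(pool)
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setGeneric("nSamplesOf", function(x) standardGeneric("nSamplesOf"))
#' @rdname accessors
#' @export
setGeneric("alleleMatrix", function(x, which = c("A", "B"))
    standardGeneric("alleleMatrix"))
#' @rdname accessors
#' @export
setGeneric("haplotypeNames", function(x) standardGeneric("haplotypeNames"))
#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setGeneric("majorHaplotype", function(x) standardGeneric("majorHaplotype"))
#' @rdname accessors
#' @export
setGeneric("marginalPosteriors", function(x)
    standardGeneric("marginalPosteriors"))

## ---- HaplotypePool ----

#' @rdname accessors
#' @export
setMethod("variantInfo", "HaplotypePool", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("nVariants", "HaplotypePool", function(x) nrow(x@variants))
#' @rdname accessors
#' @export
setMethod("haplotypeNames", "HaplotypePool", function(x) rownames(x@haplotypes))
#' @rdname accessors
#' @export
setMethod("frequencies", "HaplotypePool", function(x) x@frequencies)

setMethod("show", "HaplotypePool", function(object) {
    cat("HaplotypePool:", nrow(object@haplotypes), "haplotypes x",
        nrow(object@variants), "variants;",
        ncol(object@frequencies), "population(s):",
        paste(colnames(object@frequencies), collapse = ", "), "\n")
})

## ---- PhasedGenotypes ----

#' @rdname accessors
#' @export
setMethod("sampleIds", "PhasedGenotypes", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("variantInfo", "PhasedGenotypes", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("nVariants", "PhasedGenotypes", function(x) nrow(x@variants))
#' @rdname accessors
#' @export
setMethod("nSamplesOf", "PhasedGenotypes", function(x) length(x@samples))
#' @rdname accessors
#' @export
setMethod("alleleMatrix", "PhasedGenotypes", function(x, which = c("A", "B")) {
    which <- match.arg(which)
    if (which == "A") x@hapA else x@hapB
})

#' Subset phased genotypes
#'
#' `x[i, j]` keeps variants `i` (index, logical or variant id) and samples `j`
#' (index, logical or sample id).
#'
#' @param x a [PhasedGenotypes-class] object.
#' @param i,j variant and sample selectors.
#' @param ... ignored.
#' @param drop ignored (always `FALSE`).
#' @return A [PhasedGenotypes-class] object.
#' @export
setMethod("[", "PhasedGenotypes", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nVariants(x))
    if (missing(j)) j <- seq_along(x@samples)
    if (is.character(i)) i <- match(i, x@variants$id)
    if (is.character(j)) j <- match(j, x@samples)
    if (anyNA(i)) stop("unknown variant id in subset")
    if (anyNA(j)) stop("unknown sample id in subset")
    .PhasedGenotypes(x@samples[j], x@variants[i, , drop = FALSE],
                     x@hapA[i, j, drop = FALSE], x@hapB[i, j, drop = FALSE])
})

setMethod("show", "PhasedGenotypes", function(object) {
    cat("PhasedGenotypes:", nrow(object@variants), "variants x",
        length(object@samples), "samples\n")
    if (nrow(object@variants)) {
        v <- object@variants
        cat("  region:", v$chrom[1], paste0(min(v$pos), "-", max(v$pos)), "\n")
    }
    nmiss <- sum(is.na(object@hapA)) + sum(is.na(object@hapB))
    if (nmiss) cat("  missing alleles:", nmiss, "\n")
})

#' Additive genotype dosage matrix
#'
#' Per-sample count (0/1/2) of the alternate allele at every variant,
#' the additive coding used for LD and single-variant association.
#'
#' @param x a [PhasedGenotypes-class] object.
#' @return Integer matrix, variants x samples, with `NA` where either allele
#'   is missing.
#' @export
genotypeDosage <- function(x) {
    stopifnot(is(x, "PhasedGenotypes"))
    x@hapA + x@hapB
}

## ---- HaplotypeCatalog ----

#' @rdname accessors
#' @export
setMethod("haplotypeNames", "HaplotypeCatalog", function(x) x@haplotypes)
#' @rdname accessors
#' @export
setMethod("frequencies", "HaplotypeCatalog", function(x) x@frequencies)
#' @rdname accessors
#' @export
setMethod("majorHaplotype", "HaplotypeCatalog", function(x) x@major)

#' Named (common) haplotypes of a catalog
#'
#' Haplotypes whose control-group frequency exceeds the common-frequency
#' threshold used at enumeration time; always contains the major haplotype.
#'
#' @param x a [HaplotypeCatalog-class] object.
#' @return Character vector of haplotype strings.
#' @export
namedHaplotypes <- function(x) {
    stopifnot(is(x, "HaplotypeCatalog"))
    x@named
}

setMethod("show", "HaplotypeCatalog", function(object) {
    cat("HaplotypeCatalog for block '", object@block, "': ",
        length(object@haplotypes), " haplotypes, major = ",
        object@major, "\n", sep = "")
    df <- data.frame(haplotype = object@haplotypes,
                     round(object@frequencies, 4),
                     check.names = FALSE)
    print(utils::head(df, 8), row.names = FALSE)
    if (length(object@haplotypes) > 8)
        cat("  ...", length(object@haplotypes) - 8, "more\n")
})

## ---- FineMapResult ----

#' @rdname accessors
#' @export
setMethod("variantInfo", "FineMapResult", function(x)
    data.frame(id = x@variantIds, marginal = x@marginal))
#' @rdname accessors
#' @export
setMethod("marginalPosteriors", "FineMapResult", function(x)
    stats::setNames(x@marginal, x@variantIds))

setMethod("show", "FineMapResult", function(object) {
    cat("FineMapResult:", length(object@variantIds), "variants,",
        nrow(object@configurations), "configurations (maxCausal =",
        object@parameters$maxCausal, ")\n")
    o <- order(object@marginal, decreasing = TRUE)
    top <- utils::head(o, 5)
    cat("  top marginals:\n")
    for (i in top)
        cat(sprintf("    %s  %.4f\n", object@variantIds[i], object@marginal[i]))
})
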