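#' @import methods
NULL

## Variant descriptor tables used by several classes share one layout:
## id, chrom, pos (1-based), ref, alt, and optionally dr2 (imputation quality).
.checkVariantTable <- function(v, requireStrict = FALSE) {
    msg <- character()
    need <- c("id", "chrom", "pos", "ref", "alt")
    if (!is.data.frame(v) || !all(need %in% names(v)))
        return("variants must be a data.frame with columns id, chrom, pos, ref, alt")
    if (anyDuplicated(v$id))
        msg <- c(msg, "variant ids must be unique")
    if (nrow(v) > 1) {
        d <- diff(v$pos)
        if (requireStrict && any(d <= 0))
            msg <- c(msg, "positions must be strictly increasing")
        if (!requireStrict && any(d < 0))
            msg <- c(msg, "positions must be non-decreasing")
    }
    msg
}

#' HaplotypePool: a known pool of region haplotypes with population frequencies
#'
#' A `HaplotypePool` defines the ground truth for cohort simulation: an ordered
#' set of biallelic variants across a region, a set of haplotypes (one
#' ref/alt indicator per variant), and per-population haplotype frequencies.
#'
#' @slot variants data.frame with columns `id`, `chrom`, `pos` (1-based,
#'   strictly increasing), `ref`, `alt`.
#' @slot haplotypes integer matrix, haplotypes x variants, entries 0 (ref) or
#'   1 (alt); rownames are haplotype names.
#' @slot frequencies numeric matrix, haplotypes x populations; each column is
#'   a probability vector summing to 1.
#'
#' @seealso [HaplotypePool()], [simulateCohort()]
#' @export
setClass("HaplotypePool",
    slots = c(variants = "data.frame",
              haplotypes = "matrix",
              frequencies = "matrix"))

setValidity("HaplotypePool", function(object) {
    msg <- .checkVariantTable(object@variants, requireStrict = TRUE)
    H <- object@haplotypes
    f <- object@frequencies
    if (ncol(H) != nrow(object@variants))
        msg <- c(msg, "haplotype matrix must have one column per variant")
    if (!all(H %in% c(0L, 1L)))
        msg <- c(msg, "haplotype matrix entries must be 0 (ref) or 1 (alt)")
    if (is.null(rownames(H)))
        msg <- c(msg, "haplotypes must be named (rownames)")
    if (nrow(f) != nrow(H))
        msg <- c(msg, "frequencies must have one row per haplotype")
    if (is.null(colnames(f)))
        msg <- c(msg, "frequency columns must be named by population")
    if (any(f < 0))
        msg <- c(msg, "frequencies must be non-negative")
    if (any(abs(colSums(f) - 1) > 1e-12))
        msg <- c(msg, "per-population frequencies must sum to 1 (within 1e-12)")
    if (length(msg)) msg else TRUE
})

#' Construct a HaplotypePool
#'
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#' @param haplotypes matrix of 0/1 allele indicators (haplotypes x variants)
#'   with rownames, or a character vector of strings like `"0101"`.
#' @param frequencies numeric matrix (haplotypes x populations) with column
#'   names, or a named numeric vector for a single population (named `"pop"`).
#' @return A [HaplotypePool-class] object.
#' @examples
#' pool <- HaplotypePool(
#'   variants = data.frame(id = c("v1", "v2"), chrom = "19",
#'                         pos = c(100L, 200L), ref = c("A", "G"),
#'                         alt = c("C", "T")),
#'   haplotypes = c(H1 = "00", H2 = "11"),
#'   frequencies = c(H1 = 0.9, H2 = 0.1))
#' pool
#' @export
HaplotypePool <- function(variants, haplotypes, frequencies) {
    if (is.character(haplotypes)) {
        nm <- names(haplotypes)
        haplotypes <- do.call(rbind, lapply(strsplit(haplotypes, ""),
                                            function(x) as.integer(x)))
        rownames(haplotypes) <- nm
    }
    storage.mode(haplotypes) <- "integer"
    if (is.null(dim(frequencies)))
        frequencies <- matrix(frequencies, ncol = 1,
                              dimnames = list(names(frequencies), "pop"))
    variants$pos <- as.integer(variants$pos)
    new("HaplotypePool", variants = variants, haplotypes = haplotypes,
        frequencies = frequencies)
}

#' PhasedGenotypes: phased biallelic genotypes for a region
#'
#' Holds, for every sample, the two haploid allele vectors (0 = ref, 1 = alt)
#' across an ordered set of biallelic variants, as read from a phased VCF
#' (left of `|` is haplotype A) or produced by [simulateCohort()]. Missing
#' alleles are `NA`.
#'
#' @slot samples character vector of sample IDs.
#' @slot variants data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `dr2` (imputation allele-dosage R2, `NA` when absent).
#' @slot hapA,hapB integer matrices (variants x samples) of 0/1/NA alleles.
#'
#' @seealso [readPhasedVcf()], [writePhasedVcf()], [qcFilter()]
#' @export
setClass("PhasedGenotypes",
    slots = c(samples = "character",
              variants = "data.frame",
              hapA = "matrix",
              hapB = "matrix"))

setValidity("PhasedGenotypes", function(object) {
    msg <- .checkVariantTable(object@variants)
    if (!"dr2" %in% names(object@variants))
        msg <- c(msg, "variants must carry a dr2 column (NA allowed)")
    nv <- nrow(object@variants); ns <- length(object@samples)
    for (nmm in c("hapA", "hapB")) {
        m <- slot(object, nmm)
        if (!all(dim(m) == c(nv, ns)))
            msg <- c(msg, sprintf("%s must be variants x samples (%d x %d)",
                                  nmm, nv, ns))
        if (!all(m %in% c(0L, 1L, NA_integer_)))
            msg <- c(msg, sprintf("%s entries must be 0, 1 or NA", nmm))
    }
    if (anyDuplicated(object@samples))
        msg <- c(msg, "sample IDs must be unique")
    if (length(msg)) msg else TRUE
})

.PhasedGenotypes <- function(samples, variants, hapA, hapB) {
    if (!"dr2" %in% names(variants)) variants$dr2 <- NA_real_
    variants$pos <- as.integer(variants$pos)
    storage.mode(hapA) <- "integer"
    storage.mode(hapB) <- "integer"
    dimnames(hapA) <- dimnames(hapB) <- list(variants$id, samples)
    rownames(variants) <- NULL
    new("PhasedGenotypes", samples = samples, variants = variants,
        hapA = hapA, hapB = hapB)
}

#' HaplotypeCatalog: enumerated block haplotypes with group frequencies
#'
#' Produced by [enumerateHaplotypes()]. Haplotype strings follow the
#' uppercase-major / lowercase-minor letter convention; frequencies are
#' chromosome counts over 2N per phenotype group plus an `"overall"` column.
#'
#' @slot block block name.
#' @slot haplotypes character vector of haplotype strings, sorted by
#'   decreasing overall frequency.
#' @slot frequencies numeric matrix (haplotypes x groups), last column
#'   `"overall"`; every column sums to 1.
#' @slot counts integer matrix of chromosome counts in the same layout.
#' @slot major the single major haplotype (most frequent in controls).
#' @slot named haplotypes exceeding the common-frequency threshold in the
#'   control group (always includes the major haplotype).
#'
#' @export
setClass("HaplotypeCatalog",
    slots = c(block = "character",
              haplotypes = "character",
              frequencies = "matrix",
              counts = "matrix",
              major = "character",
              named = "character"))

setValidity("HaplotypeCatalog", function(object) {
    msg <- character()
    if (nrow(object@frequencies) != length(object@haplotypes))
        msg <- c(msg, "one frequency row per haplotype required")
    if (any(abs(colSums(object@frequencies) - 1) > 1e-9))
        msg <- c(msg, "group frequencies must sum to 1 (within 1e-9)")
    if (length(object@major) != 1 || !object@major %in% object@haplotypes)
        msg <- c(msg, "exactly one major haplotype, present in the catalog")
    if (!"overall" %in% colnames(object@frequencies))
        msg <- c(msg, "frequencies must include an 'overall' column")
    if (length(msg)) msg else TRUE
})

#' FineMapResult: causal-variant posteriors from summary statistics
#'
#' Result of [caviarPosteriors()]: marginal posterior probability of
#' causality per variant, plus the per-configuration posterior table over the
#' enumerated causal-indicator space.
#'
#' @slot variantIds variant identifiers.
#' @slot marginal per-variant marginal posterior probability of causality.
#' @slot configurations data.frame with columns `configuration`
#'   (comma-separated variant ids, `""` for the null configuration), `size`,
#'   and `posterior`; posteriors sum to 1 over the enumerated space.
#' @slot parameters list of the settings used (`maxCausal`, `gamma`, `sigma`,
#'   `ridge`).
#'
#' @export
setClass("FineMapResult",
    slots = c(variantIds = "character",
              marginal = "numeric",
              configurations = "data.frame",
              parameters = "list"))

setValidity("FineMapResult", function(object) {
    msg <- character()
    if (length(object@marginal) != length(object@variantIds))
        msg <- c(msg, "one marginal posterior per variant required")
    if (any(object@marginal < -1e-12 | object@marginal > 1 + 1e-12))
        msg <- c(msg, "marginal posteriors must lie in [0, 1]")
    if (abs(sum(object@configurations$posterior) - 1) > 1e-9)
        msg <- c(msg, "configuration posteriors must sum to 1 (within 1e-9)")
    if (length(msg)) msg else TRUE
})
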