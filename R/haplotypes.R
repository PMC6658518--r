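## Variant QC, LD block expansion, per-individual block haplotype strings,
## haplotype enumeration, and the N x (M+1) dosage matrix.

#' Variant quality-control filter
#'
#' Removes variants failing any of: minor allele frequency (`maf > mafMin`),
#' exact Hardy-Weinberg p-value (`hweP > hwePMin`), and imputation
#' allele-dosage R2 (`dr2 > dr2Min`). All thresholds are strict inequalities.
#' Variants lacking a DR2 value are passed by default with a warning
#' (`missingDr2 = "pass"`), or removed with `missingDr2 = "fail"`.
#'
#' @param genotypes a [PhasedGenotypes-class] object (non-empty).
#' @param mafMin,hwePMin,dr2Min thresholds; set a threshold to `NULL` to
#'   disable that filter.
#' @param missingDr2 policy for variants without DR2 when `dr2Min` is set.
#' @return List with `genotypes` (filtered) and `report`, a per-variant
#'   data.frame of `id`, `maf`, `hweP`, `dr2`, `pass` and `reason`
#'   (comma-separated failed filters, `""` when passing).
#' @export
qcFilter <- function(genotypes, mafMin = 0.05, hwePMin = 1e-5,
                     dr2Min = 0.30, missingDr2 = c("pass", "fail")) {
    missingDr2 <- match.arg(missingDr2)
    stopifnot(is(genotypes, "PhasedGenotypes"))
    if (nVariants(genotypes) == 0) stop("empty genotype matrix")
    st <- alleleStats(genotypes)
    v <- variantInfo(genotypes)
    reasons <- rep("", nrow(v))
    add <- function(reasons, bad, tag)
        ifelse(bad, ifelse(reasons == "", tag, paste(reasons, tag, sep = ",")),
               reasons)
    if (!is.null(mafMin))
        reasons <- add(reasons, !(st$maf > mafMin), "MAF")
    if (!is.null(hwePMin))
        reasons <- add(reasons, !(st$hweP > hwePMin), "HWE")
    if (!is.null(dr2Min)) {
        noDr2 <- is.na(v$dr2)
        if (any(noDr2) && missingDr2 == "pass")
            warning(sum(noDr2), " variant(s) lack DR2; passed unfiltered")
        failDr2 <- if (missingDr2 == "pass")
            !noDr2 & !(v$dr2 > dr2Min)
        else noDr2 | !(v$dr2 > dr2Min)
        reasons <- add(reasons, failDr2, "DR2")
    }
    report <- data.frame(id = v$id, maf = st$maf, hweP = st$hweP,
                         dr2 = v$dr2, pass = reasons == "", reason = reasons)
    list(genotypes = genotypes[which(report$pass), ], report = report)
}

#' Expand a seed variant set by linkage disequilibrium
#'
#' Returns the seed variants plus every variant whose maximum r2 with any
#' seed reaches `r2Min`, ordered by genomic position.
#'
#' @param genotypes a [PhasedGenotypes-class] object.
#' @param seedIds character vector of seed variant ids (must be present).
#' @param r2Min inclusion threshold (`r2 >= r2Min`); 0 returns all variants.
#' @param mode LD mode passed to [ldR2()].
#' @return Character vector of variant ids, position-ordered.
#' @export
expandBlockByLd <- function(genotypes, seedIds, r2Min = 0.50,
                            mode = c("genotype", "haplotype")) {
    mode <- match.arg(mode)
    v <- variantInfo(genotypes)
    if (!all(seedIds %in% v$id))
        stop("unknown seed variant(s): ",
             paste(setdiff(seedIds, v$id), collapse = ", "))
    inSet <- v$id %in% seedIds
    for (i in which(!inSet)) {
        r2 <- vapply(seedIds, function(s) {
            r <- ldR2(genotypes, v$id[i], s, mode)
            if (is.na(r)) -Inf else r
        }, numeric(1))
        if (max(r2) >= r2Min) inSet[i] <- TRUE
    }
    v$id[inSet][order(v$pos[inSet])]
}

.alleleToken <- function(ref, alt, which) {
    ## one printable token per allele; INDEL alleles render as I (longer)
    ## or D (shorter) so strings keep one character per variant
    if (nchar(ref) > 1 || nchar(alt) > 1) {
        if (which == "ref") (if (nchar(ref) >= nchar(alt)) "I" else "D")
        else (if (nchar(alt) > nchar(ref)) "I" else "D")
    } else toupper(if (which == "ref") ref else alt)
}

#' Extract per-individual block haplotype strings
#'
#' For each retained sample, concatenates one letter per block variant along
#' each phased chromosome: uppercase for the major (non-effect) allele,
#' lowercase for the minor (effect/risk) allele, matching the usual risk
#' haplotype display convention. INDEL alleles are rendered as single tokens
#' `I`/`D` (cased the same way). Samples with any missing allele inside the
#' block are dropped and listed in the `dropped` attribute.
#'
#' @param genotypes a [PhasedGenotypes-class] object.
#' @param block data.frame with columns `id` (variant ids, all present in
#'   `genotypes`) and `effect_allele` (the minor/risk allele, matching the
#'   variant's ref or alt), plus an optional `name` attribute.
#' @return data.frame `sample`, `hap1`, `hap2` with attribute `dropped`
#'   (character vector of excluded samples) and attribute `block` (name).
#' @export
extractBlockHaplotypes <- function(genotypes, block) {
    stopifnot(is(genotypes, "PhasedGenotypes"),
              all(c("id", "effect_allele") %in% names(block)))
    v <- variantInfo(genotypes)
    miss <- setdiff(block$id, v$id)
    if (length(miss))
        stop("block variant(s) absent from matrix: ",
             paste(miss, collapse = ", "))
    idx <- match(block$id, v$id)
    effIsAlt <- logical(length(idx))
    for (k in seq_along(idx)) {
        i <- idx[k]
        ea <- block$effect_allele[k]
        if (ea == v$alt[i]) effIsAlt[k] <- TRUE
        else if (ea == v$ref[i]) effIsAlt[k] <- FALSE
        else stop("effect allele '", ea, "' matches neither ref nor alt of ",
                  v$id[i])
    }
    ## letter[a+1, k]: letter written when carrying allele a (0=ref,1=alt)
    letter <- vapply(seq_along(idx), function(k) {
        i <- idx[k]
        refTok <- .alleleToken(v$ref[i], v$alt[i], "ref")
        altTok <- .alleleToken(v$ref[i], v$alt[i], "alt")
        if (effIsAlt[k]) c(toupper(refTok), tolower(altTok))
        else c(tolower(refTok), toupper(altTok))
    }, character(2))

    hapA <- genotypes@hapA[idx, , drop = FALSE]
    hapB <- genotypes@hapB[idx, , drop = FALSE]
    complete <- colSums(is.na(hapA)) + colSums(is.na(hapB)) == 0
    toStrings <- function(m) {
        apply(m, 2, function(al)
            paste(letter[cbind(al + 1L, seq_along(al))], collapse = ""))
    }
    out <- data.frame(sample = sampleIds(genotypes)[complete],
                      hap1 = toStrings(hapA[, complete, drop = FALSE]),
                      hap2 = toStrings(hapB[, complete, drop = FALSE]),
                      row.names = NULL)
    attr(out, "dropped") <- sampleIds(genotypes)[!complete]
    attr(out, "block") <- if (!is.null(attr(block, "name")))
        attr(block, "name") else "block"
    out
}

#' Enumerate haplotypes and their group frequencies
#'
#' Counts every chromosome string over the 2N chromosomes, per phenotype
#' group and overall. The major haplotype is the most frequent in the control
#' group (ties broken by overall frequency, then lexicographically);
#' haplotypes with control-group frequency above `commonFreq` are "named"
#' (common) haplotypes.
#'
#' @param pairs data.frame `sample`, `hap1`, `hap2` (from
#'   [extractBlockHaplotypes()]).
#' @param groups optional per-sample group labels (e.g. `"NC"`, `"AD"`);
#'   `NULL` treats the cohort as one group.
#' @param commonFreq naming threshold on the control-group frequency.
#' @param controlGroup which group is the control reference; default the
#'   first of `"NC"`, `"control"` present, else the overall pool.
#' @param block block name stored in the catalog.
#' @return A [HaplotypeCatalog-class] object.
#' @export
enumerateHaplotypes <- function(pairs, groups = NULL, commonFreq = 0.05,
                                controlGroup = NULL, block = "block") {
    stopifnot(all(c("hap1", "hap2") %in% names(pairs)))
    if (nrow(pairs) == 0) stop("no chromosome strings to enumerate")
    if (!is.null(groups)) .assertAligned(pairs, groups)
    strings <- c(pairs$hap1, pairs$hap2)
    grp <- if (is.null(groups)) rep("all", nrow(pairs))
           else as.character(groups)
    grp2 <- c(grp, grp)
    haps <- sort(unique(strings))
    glev <- sort(unique(grp))
    counts <- matrix(0L, length(haps), length(glev) + 1L,
                     dimnames = list(haps, c(glev, "overall")))
    for (g in glev)
        counts[, g] <- as.integer(table(factor(strings[grp2 == g],
                                               levels = haps)))
    counts[, "overall"] <- as.integer(table(factor(strings, levels = haps)))
    freq <- sweep(counts, 2, colSums(counts), "/")

    if (is.null(controlGroup))
        controlGroup <- intersect(c("NC", "control"), glev)[1]
    ctrl <- if (!is.na(controlGroup) && !is.null(controlGroup) &&
                controlGroup %in% glev) controlGroup else "overall"
    ## major: control frequency, then overall frequency, then lexicographic
    ord <- order(-freq[, ctrl], -freq[, "overall"], haps)
    major <- haps[ord[1]]
    named <- haps[freq[, ctrl] > commonFreq]
    if (!major %in% named) named <- c(major, named)

    oo <- order(-freq[, "overall"], haps)
    new("HaplotypeCatalog", block = block, haplotypes = haps[oo],
        frequencies = freq[oo, , drop = FALSE],
        counts = counts[oo, , drop = FALSE],
        major = major, named = named)
}

#' Build the N x (M+1) haplotype dosage matrix
#'
#' One named column per haplotype with overall frequency >= `rareFreq`
#' (catalog order, most frequent first) plus a final `"others"` column
#' pooling all rarer haplotypes, so every row sums to exactly 2.
#'
#' @param catalog a [HaplotypeCatalog-class].
#' @param pairs data.frame `sample`, `hap1`, `hap2`; every haplotype must be
#'   present in the catalog.
#' @param rareFreq pooling threshold (haplotypes with frequency below it go
#'   to `"others"`); 0 keeps every haplotype as its own column.
#' @return Integer matrix (samples x haplotypes+others) with attribute
#'   `major` (the catalog's major haplotype string, also a column unless
#'   itself rare).
#' @export
buildDosageMatrix <- function(catalog, pairs, rareFreq = 0.01) {
    stopifnot(is(catalog, "HaplotypeCatalog"),
              all(c("hap1", "hap2") %in% names(pairs)))
    haps <- haplotypeNames(catalog)
    unknown <- setdiff(unique(c(pairs$hap1, pairs$hap2)), haps)
    if (length(unknown))
        stop("haplotype(s) absent from catalog: ",
             paste(unknown, collapse = ", "))
    keep <- haps[frequencies(catalog)[, "overall"] >= rareFreq]
    cols <- c(keep, "others")
    m <- matrix(0L, nrow(pairs), length(cols),
                dimnames = list(pairs$sample, cols))
    colOf <- function(h) ifelse(h %in% keep, h, "others")
    for (r in seq_len(nrow(pairs))) {
        m[r, colOf(pairs$hap1[r])] <- m[r, colOf(pairs$hap1[r])] + 1L
        m[r, colOf(pairs$hap2[r])] <- m[r, colOf(pairs$hap2[r])] + 1L
    }
    attr(m, "major") <- majorHaplotype(catalog)
    m
}
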