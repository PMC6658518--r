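## Population-stratified haplotype frequency reporting, including the
## two-variant APOE epsilon-2/3/4 isoform classifier.

#' Classify APOE isoform haplotypes from the two coding variants
#'
#' Per haploid chromosome, the rs429358/rs7412 allele combination defines
#' the isoform: alt/ref -> epsilon-4, ref/alt -> epsilon-2, ref/ref ->
#' epsilon-3; the rare alt/alt combination is flagged separately as an
#' epsilon-1-like haplotype. Both variants must be present and phased.
#'
#' @param genotypes a [PhasedGenotypes-class] containing both variants.
#' @param rs429358,rs7412 the variant ids of the two coding sites in
#'   `genotypes`.
#' @return List with `calls` (data.frame `sample`, `hapA`, `hapB` isoform
#'   labels) and `dosages` (integer matrix samples x e2/e3/e4/e1like, rows
#'   summing to 2; samples with missing alleles are dropped and listed in
#'   the `dropped` attribute).
#' @export
apoeIsoformHaplotypes <- function(genotypes, rs429358 = "rs429358",
                                  rs7412 = "rs7412") {
    stopifnot(is(genotypes, "PhasedGenotypes"))
    ids <- variantInfo(genotypes)$id
    miss <- setdiff(c(rs429358, rs7412), ids)
    if (length(miss))
        stop("variant(s) missing from matrix: ", paste(miss, collapse = ", "))
    i1 <- match(rs429358, ids); i2 <- match(rs7412, ids)
    classify <- function(a358, a412) {
        ifelse(is.na(a358) | is.na(a412), NA_character_,
        ifelse(a358 == 1L & a412 == 0L, "e4",
        ifelse(a358 == 0L & a412 == 1L, "e2",
        ifelse(a358 == 0L & a412 == 0L, "e3", "e1like"))))
    }
    hapA <- classify(genotypes@hapA[i1, ], genotypes@hapA[i2, ])
    hapB <- classify(genotypes@hapB[i1, ], genotypes@hapB[i2, ])
    ok <- !is.na(hapA) & !is.na(hapB)
    lev <- c("e2", "e3", "e4", "e1like")
    dos <- t(vapply(which(ok), function(s)
        as.integer(table(factor(c(hapA[s], hapB[s]), levels = lev))),
        integer(4)))
    colnames(dos) <- lev
    rownames(dos) <- sampleIds(genotypes)[ok]
    calls <- data.frame(sample = sampleIds(genotypes)[ok],
                        hapA = hapA[ok], hapB = hapB[ok])
    out <- list(calls = calls, dosages = dos)
    attr(out, "dropped") <- sampleIds(genotypes)[!ok]
    out
}

#' Population-stratified haplotype frequencies
#'
#' Chromosome frequencies of each haplotype within every population of a
#' sample panel: count / (2 x labeled samples). Samples without a panel
#' label are excluded and reported.
#'
#' @param pairs data.frame `sample`, `hap1`, `hap2` — per-individual
#'   haplotype labels ([extractBlockHaplotypes()] output or the `calls` of
#'   [apoeIsoformHaplotypes()] renamed accordingly).
#' @param panel data.frame `sample`, `population`; at most one label per
#'   sample.
#' @return data.frame `population`, `haplotype`, `count`, `nChromosomes`,
#'   `frequency`, sorted by population then decreasing frequency, with an
#'   `unlabeled` attribute listing excluded samples. Within each population
#'   the frequencies sum to 1.
#' @export
populationFrequencies <- function(pairs, panel) {
    stopifnot(all(c("sample", "hap1", "hap2") %in% names(pairs)),
              all(c("sample", "population") %in% names(panel)))
    if (anyDuplicated(panel$sample))
        stop("panel assigns more than one label to a sample")
    lab <- panel$population[match(pairs$sample, panel$sample)]
    unlabeled <- pairs$sample[is.na(lab)]
    keep <- !is.na(lab)
    pairs <- pairs[keep, , drop = FALSE]; lab <- lab[keep]
    if (!nrow(pairs)) stop("no labeled samples left")
    out <- do.call(rbind, lapply(sort(unique(lab)), function(pp) {
        strings <- c(pairs$hap1[lab == pp], pairs$hap2[lab == pp])
        tt <- sort(table(strings), decreasing = TRUE)
        data.frame(population = pp, haplotype = names(tt),
                   count = as.integer(tt),
                   nChromosomes = length(strings),
                   frequency = as.numeric(tt) / length(strings))
    }))
    rownames(out) <- NULL
    attr(out, "unlabeled") <- unlabeled
    out
}
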