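# Shared in-code fixtures: small haplotype pools and genotype builders.

# Three-variant pool (SNP, SNP, insertion) with three haplotypes.
toyPool <- function() {
    HaplotypePool(
        variants = data.frame(id = c("v1", "v2", "v3"), chrom = "19",
                              pos = c(100L, 200L, 300L),
                              ref = c("A", "G", "T"),
                              alt = c("C", "T", "TA")),
        haplotypes = c(H1 = "000", H2 = "110", H3 = "011"),
        frequencies = c(H1 = 0.6, H2 = 0.3, H3 = 0.1))
}

toyBlock <- function() {
    data.frame(id = c("v1", "v2", "v3"),
               effect_allele = c("C", "T", "TA"))
}

# Random pool where every variant is polymorphic across haplotypes.
randomPool <- function(nVar, nHap, seed) {
    set.seed(seed)
    repeat {
        H <- matrix(rbinom(nHap * nVar, 1L, 0.5), nHap, nVar)
        if (all(colSums(H) > 0 & colSums(H) < nHap)) break
    }
    rownames(H) <- paste0("H", seq_len(nHap))
    f <- rgamma(nHap, 2) + 0.3
    HaplotypePool(
        variants = data.frame(id = paste0("v", seq_len(nVar)), chrom = "19",
                              pos = 1000L * seq_len(nVar),
                              ref = "A", alt = "G"),
        haplotypes = H,
        frequencies = matrix(f / sum(f), ncol = 1,
                             dimnames = list(rownames(H), "pop")))
}

# Hand-built PhasedGenotypes from explicit allele matrices (variants x samples).
handGenotypes <- function(hapA, hapB, ids = NULL, ref = NULL, alt = NULL,
                          dr2 = NA_real_) {
    nv <- nrow(hapA)
    if (is.null(ids)) ids <- paste0("s", seq_len(nv))
    v <- data.frame(id = ids, chrom = "19", pos = 10L * seq_len(nv),
                    ref = if (is.null(ref)) rep("A", nv) else ref,
                    alt = if (is.null(alt)) rep("G", nv) else alt,
                    dr2 = dr2)
    haplorisk:::.PhasedGenotypes(paste0("I", seq_len(ncol(hapA))), v,
                                 hapA, hapB)
}

# Per-individual haplotype-name pairs from a cohort simulation's truth.
truthPairs <- function(sim) {
    data.frame(sample = sim$phenotypes$sample,
               hap1 = sim$truth$hapA, hap2 = sim$truth$hapB)
}
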