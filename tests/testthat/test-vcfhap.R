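test_that("phased VCF writing round-trips through the reader", {
    pool <- toyPool()
    sim <- simulateCohort(pool, cohortSpec(40, seed = 3), "pop")
    v <- variantInfo(sim$genotypes)
    gt0 <- sim$genotypes
    gt0@variants$dr2 <- c(0.95, NA, 0.42)  # exercise optional DR2 INFO
    f <- tempfile(fileext = ".vcf")
    writePhasedVcf(gt0, f)
    gt <- readPhasedVcf(f)
    expect_identical(unname(alleleMatrix(gt, "A")),
                     unname(alleleMatrix(gt0, "A")))
    expect_identical(unname(alleleMatrix(gt, "B")),
                     unname(alleleMatrix(gt0, "B")))
    expect_identical(sampleIds(gt), sampleIds(gt0))
    expect_identical(variantInfo(gt)$id, v$id)
    expect_equal(variantInfo(gt)$dr2, c(0.95, NA, 0.42), tolerance = 1e-6)
})

test_that("missing alleles round-trip as .|. tokens", {
    hapA <- matrix(c(0L, NA, 1L, 0L), 2, 2)
    hapB <- matrix(c(1L, 0L, NA, 0L), 2, 2)
    gt0 <- handGenotypes(hapA, hapB)
    f <- tempfile(fileext = ".vcf")
    writePhasedVcf(gt0, f)
    gt <- readPhasedVcf(f)
    expect_identical(unname(alleleMatrix(gt, "A")), hapA)
    expect_identical(unname(alleleMatrix(gt, "B")), hapB)
})

test_that("region queries subset correctly, empty regions keep samples", {
    sim <- simulateCohort(toyPool(), cohortSpec(10, seed = 4), "pop")
    f <- tempfile(fileext = ".vcf")
    writePhasedVcf(sim$genotypes, f)
    gt <- readPhasedVcf(f, region = "19:150-250")
    expect_identical(variantInfo(gt)$id, "v2")
    empty <- readPhasedVcf(f, region = "19:1000-2000")
    expect_identical(nVariants(empty), 0L)
    expect_identical(sampleIds(empty), sampleIds(sim$genotypes))
    expect_error(readPhasedVcf(f, region = "nonsense"), "malformed region")
})

test_that("unphased genotypes are rejected strictly or masked on request", {
    lines <- c("##fileformat=VCFv4.2",
               "##contig=<ID=19>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "IND1", "IND2", sep = "\t"),
               paste("19", "100", "rs1", "A", "G", ".", "PASS", ".",
                     "GT", "0|1", "0/1", sep = "\t"))
    f <- tempfile(fileext = ".vcf")
    writeLines(lines, f)
    expect_error(readPhasedVcf(f), "IND2.*19:100")
    gt <- readPhasedVcf(f, unphased = "mask")
    expect_identical(unname(alleleMatrix(gt, "A")[1, ]), c(0L, NA))
    expect_identical(unname(alleleMatrix(gt, "B")[1, ]), c(1L, NA))
})

test_that("multiallelic records are skipped with a warning", {
    lines <- c("##fileformat=VCFv4.2",
               "##contig=<ID=19>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "IND1", sep = "\t"),
               paste("19", "100", "rs1", "A", "G,T", ".", "PASS", ".",
                     "GT", "1|2", sep = "\t"),
               paste("19", "200", "rs2", "A", "G", ".", "PASS", ".",
                     "GT", "1|0", sep = "\t"))
    f <- tempfile(fileext = ".vcf")
    writeLines(lines, f)
    expect_warning(gt <- readPhasedVcf(f), "multiallelic")
    expect_identical(variantInfo(gt)$id, "rs2")
})

test_that("QC filter applies strict MAF/HWE/DR2 thresholds with reasons", {
    # 10 individuals; v2 has MAF 0.05 (not > 0.05), the rest pass MAF
    hapA <- rbind(c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 0L, 0L, 0L),
                  c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
                  c(0L, 1L, 1L, 0L, 0L, 0L, 1L, 0L, 1L, 0L))
    hapB <- rbind(c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
                  c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
                  c(0L, 0L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 0L))
    gt <- handGenotypes(hapA, hapB, ids = c("a", "b", "c"),
                        dr2 = c(0.9, 0.9, 0.9))
    res <- qcFilter(gt, mafMin = 0.05, hwePMin = 1e-5, dr2Min = 0.30)
    expect_identical(res$report$reason[res$report$id == "b"], "MAF")
    expect_identical(variantInfo(res$genotypes)$id, c("a", "c"))

    # all passing: identity
    res2 <- qcFilter(gt[c(1, 3), ], mafMin = 0.05)
    expect_identical(nVariants(res2$genotypes), 2L)

    # DR2 threshold removes low-quality variants; missing DR2 passes + warns
    gt3 <- handGenotypes(hapA[c(1, 3), ], hapB[c(1, 3), ],
                         ids = c("a", "c"), dr2 = c(0.2, NA))
    expect_warning(res3 <- qcFilter(gt3), "lack DR2")
    expect_identical(res3$report$reason, c("DR2", ""))
    expect_identical(variantInfo(res3$genotypes)$id, "c")
})

test_that("HWE violations are removed by the QC filter", {
    # 40 individuals all heterozygous: extreme excess, exact p < 1e-5
    hapA <- matrix(0L, 1, 40); hapB <- matrix(1L, 1, 40)
    gt <- handGenotypes(rbind(hapA, c(rep(0L, 20), rep(1L, 20))),
                        rbind(hapB, c(rep(0L, 30), rep(1L, 10))))
    res <- qcFilter(gt, dr2Min = NULL)
    expect_identical(res$report$reason[1], "HWE")
    expect_true(res$report$pass[2])
})

test_that("LD expansion keeps seeds, proxies, and honors the boundary", {
    pool <- randomPool(6, 4, seed = 17)
    sim <- simulateCohort(pool, cohortSpec(2000, seed = 18), "pop")
    gt <- sim$genotypes
    # duplicate v1 as v7 (perfect proxy placed after the others)
    v <- variantInfo(gt)
    dup <- rbind(v, data.frame(id = "v7", chrom = "19", pos = 99000L,
                               ref = "A", alt = "G", dr2 = NA_real_))
    gt2 <- haplorisk:::.PhasedGenotypes(sampleIds(gt), dup,
                                        rbind(gt@hapA, gt@hapA[1, ]),
                                        rbind(gt@hapB, gt@hapB[1, ]))
    ids <- expandBlockByLd(gt2, "v1", r2Min = 0.5)
    expect_true("v7" %in% ids)
    expect_true("v1" %in% ids)

    # an independently drawn variant stays out
    set.seed(19)
    ind <- rbinom(2000, 1, 0.4)
    gt3 <- haplorisk:::.PhasedGenotypes(
        sampleIds(gt),
        rbind(v, data.frame(id = "vind", chrom = "19", pos = 99000L,
                            ref = "A", alt = "G", dr2 = NA_real_)),
        rbind(gt@hapA, ind), rbind(gt@hapB, rbinom(2000, 1, 0.4)))
    expect_false("vind" %in% expandBlockByLd(gt3, "v1", r2Min = 0.5))
    expect_identical(sort(expandBlockByLd(gt3, "v1", r2Min = 0)),
                     sort(variantInfo(gt3)$id))
    expect_error(expandBlockByLd(gt, "nope"), "unknown seed")
})

test_that("block haplotype strings follow the case and token conventions", {
    # three variants: effect allele = alt for v1, v2; ref for v3 (INDEL)
    hapA <- rbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(1L, 1L, 1L))
    hapB <- rbind(c(0L, 1L, NA), c(0L, 0L, NA), c(1L, 0L, 1L))
    gt <- handGenotypes(hapA, hapB, ids = c("x", "y", "z"),
                        ref = c("A", "G", "TA"), alt = c("C", "T", "T"))
    block <- data.frame(id = c("x", "y", "z"),
                        effect_allele = c("C", "T", "TA"))
    ph <- extractBlockHaplotypes(gt, block)
    # sample 3 carries NA at x/y on hapB: dropped and reported
    expect_identical(ph$sample, c("I1", "I2"))
    expect_identical(attr(ph, "dropped"), "I3")
    # I1 hapA = (0,0,1): major A, major G, alt at z = major INDEL token "D"
    expect_identical(ph$hap1[1], "AGD")
    # I2: hapA unchanged; hapB carries effect alleles at x (alt "c") and at
    # z (ref "TA" is the effect allele, deletion-side token -> "i")
    expect_identical(ph$hap1[2], "AGD")
    expect_identical(ph$hap2[2], "cGi")
    expect_error(extractBlockHaplotypes(gt,
        data.frame(id = "w", effect_allele = "A")), "absent")
    expect_error(extractBlockHaplotypes(gt,
        data.frame(id = "x", effect_allele = "T")), "neither ref nor alt")
})

test_that("haplotype enumeration matches hand counts and brute force", {
    # 4 individuals all H|H
    p1 <- data.frame(sample = paste0("i", 1:4), hap1 = "AAA", hap2 = "AAA")
    c1 <- enumerateHaplotypes(p1)
    expect_equal(unname(frequencies(c1)[, "overall"]), 1)
    expect_identical(majorHaplotype(c1), "AAA")

    # strings A x3, B x2, C x1 over 3 individuals
    p2 <- data.frame(sample = paste0("i", 1:3),
                     hap1 = c("A", "A", "B"), hap2 = c("A", "B", "C"))
    c2 <- enumerateHaplotypes(p2)
    expect_equal(unname(frequencies(c2)[, "overall"]),
                 c(3, 2, 1) / 6)
    expect_identical(haplotypeNames(c2), c("A", "B", "C"))

    # permuting samples leaves the catalog unchanged
    c2p <- enumerateHaplotypes(p2[c(3, 1, 2), ])
    expect_identical(frequencies(c2p), frequencies(c2))

    # property: agreement with an independent dictionary count
    set.seed(23)
    for (rep in 1:25) {
        n <- sample(2:50, 1)
        nv <- sample(2:6, 1)
        alph <- c("A", "b")
        strs <- replicate(2 * n, paste(sample(alph, nv, TRUE), collapse = ""))
        pairs <- data.frame(sample = paste0("i", 1:n),
                            hap1 = strs[1:n], hap2 = strs[(n + 1):(2 * n)])
        cat_ <- enumerateHaplotypes(pairs)
        dict <- new.env()
        for (s in strs)
            assign(s, (if (exists(s, envir = dict, inherits = FALSE))
                get(s, envir = dict) else 0) + 1, envir = dict)
        for (h in haplotypeNames(cat_))
            expect_identical(frequencies(cat_)[h, "overall"],
                             get(h, envir = dict) / (2 * n))
    }
})

test_that("major haplotype is chosen in controls with deterministic ties", {
    pairs <- data.frame(sample = paste0("i", 1:4),
                        hap1 = c("A", "A", "B", "B"),
                        hap2 = c("B", "B", "A", "C"))
    # controls carry A x2 B x2: tie on control freq; overall A 3/8 vs B 4/8
    groups <- c("NC", "NC", "AD", "AD")
    cat_ <- enumerateHaplotypes(pairs, groups, controlGroup = "NC")
    expect_identical(majorHaplotype(cat_), "B")  # tie broken by overall
})

test_that("dosage matrix pools rare haplotypes and conserves row sums", {
    pairs <- data.frame(sample = c("i1", "i2", "i3"),
                        hap1 = c("A", "A", "B"), hap2 = c("A", "B", "C"))
    cat_ <- enumerateHaplotypes(pairs)
    dm <- buildDosageMatrix(cat_, pairs, rareFreq = 0.20)
    expect_identical(colnames(dm), c("A", "B", "others"))
    expect_identical(matrix(as.integer(dm), 3, 3),
                     matrix(c(2L, 0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L),
                            3, 3, byrow = TRUE))
    expect_identical(attr(dm, "major"), "A")

    dm0 <- buildDosageMatrix(cat_, pairs, rareFreq = 0)
    expect_true(all(dm0[, "others"] == 0L))
    expect_true(all(rowSums(dm0) == 2L))
    expect_error(buildDosageMatrix(cat_,
        data.frame(sample = "x", hap1 = "Z", hap2 = "A")), "absent")

    # conservation on random instances
    set.seed(29)
    for (rep in 1:10) {
        n <- sample(3:30, 1)
        strs <- sample(c("AA", "AB", "BB", "BA"), 2 * n, TRUE)
        pr <- data.frame(sample = paste0("i", 1:n),
                         hap1 = strs[1:n], hap2 = strs[(n + 1):(2 * n)])
        dmr <- buildDosageMatrix(enumerateHaplotypes(pr), pr,
                                 rareFreq = runif(1, 0, 0.3))
        expect_true(all(rowSums(dmr) == 2L))
    }
})
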