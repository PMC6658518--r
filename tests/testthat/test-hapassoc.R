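# Two-haplotype pool: dosage of the minor haplotype is a single binomial
# variant, so the joint model must reduce to single-variant association.
biallelicPool <- function() {
    HaplotypePool(
        variants = data.frame(id = "v1", chrom = "19", pos = 100L,
                              ref = "A", alt = "G"),
        haplotypes = c(MAJ = "0", MIN = "1"),
        frequencies = c(MAJ = 0.7, MIN = 0.3))
}

test_that("one biallelic block reduces exactly to single-variant logistic", {
    sim <- simulateCohort(biallelicPool(),
                          cohortSpec(800, beta0 = -0.4,
                                     betaHaplotypes = c(MIN = 0.5),
                                     seed = 61), "pop")
    dm <- structure(sim$truth$dosages, major = "MAJ")
    hap <- haplotypeLogistic(dm, sim$phenotypes$status)
    sv <- logisticAssoc(sim$truth$dosages[, "MIN"], sim$phenotypes$status)
    expect_equal(hap$beta, sv$beta, tolerance = 1e-10)
    expect_equal(hap$se, sv$se, tolerance = 1e-10)
})

test_that("relabeling haplotype columns permutes rows without value changes", {
    pool <- toyPool()
    sim <- simulateCohort(pool, cohortSpec(600, seed = 62), "pop")
    dm <- structure(sim$truth$dosages, major = "H1")
    a <- haplotypeLogistic(dm, sim$phenotypes$status)
    dmP <- structure(sim$truth$dosages[, c("H3", "H1", "H2")], major = "H1")
    b <- haplotypeLogistic(dmP, sim$phenotypes$status)
    expect_equal(a[order(a$haplotype), -1], b[order(b$haplotype), -1],
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("haplotype terms are null-calibrated under permuted status", {
    pool <- toyPool()
    exceed <- 0
    for (s in 1:60) {
        sim <- simulateCohort(pool, cohortSpec(500, seed = 700 + s), "pop")
        set.seed(800 + s)
        status <- sample(sim$phenotypes$status)
        dm <- structure(sim$truth$dosages, major = "H1")
        res <- haplotypeLogistic(dm, status)
        if (any(abs(res$z) >= 3)) exceed <- exceed + 1
    }
    expect_lte(exceed, 1)
})

test_that("rank-deficient designs drop-and-report rather than crash", {
    sim <- simulateCohort(toyPool(), cohortSpec(300, seed = 63), "pop")
    dm <- cbind(structure(sim$truth$dosages, major = "H1"),
                others = 0L)
    attr(dm, "major") <- "H1"
    res <- haplotypeLogistic(dm, sim$phenotypes$status)
    expect_true("block:others" %in% attr(res, "dropped"))
    # a duplicated (aliased) column is reported, not fatal
    dm2 <- structure(cbind(sim$truth$dosages,
                           H2copy = sim$truth$dosages[, "H2"]),
                     major = "H1")
    res2 <- haplotypeLogistic(dm2, sim$phenotypes$status)
    expect_true(length(attr(res2, "dropped")) >= 1)
})

test_that("minor-haplotype effects are estimated conditionally on APOE dosage", {
    # pool over two tag variants: v1 tags the block minor haplotype, v2 the
    # epsilon-4-like coding allele; "11" carries both, so the block minor
    # dosage (v1) and the e4 dosage (v2) are correlated but not collinear.
    pool <- HaplotypePool(
        variants = data.frame(id = c("v1", "v2"), chrom = "19",
                              pos = c(100L, 200L), ref = "A", alt = "G"),
        haplotypes = c(h00 = "00", h11 = "11", h10 = "10", h01 = "01"),
        frequencies = c(h00 = 0.5, h11 = 0.2, h10 = 0.1, h01 = 0.2))

    fitOnce <- function(betaMinor, seed) {
        # log-odds: betaMinor * (block minor dosage) + 0.8 * (e4 dosage)
        spec <- cohortSpec(3000, beta0 = -0.5,
                           betaHaplotypes = c(h11 = 0.8 + betaMinor,
                                              h10 = betaMinor, h01 = 0.8),
                           seed = seed)
        sim <- simulateCohort(pool, spec, "pop")
        gdos <- genotypeDosage(sim$genotypes)
        dm <- structure(cbind(minor = gdos["v1", ]), major = NULL)
        res <- haplotypeLogistic(dm, sim$phenotypes$status,
                                 apoeDosages = data.frame(e4 = gdos["v2", ]))
        res[res$haplotype == "minor", "beta"]
    }

    # risk acts solely through the e4 tag: conditional beta centered at 0
    b0 <- vapply(1:25, function(s) fitOnce(0, 900 + s), numeric(1))
    expect_lt(abs(mean(b0)), 3 * sd(b0) / sqrt(25))

    # an additional independent block effect is recovered conditionally
    b1 <- vapply(1:25, function(s) fitOnce(0.4, 950 + s), numeric(1))
    expect_lt(abs(mean(b1) - 0.4), 4 * sd(b1) / sqrt(25))
})

test_that("robust regression matches OLS on clean data and recovers effects", {
    sim <- simulateCohort(toyPool(), cohortSpec(2000, seed = 64), "pop")
    dm <- structure(sim$truth$dosages, major = "H1")
    y <- simulateExpression(sim$truth$dosages,
                            expressionSpec(alpha = c(H2 = 0.5), sigma = 1,
                                           seed = 65))
    rob <- haplotypeRobustLinear(dm, y)
    ols <- haplotypeRobustLinear(dm, y, engine = "ols")
    expect_lt(max(abs(rob$beta - ols$beta) / (rob$se + ols$se)), 2)
    h2 <- rob[rob$haplotype == "H2", ]
    expect_lt(abs(h2$beta - 0.5), 3 * h2$se)
    expect_error(haplotypeRobustLinear(dm, rep(1, 2000)), "constant trait")
})

test_that("gross outliers tied to carriers break OLS but not Huber", {
    pool <- biallelicPool()
    robBad <- 0; olsBad <- 0
    for (s in 1:40) {
        sim <- simulateCohort(pool, cohortSpec(400, seed = 1100 + s), "pop")
        dos <- sim$truth$dosages
        set.seed(1200 + s)
        y <- rnorm(400)                      # null trait
        carriers <- which(dos[, "MIN"] > 0)
        bad <- sample(carriers, ceiling(0.05 * 400))
        y[bad] <- y[bad] + 50                # 5 % gross outliers in carriers
        dm <- structure(dos, major = "MAJ")
        if (abs(haplotypeRobustLinear(dm, y)$z) >= 3) robBad <- robBad + 1
        if (abs(haplotypeRobustLinear(dm, y, engine = "ols")$z) >= 3)
            olsBad <- olsBad + 1
    }
    expect_lte(robBad, 2)        # robust fit stays null-calibrated >= 95 %
    expect_gte(olsBad, 20)       # OLS is dragged by the contamination
})

test_that("partial Spearman reduces to Spearman and removes confounding", {
    x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3.5)
    y <- c(2, 7, 1, 8, 2, 8.5, 1.8, 2.8, 4, 6)
    expect_equal(partialSpearman(x, y)$rho,
                 cor(x, y, method = "spearman"), tolerance = 1e-12)
    expect_equal(partialSpearman(1:20, exp(1:20))$rho, 1)

    adjOk <- 0
    for (s in 1:20) {
        set.seed(1300 + s)
        u <- rnorm(1000)
        x <- u + rnorm(1000); y <- u + rnorm(1000)
        raw <- cor(x, y, method = "spearman")
        adj <- partialSpearman(x, y, data.frame(u = u))$rho
        expect_gt(abs(raw), 0.3)
        if (abs(adj) < 0.1) adjOk <- adjOk + 1
    }
    expect_gte(adjOk, 19)
    expect_error(partialSpearman(1:3, 1:3, data.frame(u = 1:3)), "n >")
    expect_error(partialSpearman(rep(1, 10), 1:10), "constant")
})

test_that("p-value adjustment follows the two groupings", {
    single <- adjustPvalues(matrix(0.04, 1, 1))
    expect_equal(unname(single$bonferroni[1, 1]), 0.04)
    expect_equal(unname(single$fdr[1, 1]), 0.04)

    # BH across biomarkers within one haplotype (row-wise)
    p <- matrix(c(0.01, 0.02, 0.03, 0.04), 1, 4)
    expect_equal(unname(adjustPvalues(p)$fdr[1, ]), rep(0.04, 4))

    # Bonferroni across haplotypes within one biomarker, capped at 1
    p2 <- matrix(c(0.6, 0.2, 0.01), 3, 1)
    expect_equal(unname(adjustPvalues(p2)$bonferroni[, 1]),
                 c(1, 0.6, 0.03))
    expect_error(adjustPvalues(matrix(numeric(0), 0, 0)), "empty")
    expect_error(adjustPvalues(matrix(c(0.5, 1.2), 1, 2)), "0, 1")
})
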