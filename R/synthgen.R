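## Seeded generators for phased case-control cohorts, expression traits,
## allelic read counts and contact matrices, with known ground truth.
## These are first-class, tested code: every downstream stage of the package
## is exercised against their outputs.

#' Cohort simulation settings
#'
#' Bundles the disease model and covariate distributions for
#' [simulateCohort()]. Disease status is drawn prospectively from a logistic
#' model: `logit P(case) = beta0 + sum_h betaHaplotypes[h] * dosage_h +
#' betaAge * (age - ageMean) + betaSex * sex`. Age is Normal(ageMean, ageSd)
#' truncated to \[50, 100\] (late-onset cohorts recruit at 50+); sex is
#' Bernoulli(sexFraction), coded 0/1.
#'
#' @param nIndividuals number of individuals (>= 2).
#' @param beta0 intercept on the log-odds scale.
#' @param betaHaplotypes named numeric vector of per-haplotype log-odds
#'   effects; names must be haplotype names of the pool. Unnamed haplotypes
#'   get effect 0.
#' @param betaAge,betaSex covariate log-odds effects (age is centered at
#'   `ageMean` before entering the model).
#' @param ageMean,ageSd,sexFraction covariate distribution parameters.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return A list of class `"cohortSpec"`.
#' @export
cohortSpec <- function(nIndividuals, beta0 = 0, betaHaplotypes = NULL,
                       betaAge = 0, betaSex = 0, ageMean = 75, ageSd = 8,
                       sexFraction = 0.5, seed = 1L) {
    stopifnot(nIndividuals >= 2)
    pars <- c(beta0, betaHaplotypes, betaAge, betaSex, ageMean, ageSd,
              sexFraction)
    if (!all(is.finite(pars))) stop("all effect parameters must be finite")
    structure(list(nIndividuals = as.integer(nIndividuals), beta0 = beta0,
                   betaHaplotypes = betaHaplotypes, betaAge = betaAge,
                   betaSex = betaSex, ageMean = ageMean, ageSd = ageSd,
                   sexFraction = sexFraction, seed = as.integer(seed)),
              class = "cohortSpec")
}

.truncNorm <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    bad <- which(x < lo | x > hi)
    while (length(bad)) {
        x[bad] <- stats::rnorm(length(bad), mean, sd)
        bad <- bad[x[bad] < lo | x[bad] > hi]
    }
    x
}

#' Simulate a phased case-control cohort from a haplotype pool
#'
#' Each individual receives two haplotypes drawn i.i.d. from the pool
#' frequencies of `population` (Hardy-Weinberg), covariates are drawn from
#' their stated distributions, and case/control status is Bernoulli on the
#' logistic disease model. The returned genotypes are fully phased and
#' consistent with the drawn haplotypes.
#'
#' Independent RNG sub-streams are derived from `spec$seed` for the
#' haplotype draw, each covariate, and the status draw, so enlarging one
#' component does not perturb the others.
#'
#' @param pool a [HaplotypePool-class].
#' @param spec a [cohortSpec()].
#' @param population a population name present in `frequencies(pool)`.
#' @return A list with elements
#'   \describe{
#'     \item{genotypes}{[PhasedGenotypes-class] (variants x samples).}
#'     \item{phenotypes}{data.frame `sample`, `status` (0/1), `age`, `sex`.}
#'     \item{truth}{list with the drawn haplotype name pairs (`hapA`,
#'       `hapB`), the N x haplotypes dosage matrix, and the linear predictor.}
#'   }
#' @examples
#' pool <- HaplotypePool(
#'   variants = data.frame(id = c("v1", "v2"), chrom = "19",
#'                         pos = c(100L, 200L), ref = "A", alt = "C"),
#'   haplotypes = c(H1 = "00", H2 = "11"),
#'   frequencies = c(H1 = 0.8, H2 = 0.2))
#' sim <- simulateCohort(pool, cohortSpec(100, betaHaplotypes = c(H2 = 0.4),
#'                                        seed = 7), "pop")
#' table(sim$phenotypes$status)
#' @export
simulateCohort <- function(pool, spec, population) {
    stopifnot(is(pool, "HaplotypePool"), inherits(spec, "cohortSpec"))
    freq <- frequencies(pool)
    if (!population %in% colnames(freq))
        stop("unknown population: ", population)
    n <- spec$nIndividuals
    hapNames <- haplotypeNames(pool)
    bh <- stats::setNames(numeric(length(hapNames)), hapNames)
    if (!is.null(spec$betaHaplotypes)) {
        unknown <- setdiff(names(spec$betaHaplotypes), hapNames)
        if (length(unknown))
            stop("betaHaplotypes names not in pool: ",
                 paste(unknown, collapse = ", "))
        bh[names(spec$betaHaplotypes)] <- spec$betaHaplotypes
    }

    idxA <- withSeed(subSeed(spec$seed, 1L),
                     sample.int(length(hapNames), n, replace = TRUE,
                                prob = freq[, population]))
    idxB <- withSeed(subSeed(spec$seed, 2L),
                     sample.int(length(hapNames), n, replace = TRUE,
                                prob = freq[, population]))
    age <- withSeed(subSeed(spec$seed, 3L),
                    .truncNorm(n, spec$ageMean, spec$ageSd, 50, 100))
    sex <- withSeed(subSeed(spec$seed, 4L),
                    stats::rbinom(n, 1L, spec$sexFraction))

    dos <- matrix(0L, n, length(hapNames),
                  dimnames = list(NULL, hapNames))
    for (h in seq_along(hapNames)) dos[, h] <- (idxA == h) + (idxB == h)
    eta <- spec$beta0 + drop(dos %*% bh) +
        spec$betaAge * (age - spec$ageMean) + spec$betaSex * sex
    if (!all(is.finite(eta))) stop("non-finite linear predictor; check spec")
    status <- withSeed(subSeed(spec$seed, 5L),
                       stats::rbinom(n, 1L, stats::plogis(eta)))

    samples <- sprintf("S%04d", seq_len(n))
    hapA <- t(pool@haplotypes[idxA, , drop = FALSE])
    hapB <- t(pool@haplotypes[idxB, , drop = FALSE])
    gt <- .PhasedGenotypes(samples, variantInfo(pool), hapA, hapB)
    pheno <- data.frame(sample = samples, status = status, age = age,
                        sex = sex)
    list(genotypes = gt, phenotypes = pheno,
         truth = list(hapA = hapNames[idxA], hapB = hapNames[idxB],
                      dosages = dos, eta = eta))
}

#' Expression trait simulation settings
#'
#' @param intercept trait intercept.
#' @param alpha named numeric vector of additive per-haplotype effects
#'   (units of the trait per haplotype copy); names must match dosage
#'   columns. Unnamed columns get effect 0.
#' @param betaAge effect per year of (uncentered) age, applied when age is
#'   supplied to [simulateExpression()].
#' @param sigma residual standard deviation (>= 0; 0 gives a noiseless trait).
#' @param seed integer seed.
#' @return A list of class `"expressionSpec"`.
#' @export
expressionSpec <- function(intercept = 0, alpha = NULL, betaAge = 0,
                           sigma = 1, seed = 1L) {
    stopifnot(sigma >= 0)
    structure(list(intercept = intercept, alpha = alpha, betaAge = betaAge,
                   sigma = sigma, seed = as.integer(seed)),
              class = "expressionSpec")
}

#' Simulate an expression trait with additive haplotype effects
#'
#' `y_i = intercept + sum_h alpha_h d_ih + betaAge * age_i + eps_i`,
#' `eps_i ~ Normal(0, sigma^2)`.
#'
#' @param dosages numeric matrix, individuals x haplotype columns (e.g. from
#'   [buildDosageMatrix()] or `truth$dosages` of [simulateCohort()]).
#' @param spec an [expressionSpec()].
#' @param age optional numeric vector of ages (enables the age term).
#' @return Numeric vector of trait values, one per row of `dosages`.
#' @export
simulateExpression <- function(dosages, spec, age = NULL) {
    stopifnot(inherits(spec, "expressionSpec"), is.matrix(dosages))
    n <- nrow(dosages)
    a <- stats::setNames(numeric(ncol(dosages)), colnames(dosages))
    if (!is.null(spec$alpha)) {
        unknown <- setdiff(names(spec$alpha), colnames(dosages))
        if (length(unknown))
            stop("alpha names not among dosage columns: ",
                 paste(unknown, collapse = ", "))
        a[names(spec$alpha)] <- spec$alpha
    }
    mu <- spec$intercept + drop(dosages %*% a)
    if (!is.null(age)) {
        .assertAligned(dosages, age)
        mu <- mu + spec$betaAge * age
    }
    eps <- if (spec$sigma > 0)
        withSeed(subSeed(spec$seed, 11L), stats::rnorm(n, 0, spec$sigma))
    else numeric(n)
    mu + eps
}

#' Allele-specific read-count simulation settings
#'
#' @param nSamples number of heterozygous samples.
#' @param meanDepth mean sequencing depth D (> 0); per-sample depth is
#'   Poisson(D), redrawn while 0 so every sample is observed.
#' @param fraction true alternate-allele fraction f, strictly in (0, 1).
#' @param seed integer seed.
#' @return A list of class `"aseSpec"`.
#' @export
aseSpec <- function(nSamples, meanDepth, fraction, seed = 1L) {
    stopifnot(nSamples >= 1, meanDepth > 0, fraction > 0, fraction < 1)
    structure(list(nSamples = as.integer(nSamples), meanDepth = meanDepth,
                   fraction = fraction, seed = as.integer(seed)),
              class = "aseSpec")
}

#' Simulate allele-specific expression read counts
#'
#' Per sample: depth ~ Poisson(meanDepth) (resampled while 0),
#' `alt_count ~ Binomial(depth, fraction)`, `ref_count = depth - alt_count`.
#'
#' @param spec an [aseSpec()].
#' @return data.frame with columns `sample`, `ref_count`, `alt_count`.
#' @export
simulateAseCounts <- function(spec) {
    stopifnot(inherits(spec, "aseSpec"))
    withSeed(spec$seed, {
        depth <- stats::rpois(spec$nSamples, spec$meanDepth)
        zero <- which(depth == 0L)
        while (length(zero)) {
            depth[zero] <- stats::rpois(length(zero), spec$meanDepth)
            zero <- zero[depth[zero] == 0L]
        }
        alt <- stats::rbinom(spec$nSamples, depth, spec$fraction)
        data.frame(sample = sprintf("A%04d", seq_len(spec$nSamples)),
                   ref_count = depth - alt, alt_count = alt)
    })
}

#' Contact-matrix simulation settings
#'
#' @param nBins number of genomic bins (>= 2).
#' @param binSize bin size in bp.
#' @param baseline baseline Poisson intensity C at unit bin separation (> 0).
#' @param decay distance-decay exponent alpha (>= 0): intensity
#'   `C * |i-j|^-alpha`.
#' @param enriched optional data.frame `i`, `j`, `fold` of implanted enriched
#'   bin pairs (fold > 1).
#' @param chrom chromosome label.
#' @param start coordinate of the first bin.
#' @param seed integer seed.
#' @return A list of class `"contactSpec"`.
#' @export
contactSpec <- function(nBins, binSize = 10000L, baseline = 50,
                        decay = 1, enriched = NULL, chrom = "19",
                        start = 45300001L, seed = 1L) {
    stopifnot(nBins >= 2, baseline > 0, decay >= 0)
    if (!is.null(enriched)) {
        stopifnot(all(c("i", "j", "fold") %in% names(enriched)),
                  all(enriched$fold > 1),
                  all(enriched$i >= 1), all(enriched$j <= nBins))
    }
    structure(list(nBins = as.integer(nBins), binSize = as.integer(binSize),
                   baseline = baseline, decay = decay, enriched = enriched,
                   chrom = chrom, start = as.integer(start),
                   seed = as.integer(seed)),
              class = "contactSpec")
}

#' Simulate a binned chromatin-contact matrix
#'
#' Off-diagonal counts are Poisson with a power-law distance decay,
#' `lambda(i, j) = baseline * |i-j|^-decay * fold(i, j)`, symmetrized on
#' output. Diagonal entries (self-ligation dominated in real data, excluded
#' from enrichment calling) are drawn at the unit-distance intensity.
#'
#' @param spec a [contactSpec()].
#' @return Symmetric integer matrix (nBins x nBins) with attributes `chrom`,
#'   `binSize` and `binStarts`.
#' @export
simulateContactMatrix <- function(spec) {
    stopifnot(inherits(spec, "contactSpec"))
    n <- spec$nBins
    fold <- matrix(1, n, n)
    if (!is.null(spec$enriched))
        for (k in seq_len(nrow(spec$enriched))) {
            i <- spec$enriched$i[k]; j <- spec$enriched$j[k]
            fold[i, j] <- fold[j, i] <- spec$enriched$fold[k]
        }
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    lambda <- spec$baseline * pmax(d, 1)^(-spec$decay) * fold
    m <- matrix(0L, n, n)
    up <- upper.tri(m, diag = TRUE)
    m[up] <- withSeed(spec$seed, stats::rpois(sum(up), lambda[up]))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    structure(m, chrom = spec$chrom, binSize = spec$binSize,
              binStarts = spec$start + (seq_len(n) - 1L) * spec$binSize)
}
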