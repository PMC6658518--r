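## Single-variant statistics: Hardy-Weinberg exact test, allele frequencies,
## LD r-squared, covariate-adjusted logistic association, p from Z.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Levene-Haldane exact conditional test. Given genotype counts, all
#' heterozygote counts compatible with the observed allele totals are
#' enumerated with probability
#' `P(nAa | n, nA) = n! 2^nAa nA! na! / (nAA! nAa! naa! (2n)!)`,
#' and the two-sided p-value is the sum of probabilities of outcomes no more
#' likely than the observed one (the common "exact" convention; no mid-p).
#'
#' @param nAA,nAa,naa genotype counts (non-negative, total >= 1).
#' @return Exact two-sided p-value in (0, 1].
#' @examples
#' hweExactTest(1, 0, 1)   # 1/3
#' hweExactTest(50, 0, 0)  # monomorphic: 1
#' @export
hweExactTest <- function(nAA, nAa, naa) {
    if (any(c(nAA, nAa, naa) < 0)) stop("genotype counts must be >= 0")
    n <- nAA + nAa + naa
    if (n < 1) stop("at least one genotype required")
    nA <- 2 * nAA + nAa
    na <- 2 * naa + nAa
    ## heterozygote counts share the parity of nA and cannot exceed min(nA, na)
    hets <- seq.int(nA %% 2, min(nA, na), by = 2)
    logp <- lgamma(n + 1) + hets * log(2) + lgamma(nA + 1) + lgamma(na + 1) -
        lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
        lgamma((na - hets) / 2 + 1) - lgamma(2 * n + 1)
    pr <- exp(logp - max(logp))
    pr <- pr / sum(pr)
    pObs <- pr[match(nAa, hets)]
    min(1, sum(pr[pr <= pObs * (1 + 1e-9)]))
}

#' Per-variant allele statistics
#'
#' Alternate-allele frequency, minor allele frequency, genotype counts and
#' exact HWE p-value for every variant, computed over samples with complete
#' genotypes at that variant.
#'
#' @param genotypes a [PhasedGenotypes-class] object.
#' @return data.frame with columns `id`, `n`, `altFreq`, `maf`, `nRR`, `nRA`,
#'   `nAA`, `hweP`.
#' @export
alleleStats <- function(genotypes) {
    stopifnot(is(genotypes, "PhasedGenotypes"))
    dos <- genotypeDosage(genotypes)
    v <- variantInfo(genotypes)
    out <- data.frame(id = v$id, n = integer(nrow(v)), altFreq = NA_real_,
                      maf = NA_real_, nRR = 0L, nRA = 0L, nAA = 0L,
                      hweP = NA_real_)
    for (i in seq_len(nrow(v))) {
        d <- dos[i, ]
        d <- d[!is.na(d)]
        out$n[i] <- length(d)
        if (!length(d)) next
        out$nRR[i] <- sum(d == 0L); out$nRA[i] <- sum(d == 1L)
        out$nAA[i] <- sum(d == 2L)
        af <- mean(d) / 2
        out$altFreq[i] <- af
        out$maf[i] <- min(af, 1 - af)
        out$hweP[i] <- hweExactTest(out$nRR[i], out$nRA[i], out$nAA[i])
    }
    out
}

#' Pairwise linkage disequilibrium r-squared
#'
#' `ldR2` returns r2 for one variant pair; `ldMatrix` the full symmetric
#' matrix for a set of variants. The default (`mode = "genotype"`) is the
#' squared Pearson correlation of additive 0/1/2 dosages across samples (the
#' composite measure standard association tools report). With phased input,
#' `mode = "haplotype"` computes `r2 = D^2 / (pA qA pB qB)` from the observed
#' haplotype counts. Monomorphic variants yield `NA` (undefined), never 0.
#'
#' @param genotypes a [PhasedGenotypes-class] object.
#' @param i,j variant ids (or indices).
#' @param mode `"genotype"` (dosage correlation) or `"haplotype"`
#'   (phase-based).
#' @param stat `"r2"` (default) or `"r"` for the signed correlation, the
#'   form fine-mapping consumes as an LD covariance.
#' @return `ldR2`: a single r2 in \[0, 1\] (or signed r in \[-1, 1\]) or
#'   `NA`. `ldMatrix`: a symmetric matrix with unit diagonal for polymorphic
#'   variants.
#' @export
ldR2 <- function(genotypes, i, j, mode = c("genotype", "haplotype"),
                 stat = c("r2", "r")) {
    mode <- match.arg(mode)
    stat <- match.arg(stat)
    stopifnot(is(genotypes, "PhasedGenotypes"))
    ids <- variantInfo(genotypes)$id
    if (is.character(i)) i <- match(i, ids)
    if (is.character(j)) j <- match(j, ids)
    if (anyNA(c(i, j))) stop("unknown variant id")
    r <- if (mode == "genotype") {
        dos <- genotypeDosage(genotypes)
        x <- dos[i, ]; y <- dos[j, ]
        ok <- !is.na(x) & !is.na(y)
        if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0)
            return(NA_real_)
        stats::cor(x[ok], y[ok])
    } else {
        a <- c(genotypes@hapA[i, ], genotypes@hapB[i, ])
        b <- c(genotypes@hapA[j, ], genotypes@hapB[j, ])
        ok <- !is.na(a) & !is.na(b)
        a <- a[ok]; b <- b[ok]
        pA <- mean(a); pB <- mean(b)
        if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
        D <- mean(a * b) - pA * pB
        D / sqrt(pA * (1 - pA) * pB * (1 - pB))
    }
    if (stat == "r2") r^2 else r
}

#' @rdname ldR2
#' @param ids variant ids to include (default: all).
#' @export
ldMatrix <- function(genotypes, ids = NULL,
                     mode = c("genotype", "haplotype"),
                     stat = c("r2", "r")) {
    mode <- match.arg(mode)
    stat <- match.arg(stat)
    stopifnot(is(genotypes, "PhasedGenotypes"))
    if (is.null(ids)) ids <- variantInfo(genotypes)$id
    m <- length(ids)
    r2 <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
    for (a in seq_len(m)) {
        r2[a, a] <- if (is.na(ldR2(genotypes, ids[a], ids[a], mode, stat)))
            NA_real_ else 1
        if (a < m) for (b in seq((a + 1), m)) {
            r2[a, b] <- r2[b, a] <- ldR2(genotypes, ids[a], ids[b], mode,
                                         stat)
        }
    }
    r2
}

#' Covariate-adjusted logistic association for one dosage term
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via `stats::glm`, relative deviance convergence 1e-14, 50
#' iterations) of
#' case/control status on an additive dosage, with optional covariates.
#' Quasi-complete separation is detected through fitted probabilities within
#' 1e-8 of 0 or 1 and flagged rather than silently reported.
#'
#' @param dosage numeric vector (0/1/2 or any additive coding).
#' @param status binary 0/1 vector; both classes must be present.
#' @param covariates optional data.frame/matrix of covariates.
#' @param term label for the dosage term in the output.
#' @return One-row data.frame: `term`, `beta`, `se`, `z`, `p`, `n`,
#'   `converged`, `separation`.
#' @export
logisticAssoc <- function(dosage, status, covariates = NULL,
                          term = "dosage") {
    .assertAligned(dosage, status)
    if (!all(status %in% c(0, 1)) || length(unique(status)) < 2)
        stop("status must be binary with both classes present")
    df <- data.frame(.y = status, .dos = dosage)
    if (!is.null(covariates)) {
        .assertAligned(dosage, covariates)
        df <- cbind(df, as.data.frame(covariates))
    }
    ok <- stats::complete.cases(df)
    df <- df[ok, , drop = FALSE]
    fit <- stats::glm(.y ~ ., data = df, family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-14,
                                                   maxit = 50L))
    co <- summary(fit)$coefficients
    if (!".dos" %in% rownames(co))
        stop("dosage term dropped from the fit (rank deficiency)")
    sep <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
    data.frame(term = term, beta = co[".dos", 1], se = co[".dos", 2],
               z = co[".dos", 1] / co[".dos", 2],
               p = pFromZ(co[".dos", 1] / co[".dos", 2]),
               n = nrow(df), converged = fit$converged, separation = sep,
               row.names = NULL)
}

#' Two-sided normal p-value from a Z statistic
#'
#' `p = 2 * Phi(-|z|)`, evaluated through the normal tail directly (no
#' `1 - CDF` subtraction), so far-tail values (|z| up to 37) do not underflow
#' to zero.
#'
#' @param z numeric vector of Z statistics.
#' @return Two-sided p-values in (0, 1].
#' @examples
#' pFromZ(6.44)   # 1.2e-10
#' pFromZ(-3.28)  # 1.0e-03
#' @export
pFromZ <- function(z) {
    stopifnot(all(is.finite(z)))
    2 * stats::pnorm(-abs(z))
}
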