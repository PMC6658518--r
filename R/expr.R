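## Haplotype/variant-expression association and allele-specific expression
## imbalance testing.

#' Rank-based inverse normal transform
#'
#' Maps values through `qnorm((rank - 0.5) / n)` with average ranks for
#' ties; missing values propagate as missing (they do not consume ranks).
#' Invariant under any strictly monotone transform of the input.
#'
#' @param values numeric vector with at least 2 distinct non-missing values.
#' @return Numeric vector of the same length.
#' @examples
#' inverseNormalTransform(c(10, 20, 30))  # -0.9674, 0, 0.9674
#' @export
inverseNormalTransform <- function(values) {
    ok <- !is.na(values)
    x <- values[ok]
    if (length(x) < 2) stop("need at least 2 non-missing values")
    if (length(unique(x)) == 1)
        stop("all values identical: no ordering information")
    out <- rep(NA_real_, length(values))
    n <- length(x)
    out[ok] <- stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
    out
}

#' Haplotype- or variant-expression association
#'
#' Associates (inverse-normal transformed) expression with haplotype dosages
#' via robust regression ([haplotypeRobustLinear()]) or, for a single
#' variant dosage vector, ordinary least squares.
#'
#' @param dosages dosage matrix/list (haplotype mode) or a numeric vector
#'   (single-variant mode).
#' @param expression numeric trait, typically from
#'   [inverseNormalTransform()].
#' @param covariates optional covariate data.frame.
#' @param engine passed through in haplotype mode (`"huber"` or `"ols"`).
#' @return data.frame of per-term `beta`, `se`, `z` (robust or OLS T), `p`.
#' @export
expressionAssoc <- function(dosages, expression, covariates = NULL,
                            engine = c("huber", "ols")) {
    engine <- match.arg(engine)
    if (is.numeric(dosages) && is.null(dim(dosages))) {
        .assertAligned(dosages, expression)
        if (stats::var(dosages, na.rm = TRUE) == 0)
            stop("constant dosage: nothing to test")
        df <- data.frame(.y = expression, .dos = dosages)
        if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
        fit <- stats::lm(.y ~ ., data = df)
        co <- summary(fit)$coefficients
        t <- co[".dos", 3]
        return(data.frame(term = "dosage", beta = co[".dos", 1],
                          se = co[".dos", 2], z = t,
                          p = 2 * stats::pt(-abs(t), fit$df.residual),
                          n = sum(stats::complete.cases(df))))
    }
    haplotypeRobustLinear(dosages, expression, covariates, engine = engine)
}

#' Per-sample minor-allele expression fractions
#'
#' @param ase data.frame with columns `ref_count`, `alt_count` (and
#'   optionally `sample`).
#' @param minorAllele which allele is the minor/risk allele (`"alt"` or
#'   `"ref"`); supplied by the caller, never inferred from the counts.
#' @param minDepth minimum read depth for a sample to be used.
#' @return Numeric vector of fractions (named by sample when available) with
#'   attribute `excluded` listing samples below the depth filter.
#' @export
allelicFraction <- function(ase, minorAllele = c("alt", "ref"),
                            minDepth = 8) {
    minorAllele <- match.arg(minorAllele)
    stopifnot(all(c("ref_count", "alt_count") %in% names(ase)))
    if (!nrow(ase)) stop("empty ASE table")
    if (any(ase$ref_count < 0 | ase$alt_count < 0))
        stop("negative read counts")
    depth <- ase$ref_count + ase$alt_count
    keep <- depth >= minDepth
    if (!any(keep)) stop("all samples fall below the depth filter")
    minor <- if (minorAllele == "alt") ase$alt_count else ase$ref_count
    f <- minor[keep] / depth[keep]
    if (!is.null(ase$sample)) names(f) <- ase$sample[keep]
    attr(f, "excluded") <- if (!is.null(ase$sample))
        ase$sample[!keep] else which(!keep)
    f
}

#' One-sample t-test for allelic imbalance
#'
#' Two-sided one-sample t-test of the mean minor-allele fraction against the
#' balanced-expression null of 0.5, on n - 1 degrees of freedom.
#'
#' @param fractions per-sample minor-allele fractions (>= 2 values).
#' @return data.frame `meanFraction`, `t`, `df`, `p`, `n`, `degenerate`
#'   (TRUE when the fractions have zero variance, where p collapses to the
#'   0/1 limit).
#' @examples
#' imbalanceTest(c(0.3, 0.35, 0.4))  # t = -5.196, p = 0.0351
#' @export
imbalanceTest <- function(fractions) {
    fractions <- fractions[!is.na(fractions)]
    n <- length(fractions)
    if (n < 2) stop("need at least 2 fractions")
    m <- mean(fractions)
    s <- stats::sd(fractions)
    if (s == 0) {
        return(data.frame(meanFraction = m,
                          t = if (m == 0.5) 0 else sign(m - 0.5) * Inf,
                          df = n - 1, p = if (m == 0.5) 1 else 0,
                          n = n, degenerate = TRUE))
    }
    tt <- stats::t.test(fractions, mu = 0.5)
    data.frame(meanFraction = m, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value, n = n,
               degenerate = FALSE)
}

#' Association of allelic fractions with haplotype dosage
#'
#' Linear model of per-sample minor-allele expression fraction on haplotype
#' dosage plus covariates — tests whether a haplotype shifts the allelic
#' balance of a transcript.
#'
#' @param dosages numeric dosage vector or matrix/list for
#'   [haplotypeRobustLinear()].
#' @param fractions per-sample allelic fractions aligned with the dosages.
#' @param covariates optional covariates.
#' @param engine regression engine in haplotype mode.
#' @return As [expressionAssoc()].
#' @export
hapFractionAssoc <- function(dosages, fractions, covariates = NULL,
                             engine = c("huber", "ols")) {
    if (is.numeric(dosages) && is.null(dim(dosages)) &&
        length(unique(dosages)) < 2)
        stop("a single dosage level offers no contrast")
    expressionAssoc(dosages, fractions, covariates, engine = engine)
}
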