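## Major-haplotype referenced multivariate association: joint logistic fits
## across blocks with APOE-genotype control, robust regression for
## quantitative endophenotypes, partial Spearman correlation, and grouped
## multiple-testing adjustment.

## Assemble the joint design from one or more dosage blocks: each block's
## major column is dropped so every effect is relative to the major
## haplotype; constant or aliased columns are dropped and reported.
.hapDesign <- function(dosages, dropOthers = FALSE) {
    if (is.matrix(dosages)) dosages <- list(block = dosages)
    if (is.null(names(dosages)))
        names(dosages) <- paste0("block", seq_along(dosages))
    cols <- list(); labels <- character(); blocks <- character()
    droppedConst <- character()
    for (b in names(dosages)) {
        dm <- dosages[[b]]
        major <- attr(dm, "major")
        keep <- colnames(dm)
        if (!is.null(major)) keep <- setdiff(keep, major)
        if (dropOthers) keep <- setdiff(keep, "others")
        for (h in keep) {
            x <- dm[, h]
            if (stats::var(x) == 0) {
                droppedConst <- c(droppedConst, paste0(b, ":", h))
                next
            }
            cols[[length(cols) + 1L]] <- x
            labels <- c(labels, h); blocks <- c(blocks, b)
        }
    }
    X <- do.call(cbind, cols)
    ## syntactic internal column names keep the formula interface of the
    ## fitting engines happy; block/haplotype labels travel alongside
    if (!is.null(X)) colnames(X) <- sprintf(".hap%03d", seq_len(ncol(X)))
    list(X = X, labels = labels, blocks = blocks, dropped = droppedConst)
}

## QR rank screen of the assembled design (intercept included): returns the
## names of aliased predictor columns so they can be dropped-and-reported
## before the fit (IRLS does not reliably pivot exact duplicates away).
.aliasedColumns <- function(df) {
    M <- stats::model.matrix(~ ., data = df)
    q <- qr(M)
    if (q$rank == ncol(M)) return(character(0))
    bad <- colnames(M)[q$pivot[(q$rank + 1):ncol(M)]]
    intersect(gsub("`", "", bad, fixed = TRUE), names(df))
}

.termTable <- function(co, design, n, extra = NULL) {
    idx <- match(colnames(design$X), rownames(co))
    found <- !is.na(idx)
    out <- data.frame(block = design$blocks[found],
                      haplotype = design$labels[found],
                      beta = co[idx[found], 1], se = co[idx[found], 2],
                      row.names = NULL)
    out$z <- out$beta / out$se
    out$p <- pFromZ(out$z)
    out$n <- n
    out$composite <- out$haplotype == "others"
    aliased <- paste0(design$blocks, ":", design$labels)[!found]
    attr(out, "dropped") <- c(design$dropped, aliased)
    if (!is.null(extra)) attr(out, "model") <- extra
    out
}

#' Joint logistic association of minor-haplotype dosages
#'
#' Fits a single multivariate logistic model whose design holds the
#' minor-haplotype dosage columns of all supplied blocks (each block's major
#' haplotype is excluded, so betas are log-odds relative to the major
#' haplotype), optional APOE epsilon-4/epsilon-2 genotype dosages, and
#' covariates. The `"others"` pooled column is kept as a regressor by
#' default (flagged composite in the output); with the major column removed
#' the design is full rank despite the row-sum-2 structure.
#'
#' @param dosages a dosage matrix from [buildDosageMatrix()] or a named list
#'   of them (one per block), row-aligned with `status`.
#' @param status binary 0/1 outcome.
#' @param covariates optional data.frame of covariates.
#' @param apoeDosages optional data.frame/matrix with columns `e4`, `e2`
#'   (0/1/2 counts) entering the model as genotype controls.
#' @param dropOthers drop the pooled `"others"` column instead of fitting it.
#' @return data.frame with one row per tested haplotype term: `block`,
#'   `haplotype`, `beta`, `se`, `z`, `p`, `n`, `composite`; attributes
#'   `dropped` (constant/aliased terms) and `model` (flags incl. separation).
#' @export
haplotypeLogistic <- function(dosages, status, covariates = NULL,
                              apoeDosages = NULL, dropOthers = FALSE) {
    design <- .hapDesign(dosages, dropOthers)
    if (is.null(design$X)) stop("no testable haplotype columns")
    .assertAligned(design$X, status)
    if (!all(status %in% c(0, 1)) || length(unique(status)) < 2)
        stop("status must be binary with both classes present")
    df <- data.frame(design$X, check.names = FALSE)
    if (!is.null(apoeDosages)) {
        .assertAligned(design$X, apoeDosages)
        df <- cbind(df, as.data.frame(apoeDosages))
    }
    if (!is.null(covariates)) {
        .assertAligned(design$X, covariates)
        df <- cbind(df, as.data.frame(covariates))
    }
    df$.y <- status
    ok <- stats::complete.cases(df)
    df <- df[ok, , drop = FALSE]
    alias <- .aliasedColumns(df[setdiff(names(df), ".y")])
    if (length(alias)) df <- df[, setdiff(names(df), alias), drop = FALSE]
    fit <- stats::glm(.y ~ ., data = df, family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-14,
                                                   maxit = 50L))
    co <- summary(fit)$coefficients
    ## non-syntactic "block:hap" labels come back backtick-quoted
    rownames(co) <- gsub("`", "", rownames(co), fixed = TRUE)
    sep <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
    .termTable(co, design, nrow(df),
               extra = list(converged = fit$converged, separation = sep,
                            apoeAdjusted = !is.null(apoeDosages)))
}

#' Robust linear association of haplotype dosages with a quantitative trait
#'
#' Huber M-estimation (tuning constant 1.345, MAD residual scale, fitted by
#' iteratively reweighted least squares via `MASS::rlm`) of a quantitative
#' trait on minor-haplotype dosages plus covariates; per-term T uses the
#' robust standard errors with a normal reference distribution. Set
#' `engine = "ols"` for an ordinary least-squares fallback.
#'
#' @inheritParams haplotypeLogistic
#' @param trait numeric trait vector (non-constant).
#' @param engine `"huber"` (default) or `"ols"`.
#' @return data.frame as in [haplotypeLogistic()] (z column is the robust T).
#' @export
haplotypeRobustLinear <- function(dosages, trait, covariates = NULL,
                                  dropOthers = FALSE,
                                  engine = c("huber", "ols")) {
    engine <- match.arg(engine)
    design <- .hapDesign(dosages, dropOthers)
    if (is.null(design$X)) stop("no testable haplotype columns")
    .assertAligned(design$X, trait)
    if (stats::var(trait, na.rm = TRUE) == 0)
        stop("constant trait: zero residual scale")
    df <- data.frame(design$X, check.names = FALSE)
    if (!is.null(covariates)) {
        .assertAligned(design$X, covariates)
        df <- cbind(df, as.data.frame(covariates))
    }
    df$.y <- trait
    ok <- stats::complete.cases(df)
    df <- df[ok, , drop = FALSE]
    alias <- .aliasedColumns(df[setdiff(names(df), ".y")])
    if (length(alias)) df <- df[, setdiff(names(df), alias), drop = FALSE]
    if (engine == "huber") {
        fit <- MASS::rlm(.y ~ ., data = df, psi = MASS::psi.huber,
                         k = 1.345, scale.est = "MAD", maxit = 100)
        if (!fit$converged) warning("robust fit did not converge")
        co <- summary(fit)$coefficients[, 1:2, drop = FALSE]
    } else {
        fit <- stats::lm(.y ~ ., data = df)
        co <- summary(fit)$coefficients[, 1:2, drop = FALSE]
    }
    rownames(co) <- gsub("`", "", rownames(co), fixed = TRUE)
    .termTable(co, design, nrow(df), extra = list(engine = engine))
}

#' Partial Spearman rank correlation
#'
#' Rank-transforms `x` and `y` (average ranks for ties), residualizes each on
#' the covariates by least squares, and correlates the residuals. With no
#' covariates this reduces exactly to the classical Spearman correlation.
#' The p-value uses `t = rho * sqrt((n - 2 - k) / (1 - rho^2))` on
#' `n - 2 - k` degrees of freedom (k = number of covariate columns).
#'
#' @param x,y numeric vectors.
#' @param covariates optional data.frame/matrix of adjustment covariates.
#' @return data.frame `rho`, `p`, `n`, `df`.
#' @export
partialSpearman <- function(x, y, covariates = NULL) {
    .assertAligned(x, y)
    k <- 0L
    cc <- stats::complete.cases(x, y)
    if (!is.null(covariates)) {
        .assertAligned(x, covariates)
        covariates <- as.data.frame(covariates)
        cc <- cc & stats::complete.cases(covariates)
        covariates <- covariates[cc, , drop = FALSE]
        k <- ncol(covariates)
    }
    x <- x[cc]; y <- y[cc]
    n <- length(x)
    if (n <= k + 3) stop("need n > covariates + 3 observations")
    rx <- rank(x); ry <- rank(y)
    if (stats::var(rx) == 0 || stats::var(ry) == 0)
        stop("constant input after ranking")
    if (k > 0) {
        rx <- stats::residuals(stats::lm(rx ~ ., data = covariates))
        ry <- stats::residuals(stats::lm(ry ~ ., data = covariates))
    }
    rho <- stats::cor(rx, ry)
    dfree <- n - 2L - k
    p <- if (abs(rho) >= 1) 0
         else 2 * stats::pt(-abs(rho * sqrt(dfree / (1 - rho^2))), dfree)
    data.frame(rho = rho, p = p, n = n, df = dfree)
}

#' Grouped multiple-testing adjustment for haplotype x biomarker p-values
#'
#' For a matrix of p-values with haplotypes in rows and biomarkers in
#' columns: Bonferroni correction is applied across haplotypes within each
#' biomarker (column-wise, capped at 1), and Benjamini-Hochberg FDR across
#' biomarkers within each haplotype (row-wise) — the two groupings used for
#' endophenotype panels.
#'
#' @param p numeric matrix of raw p-values (rows = haplotypes, columns =
#'   biomarkers); a vector is treated as a single biomarker column.
#' @return List with matrices `bonferroni` and `fdr` in the same layout,
#'   plus `grouping` describing the direction of each adjustment.
#' @export
adjustPvalues <- function(p) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 1,
                                     dimnames = list(names(p), "trait"))
    if (!length(p)) stop("empty p-value input")
    if (any(p <= 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in (0, 1]")
    bon <- apply(p, 2, stats::p.adjust, method = "bonferroni")
    fdr <- t(apply(p, 1, stats::p.adjust, method = "BH"))
    dim(bon) <- dim(fdr) <- dim(p)
    dimnames(bon) <- dimnames(fdr) <- dimnames(p)
    list(bonferroni = bon, fdr = fdr,
         grouping = c(bonferroni = "across haplotypes within biomarker",
                      fdr = "across biomarkers within haplotype"))
}
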