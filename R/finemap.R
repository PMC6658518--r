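## Bayesian fine-mapping of causal variants from Z-scores and LD, in the
## style of summary-statistic causal-configuration enumeration.

#' Fine-mapping settings
#'
#' @param maxCausal maximum number of simultaneously causal variants
#'   enumerated (>= 1).
#' @param gamma per-variant prior probability of being causal, in (0, 1).
#' @param sigma non-centrality scale: a causal variant contributes a mean
#'   shift of `sigma` (in Z units) before LD spreading.
#' @param ridge small diagonal added to the LD matrix for numerical
#'   positive-definiteness (preserves LD structure, unlike eigenvalue
#'   truncation).
#' @param maxConfigurations hard cap on the enumerated configuration count;
#'   exceeding it is an error instructing to lower `maxCausal`.
#' @return A list of class `"fineMapConfig"`.
#' @export
fineMapConfig <- function(maxCausal = 3L, gamma = 0.01, sigma = 5.2,
                          ridge = 1e-3, maxConfigurations = 5e6) {
    stopifnot(maxCausal >= 1, gamma > 0, gamma < 1, sigma > 0, ridge >= 0)
    structure(list(maxCausal = as.integer(maxCausal), gamma = gamma,
                   sigma = sigma, ridge = ridge,
                   maxConfigurations = maxConfigurations),
              class = "fineMapConfig")
}

.configCount <- function(m, cmax) sum(choose(m, 0:cmax))

#' Causal-variant posterior probabilities from Z-scores and LD
#'
#' Enumerates every causal-indicator configuration `c` with at most
#' `maxCausal` causal variants. Under configuration `c`, the vector of
#' absolute Z-scores is modelled as multivariate normal with mean
#' `Sigma %*% lambda(c)` (where `lambda_i = sigma` for causal variants, 0
#' otherwise) and covariance `Sigma = LD + ridge * I`; the prior is
#' `gamma^|c| (1-gamma)^(m-|c|)`. Posteriors are normalized over the
#' enumerated space (log-space likelihoods with log-sum-exp, so |z| around
#' 6.5 does not underflow). The marginal posterior of a variant sums the
#' posteriors of all configurations containing it.
#'
#' Effect-allele orientation is arbitrary, so each variant is first
#' reoriented to make its Z non-negative; the LD matrix is conjugated by the
#' same sign flips (`Sigma -> D Sigma D`, `D = diag(sign(z))`), which
#' preserves positive definiteness and makes the non-negative
#' non-centrality model consistent for negatively correlated proxies.
#'
#' @param z named numeric vector of association Z-scores.
#' @param ld LD matrix (r, or r2-consistent correlation matrix) matching `z`
#'   in dimension; a correlation (r) matrix is expected.
#' @param config a [fineMapConfig()].
#' @return A [FineMapResult-class] object.
#' @examples
#' z <- c(a = 6.4, b = 1.1)
#' ld <- diag(2); dimnames(ld) <- list(names(z), names(z))
#' fm <- caviarPosteriors(z, ld)
#' marginalPosteriors(fm)
#' @export
caviarPosteriors <- function(z, ld, config = fineMapConfig()) {
    stopifnot(inherits(config, "fineMapConfig"))
    m <- length(z)
    if (!all(dim(ld) == c(m, m)))
        stop("LD dimension does not match the Z vector")
    ids <- names(z)
    if (is.null(ids)) ids <- paste0("v", seq_len(m))
    nConf <- .configCount(m, config$maxCausal)
    if (nConf > config$maxConfigurations)
        stop(sprintf(paste0("%.3g configurations exceed the cap (%.3g); ",
                            "lower maxCausal"), nConf,
             config$maxConfigurations))
    flip <- ifelse(z < 0, -1, 1)
    Sigma <- outer(flip, flip) * unname(as.matrix(ld)) +
        config$ridge * diag(m)
    R <- tryCatch(chol(Sigma),
                  error = function(e)
                      stop("LD matrix is not positive definite after the ",
                           "ridge; increase `ridge`"))
    az <- abs(z)
    ## log MVN density at |z| for mean Sigma %*% lambda: with u = R^-T x,
    ## the quadratic form is |u(z) - R lambda|^2 since Sigma lambda maps to
    ## R lambda in the whitened space.
    uz <- backsolve(R, az, transpose = TRUE)
    logdet <- 2 * sum(log(diag(R)))
    const <- -0.5 * (m * log(2 * pi) + logdet)
    lgam <- log(config$gamma); l1mg <- log1p(-config$gamma)

    sizes <- 0:min(config$maxCausal, m)
    labels <- character(nConf); sizeOf <- integer(nConf)
    logpost <- numeric(nConf)
    marg <- numeric(m)
    k <- 0L
    for (s in sizes) {
        combs <- if (s == 0) list(integer(0))
                 else utils::combn(m, s, simplify = FALSE)
        for (cc in combs) {
            k <- k + 1L
            lam <- numeric(m); lam[cc] <- config$sigma
            mu <- drop(R %*% lam)          # whitened mean
            ll <- const - 0.5 * sum((uz - mu)^2)
            logpost[k] <- ll + s * lgam + (m - s) * l1mg
            labels[k] <- paste(ids[cc], collapse = ",")
            sizeOf[k] <- s
        }
    }
    mx <- max(logpost)
    w <- exp(logpost - mx)
    post <- w / sum(w)
    k <- 0L
    for (s in sizes) {
        combs <- if (s == 0) list(integer(0))
                 else utils::combn(m, s, simplify = FALSE)
        for (cc in combs) {
            k <- k + 1L
            if (s > 0) marg[cc] <- marg[cc] + post[k]
        }
    }
    cfg <- data.frame(configuration = labels, size = sizeOf,
                      posterior = post)
    cfg <- cfg[order(-cfg$posterior), , drop = FALSE]
    rownames(cfg) <- NULL
    new("FineMapResult", variantIds = ids, marginal = pmin(marg, 1),
        configurations = cfg,
        parameters = list(maxCausal = config$maxCausal,
                          gamma = config$gamma, sigma = config$sigma,
                          ridge = config$ridge))
}

#' Credible set and threshold rule from a fine-mapping result
#'
#' Grows the set greedily by decreasing marginal posterior until the summed
#' posterior of all configurations contained entirely within the set reaches
#' `rho` (the null configuration is contained in every set). Also reports
#' the simple threshold rule: variants whose marginal posterior reaches
#' `threshold` (default 0.10).
#'
#' @param result a [FineMapResult-class].
#' @param rho credible level in (0, 1\]; `rho = 1` returns all variants with
#'   non-zero marginal posterior.
#' @param threshold marginal-posterior cutoff for the threshold rule.
#' @return List with `credibleSet` (variant ids), `coverage` (achieved
#'   configuration mass), and `aboveThreshold` (threshold-rule ids).
#' @export
credibleSet <- function(result, rho = 0.95, threshold = 0.10) {
    stopifnot(is(result, "FineMapResult"))
    if (rho <= 0 || rho > 1) stop("rho must lie in (0, 1]")
    ids <- result@variantIds
    cfg <- result@configurations
    members <- strsplit(cfg$configuration, ",", fixed = TRUE)
    ord <- order(result@marginal, decreasing = TRUE)
    covered <- function(set) {
        inSet <- vapply(members, function(mm)
            all(mm %in% set) || identical(mm, character(0)), logical(1))
        sum(cfg$posterior[inSet])
    }
    if (rho == 1) {
        sel <- ids[result@marginal > 0]
        return(list(credibleSet = sel, coverage = covered(sel),
                    aboveThreshold = ids[result@marginal >= threshold]))
    }
    sel <- character(0)
    cov <- covered(sel)
    i <- 0L
    while (cov < rho && i < length(ids)) {
        i <- i + 1L
        sel <- ids[ord[seq_len(i)]]
        cov <- covered(sel)
    }
    list(credibleSet = sel, coverage = cov,
         aboveThreshold = ids[result@marginal >= threshold])
}
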