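## Cross-cohort meta-analysis: DerSimonian-Laird heterogeneity,
## inverse-variance random-effects pooling, and the Han-Eskin RE2
## likelihood-ratio test.

#' Cochran Q and DerSimonian-Laird heterogeneity statistics
#'
#' With fixed-effect weights `w = 1/se^2` and pooled `b = sum(w b)/sum(w)`:
#' `Q = sum(w (b_i - b)^2)`, `p_Q` from chi-square on k-1 df,
#' `I2 = max(0, (Q - (k-1))/Q) * 100`, and the DerSimonian-Laird
#' between-study variance `tau2 = max(0, (Q - (k-1)) / (sum(w) -
#' sum(w^2)/sum(w)))`.
#'
#' @param betas,ses per-study effect sizes and standard errors (k >= 2,
#'   ses > 0).
#' @return data.frame `Q`, `pQ`, `I2` (percent), `tau2`, `k`.
#' @examples
#' heterogeneity(c(0.5, 0.1), c(0.1, 0.1))  # Q = 8, I2 = 87.5, tau2 = 0.07
#' @export
heterogeneity <- function(betas, ses) {
    .assertAligned(betas, ses)
    k <- length(betas)
    if (k < 2) stop("at least two studies required")
    if (any(ses <= 0)) stop("standard errors must be positive")
    w <- 1 / ses^2
    bFix <- sum(w * betas) / sum(w)
    Q <- sum(w * (betas - bFix)^2)
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
    data.frame(Q = Q, pQ = stats::pchisq(Q, k - 1, lower.tail = FALSE),
               I2 = I2, tau2 = tau2, k = k)
}

#' Inverse-variance random-effects pooled estimate
#'
#' DerSimonian-Laird random-effects model: weights
#' `w* = 1/(se^2 + tau2_DL)`, pooled `betaRE = sum(w* b)/sum(w*)`,
#' `sdRE = sqrt(1/sum(w*))`, Wald `pRE = 2 Phi(-|betaRE|/sdRE)`. When
#' `tau2 = 0` this reduces to the fixed-effect inverse-variance result.
#'
#' @inheritParams heterogeneity
#' @return data.frame `betaRE`, `sdRE`, `pRE`, together with the
#'   heterogeneity columns of [heterogeneity()].
#' @export
metaRe <- function(betas, ses) {
    het <- heterogeneity(betas, ses)
    w <- 1 / (ses^2 + het$tau2)
    betaRE <- sum(w * betas) / sum(w)
    sdRE <- sqrt(1 / sum(w))
    cbind(data.frame(betaRE = betaRE, sdRE = sdRE,
                     pRE = pFromZ(betaRE / sdRE)), het)
}

## Profile log-likelihood of betas ~ N(mu, se^2 + tau2) at fixed tau2,
## with the closed-form mu-hat plugged in.
.re2ProfileLL <- function(tau2, betas, ses) {
    v <- ses^2 + tau2
    w <- 1 / v
    mu <- sum(w * betas) / sum(w)
    -0.5 * sum(log(2 * pi * v) + (betas - mu)^2 / v)
}

#' Han-Eskin RE2 random-effects likelihood-ratio test
#'
#' Studies are modelled `beta_i ~ Normal(mu, se_i^2 + tau2)`. The statistic
#' is `S = -2 (l0 - l1)` where the null fixes `mu = 0, tau2 = 0` and the
#' alternative maximizes jointly over `mu` (closed form given tau2) and
#' `tau2 >= 0` (bounded one-dimensional profile search on
#' `[0, 10 max(se^2) + var(betas)]`, Brent tolerance 1e-10, with a grid
#' fallback and the boundary checked explicitly). The asymptotic null is the
#' even mixture `p = 0.5 P(chi2_1 > S) + 0.5 P(chi2_2 > S)`; tabulated
#' small-k corrections are not applied.
#'
#' @inheritParams heterogeneity
#' @return data.frame `S` (the LRT statistic, >= 0), `pRE2`, `muHat`,
#'   `tau2Hat`, `k`.
#' @export
metaRe2 <- function(betas, ses) {
    .assertAligned(betas, ses)
    k <- length(betas)
    if (k < 2) stop("at least two studies required")
    if (any(ses <= 0)) stop("standard errors must be positive")
    l0 <- -0.5 * sum(log(2 * pi * ses^2) + betas^2 / ses^2)
    hi <- 10 * max(ses^2) + stats::var(betas)
    opt <- tryCatch(
        stats::optimize(.re2ProfileLL, c(0, hi), betas = betas, ses = ses,
                        maximum = TRUE, tol = 1e-10),
        error = function(e) NULL)
    if (is.null(opt)) {   # optimizer failure: coarse grid fallback
        grid <- seq(0, hi, length.out = 2048)
        ll <- vapply(grid, .re2ProfileLL, numeric(1), betas = betas,
                     ses = ses)
        opt <- list(maximum = grid[which.max(ll)], objective = max(ll))
    }
    ## the boundary tau2 = 0 is not interior to the search interval
    ll0tau <- .re2ProfileLL(0, betas, ses)
    if (ll0tau >= opt$objective) {
        tau2Hat <- 0; l1 <- ll0tau
    } else {
        tau2Hat <- opt$maximum; l1 <- opt$objective
    }
    S <- max(0, -2 * (l0 - l1))
    v <- ses^2 + tau2Hat
    muHat <- sum(betas / v) / sum(1 / v)
    p <- 0.5 * stats::pchisq(S, 1, lower.tail = FALSE) +
         0.5 * stats::pchisq(S, 2, lower.tail = FALSE)
    data.frame(S = S, pRE2 = min(1, p), muHat = muHat, tau2Hat = tau2Hat,
               k = k)
}

#' Full meta-analysis summary for one haplotype across cohorts
#'
#' Combines [metaRe()] and [metaRe2()] into the standard reporting layout:
#' pooled random-effects beta and SD, RE2 p-value, and the heterogeneity
#' block (I2, Q, p_Q, tau2).
#'
#' @inheritParams heterogeneity
#' @return One-row data.frame: `betaRE`, `sdRE`, `pRE2`, `I2`, `Q`, `pQ`,
#'   `tau2`, `k`.
#' @export
metaSummary <- function(betas, ses) {
    re <- metaRe(betas, ses)
    re2 <- metaRe2(betas, ses)
    data.frame(betaRE = re$betaRE, sdRE = re$sdRE, pRE2 = re2$pRE2,
               I2 = re$I2, Q = re$Q, pQ = re$pQ, tau2 = re$tau2, k = re$k)
}
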