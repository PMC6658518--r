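## Internal helpers shared across modules.

## Run `expr` under a fixed RNG seed without disturbing the caller's stream.
withSeed <- function(seed, expr) {
    if (!is.finite(seed)) stop("seed must be a finite number")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Deterministic per-component sub-seed so that adding draws to one generator
## component leaves the others' output untouched.
subSeed <- function(seed, k) {
    as.integer((as.double(seed) * 48271 + k * 1000003) %% 2147483647)
}

.assertAligned <- function(...) {
    lens <- vapply(list(...), NROW, integer(1))
    if (length(unique(lens)) != 1)
        stop("inputs are not row-aligned: lengths ", paste(lens, collapse = ", "))
    invisible(lens[1])
}

## Two-sided normal p from t-like statistics used in several result tables.
.wald <- function(beta, se) {
    z <- beta / se
    data.frame(beta = beta, se = se, z = z, p = pFromZ(z))
}
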