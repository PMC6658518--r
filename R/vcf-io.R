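## Phased VCF input/output. Reading goes through VariantAnnotation so the
## package's own writer is round-trip checked against an independent parser.

#' Write phased genotypes to a VCFv4.2 file
#'
#' Emits a minimal valid VCFv4.2 with a contig header line, phased `GT`
#' fields (`|` separator) and, for variants whose `dr2` is non-missing, a
#' `DR2` INFO field. Missing alleles are written as `.|.`.
#'
#' @param genotypes a [PhasedGenotypes-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readPhasedVcf()] for the round-trip reader.
#' @export
writePhasedVcf <- function(genotypes, path) {
    stopifnot(is(genotypes, "PhasedGenotypes"))
    v <- variantInfo(genotypes)
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s>",
                     unique(as.character(v$chrom))),
             paste0("##INFO=<ID=DR2,Number=1,Type=Float,",
                    "Description=\"Estimated allele dosage R-squared\">"),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sampleIds(genotypes)),
                   collapse = "\t"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    if (nrow(v)) {
        tok <- function(m) ifelse(is.na(m), ".", as.character(m))
        gtm <- matrix(paste0(tok(genotypes@hapA), "|", tok(genotypes@hapB)),
                      nrow = nrow(v))
        info <- ifelse(is.na(v$dr2), ".", sprintf("DR2=%.4g", v$dr2))
        body <- cbind(as.character(v$chrom), v$pos, v$id, v$ref, v$alt,
                      ".", "PASS", info, "GT", gtm)
        writeLines(apply(body, 1, paste, collapse = "\t"), con)
    }
    invisible(path)
}

.parseRegion <- function(region) {
    m <- regmatches(region,
                    regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4)
        stop("malformed region '", region, "'; expected chrom:start-end")
    list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Read a phased VCF into a PhasedGenotypes object
#'
#' Parses a (multi-sample) VCF via `VariantAnnotation::readVcf`, keeping only
#' biallelic records, optionally restricted to a region. The allele left of
#' `|` becomes haplotype A. Records with more than one ALT allele are skipped
#' with a warning (haplotype strings need one token per variant).
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param region optional `"chrom:start-end"` string, 1-based inclusive; a
#'   region excluding all variants yields a 0-variant matrix with the full
#'   sample list.
#' @param unphased what to do with unphased (`/`-separated) genotypes:
#'   `"error"` (strict, default) names the offending sample and position;
#'   `"mask"` sets both alleles missing for that sample/variant.
#' @return A [PhasedGenotypes-class] object.
#' @export
readPhasedVcf <- function(path, region = NULL,
                          unphased = c("error", "mask")) {
    unphased <- match.arg(unphased)
    if (!file.exists(path)) stop("no such file: ", path)
    vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
    rr <- SummarizedExperiment::rowRanges(vcf)
    chrom <- as.character(GenomeInfoDb::seqnames(rr))
    pos <- BiocGenerics::start(rr)

    nalt <- lengths(VariantAnnotation::alt(vcf))
    keep <- nalt == 1L
    if (any(!keep))
        warning(sum(!keep), " multiallelic record(s) skipped")
    if (!is.null(region)) {
        rg <- .parseRegion(region)
        keep <- keep & chrom == rg$chrom & pos >= rg$start & pos <= rg$end
    }
    idx <- which(keep)
    samples <- colnames(vcf)

    v <- data.frame(
        id = if (length(idx)) rownames(vcf)[idx] else character(),
        chrom = chrom[idx],
        pos = pos[idx],
        ref = as.character(VariantAnnotation::ref(vcf))[idx],
        alt = if (length(idx))
            as.character(unlist(VariantAnnotation::alt(vcf)[idx]))
        else character())
    inf <- VariantAnnotation::info(vcf)
    v$dr2 <- if ("DR2" %in% colnames(inf))
        as.numeric(inf$DR2)[idx] else NA_real_
    if (anyDuplicated(v$id)) {
        warning("duplicated variant ids made unique")
        v$id <- make.unique(v$id)
    }

    gtm <- VariantAnnotation::geno(vcf)$GT
    gtm <- gtm[idx, , drop = FALSE]
    sep <- ifelse(grepl("|", gtm, fixed = TRUE), "|",
                  ifelse(grepl("/", gtm, fixed = TRUE), "/", ""))
    badM <- matrix(sep == "/" & !gtm %in% c("./.", ".|."), nrow = nrow(v))
    bad <- which(badM, arr.ind = TRUE)
    if (nrow(bad)) {
        if (unphased == "error")
            stop(sprintf(
                "unphased genotype '%s' for sample %s at %s:%d",
                gtm[bad[1, 1], bad[1, 2]], samples[bad[1, 2]],
                v$chrom[bad[1, 1]], v$pos[bad[1, 1]]))
        gtm[bad] <- ".|."
    }
    a1 <- sub("[|/].*$", "", gtm)
    a2 <- sub("^[^|/]*[|/]", "", gtm)
    a2[sep == ""] <- "."   # haploid/garbage token: treat as missing
    a1[sep == ""] <- "."
    toInt <- function(x) {
        x[x == "."] <- NA
        xi <- suppressWarnings(as.integer(x))
        if (any(stats::na.omit(xi) > 1L))
            stop("allele index > 1 in a record reported as biallelic")
        xi
    }
    hapA <- matrix(toInt(a1), nrow = nrow(v), ncol = length(samples))
    hapB <- matrix(toInt(a2), nrow = nrow(v), ncol = length(samples))
    .PhasedGenotypes(samples, v, hapA, hapB)
}
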