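#' SNP proportion: pooled alternative-allele read fraction
#'
#' The core mapping statistic: for each variant, the number of reads
#' carrying the alternative base divided by the total number of reads
#' covering the position. In a pool of individuals selected for a recessive
#' phenotype it approaches 1 at and near the causal variant and ~0.5 at
#' unlinked heterozygous positions.
#'
#' Positions with total depth below `minDepth` (default 1, i.e. zero-depth
#' positions) are returned as `NA` and are excluded from downstream
#' statistics rather than scored as 0.
#'
#' @param x a [BsaExperiment-class], or a numeric vector of reference
#'   depths.
#' @param altDepth numeric vector of alternative depths (vector method).
#' @param pool optional pool label or index to return a single column.
#' @param minDepth minimum total depth for a defined proportion.
#' @param ... unused.
#' @return For a `BsaExperiment`, a numeric matrix (variants x pools), or a
#'   vector if `pool` is given; for depth vectors, a numeric vector.
#' @export
#' @examples
#' snpProportion(c(1, 0, 20), c(9, 25, 0))  # 0.9, 1, 0
setMethod("snpProportion", "BsaExperiment",
    function(x, pool = NULL, minDepth = 1L, ...) {
        rd <- refDepth(x); ad <- altDepth(x)
        tot <- rd + ad
        p <- ad / tot
        p[tot < minDepth] <- NA_real_
        if (!is.null(pool)) p[, pool] else p
    })

#' @rdname snpProportion
#' @export
setMethod("snpProportion", "numeric", function(x, altDepth, minDepth = 1L, ...) {
    tot <- x + altDepth
    p <- altDepth / tot
    p[tot < minDepth] <- NA_real_
    p
})

#' Filter variants to the EMS mutation spectrum
#'
#' Retains exactly the records whose substitution is G>A or C>T -- the
#' reference-strand signatures of EMS-induced G:C -> A:T transitions on
#' either strand. Order is preserved and the filter is idempotent.
#'
#' @param x a [BsaExperiment-class] or a variant `GRanges` with `ref`/`alt`
#'   metadata columns.
#' @param ... unused.
#' @return Object of the same class, subset to EMS-consistent records.
#' @export
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:3, width = 1),
#'                              ref = c("G", "A", "C"), alt = c("A", "G", "T"))
#' length(emsFilter(gr))  # 2
setMethod("emsFilter", "BsaExperiment", function(x, ...) {
    rr <- SummarizedExperiment::rowRanges(x)
    keep <- emsConsistent(rr$ref, rr$alt)
    x[keep, ]
})

#' @rdname emsFilter
#' @export
setMethod("emsFilter", "GRanges", function(x, ...) {
    x[emsConsistent(x$ref, x$alt)]
})

emsConsistent <- function(ref, alt) {
    (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
}

#' Filter variants by SNP proportion threshold
#'
#' Keeps records whose SNP proportion in the given pool is strictly greater
#' than `tau` (default 0.85, the cut-off used to shortlist linked-region
#' variants). Records with undefined proportion (depth below `minDepth`)
#' are dropped and counted in `metadata(x)$nExcludedLowDepth`.
#'
#' @param x a [BsaExperiment-class].
#' @param pool pool label or index.
#' @param tau proportion threshold in `[0, 1]`; strict inequality.
#' @param minDepth minimum total depth for a defined proportion.
#' @return The subset [BsaExperiment-class].
#' @export
thresholdFilter <- function(x, pool, tau = 0.85, minDepth = 1L) {
    stopifnot(is(x, "BsaExperiment"))
    if (tau < 0 || tau > 1)
        bsaStop("invalid_argument", "tau must be in [0, 1]")
    p <- snpProportion(x, pool = pool, minDepth = minDepth)
    out <- x[!is.na(p) & p > tau, ]
    S4Vectors::metadata(out)$nExcludedLowDepth <- sum(is.na(p))
    out
}

#' Per-chromosome SNP-proportion profile
#'
#' Ordered (position, proportion) series for one pool on one chromosome,
#' ready for scatter plotting against chromosomal position. Unknown
#' chromosomes give an empty series; undefined proportions are dropped.
#'
#' @param x a [BsaExperiment-class].
#' @param pool pool label or index.
#' @param chrom chromosome name.
#' @param minDepth minimum total depth for a defined proportion.
#' @return data.frame with columns `pos` and `proportion`, sorted by `pos`.
#' @export
proportionProfile <- function(x, pool, chrom, minDepth = 1L) {
    stopifnot(is(x, "BsaExperiment"))
    rr <- SummarizedExperiment::rowRanges(x)
    on <- as.character(GenomeInfoDb::seqnames(rr)) == chrom
    p <- snpProportion(x, pool = pool, minDepth = minDepth)
    keep <- on & !is.na(p)
    out <- data.frame(pos = GenomicRanges::start(rr)[keep],
                      proportion = unname(p[keep]))
    out[order(out$pos), , drop = FALSE]
}

#' Plot a SNP-proportion profile
#'
#' Scatter plot of SNP proportion by chromosomal position for one pool and
#' chromosome, with detected linked regions bracketed.
#'
#' @param x a [BsaExperiment-class].
#' @param pool pool label or index.
#' @param chrom chromosome name.
#' @param regions optional `GRanges` of linked regions to mark.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the profile data.frame.
#' @export
plotProportionProfile <- function(x, pool, chrom, regions = NULL, ...) {
    prof <- proportionProfile(x, pool, chrom)
    graphics::plot(prof$pos / 1e6, prof$proportion, pch = 16, cex = 0.6,
                   col = "grey30", ylim = c(0, 1),
                   xlab = sprintf("%s position (Mb)", chrom),
                   ylab = "SNP proportion",
                   main = sprintf("%s pool, %s", pool, chrom), ...)
    if (!is.null(regions) && length(regions)) {
        reg <- regions[as.character(GenomeInfoDb::seqnames(regions)) == chrom]
        if (length(reg))
            graphics::rect(GenomicRanges::start(reg) / 1e6, -0.02,
                           GenomicRanges::end(reg) / 1e6, 1.02,
                           border = "firebrick", lty = 2)
    }
    invisible(prof)
}
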