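#' Detect linked regions by sliding-window SNP proportion
#'
#' Scans each chromosome with windows of `windowN` consecutive variants
#' (ordered by position). A window qualifies when its mean SNP proportion
#' in the selected (suppressed) pool exceeds `tLink` and, when a control
#' pool is supplied, the mean difference suppressed minus control over the
#' window's shared variants (those with defined proportion in both pools)
#' exceeds `deltaMin`. Overlapping qualifying windows are merged into
#' regions; regions holding fewer than `minSnps` variants are dropped.
#' Regions are returned ranked by mean proportion (ties: more variants,
#' then leftmost).
#'
#' @param x a [BsaExperiment-class].
#' @param pool label/index of the selected (suppressed) pool.
#' @param control optional label/index of an unselected pool; adds the
#'   delta criterion.
#' @param windowN window size in consecutive variants (default 15).
#' @param tLink minimum window mean proportion (default 0.75).
#' @param deltaMin minimum suppressed-minus-control window mean difference
#'   (default 0.2; only with `control`).
#' @param minSnps minimum variants per reported region (default 10).
#' @param minDepth minimum total depth for a defined proportion.
#' @return A [GenomicRanges::GRanges] of regions (1-based closed intervals
#'   spanning the member variants) with metadata columns `nVariants`,
#'   `meanProportion` and `meanDelta` (`NA` without a control), in rank
#'   order. Empty, with a warning, if no chromosome has `windowN` usable
#'   variants.
#' @export
detectLinkedRegion <- function(x, pool, control = NULL, windowN = 15L,
                               tLink = 0.75, deltaMin = 0.2, minSnps = 10L,
                               minDepth = 1L) {
    stopifnot(is(x, "BsaExperiment"))
    windowN <- as.integer(windowN)
    if (windowN < 1L) bsaStop("invalid_argument", "windowN must be >= 1")
    rr <- SummarizedExperiment::rowRanges(x)
    pSup <- snpProportion(x, pool = pool, minDepth = minDepth)
    pCtl <- if (!is.null(control))
        snpProportion(x, pool = control, minDepth = minDepth) else NULL
    chroms <- unique(as.character(GenomeInfoDb::seqnames(rr)))
    regions <- list()
    anyScanned <- FALSE
    for (ch in chroms) {
        onCh <- which(as.character(GenomeInfoDb::seqnames(rr)) == ch &
                      !is.na(pSup))
        if (length(onCh) < windowN) next
        anyScanned <- TRUE
        pos <- GenomicRanges::start(rr)[onCh]
        o <- order(pos)
        onCh <- onCh[o]; pos <- pos[o]
        p <- pSup[onCh]
        nWin <- length(onCh) - windowN + 1L
        qualifies <- logical(nWin)
        for (w in seq_len(nWin)) {
            idx <- w:(w + windowN - 1L)
            ok <- mean(p[idx]) > tLink
            if (ok && !is.null(pCtl)) {
                shared <- idx[!is.na(pCtl[onCh[idx]])]
                ok <- length(shared) > 0L &&
                    (mean(pSup[onCh[shared]]) -
                     mean(pCtl[onCh[shared]])) > deltaMin
            }
            qualifies[w] <- ok
        }
        if (!any(qualifies)) next
        ## merge overlapping qualifying windows on the variant-index axis
        r <- rle(qualifies)
        endsAt <- cumsum(r$lengths)
        startsAt <- endsAt - r$lengths + 1L
        for (k in which(r$values)) {
            lo <- startsAt[k]
            hi <- endsAt[k] + windowN - 1L   # last variant of last window
            memb <- onCh[lo:hi]
            if (length(memb) < minSnps) next
            delta <- NA_real_
            if (!is.null(pCtl)) {
                shared <- memb[!is.na(pCtl[memb])]
                if (length(shared))
                    delta <- mean(pSup[shared]) - mean(pCtl[shared])
            }
            regions[[length(regions) + 1L]] <- data.frame(
                chrom = ch, start = min(pos[lo:hi]), end = max(pos[lo:hi]),
                nVariants = length(memb),
                meanProportion = mean(pSup[memb]),
                meanDelta = delta)
        }
    }
    if (!anyScanned)
        warning("no chromosome has ", windowN, " variants with defined ",
                "proportion; no windows scanned")
    if (!length(regions))
        return(GenomicRanges::GRanges(nVariants = integer(),
                                      meanProportion = numeric(),
                                      meanDelta = numeric()))
    tab <- do.call(rbind, regions)
    o <- order(-tab$meanProportion, -tab$nVariants,
               match(tab$chrom, chroms), tab$start)
    tab <- tab[o, , drop = FALSE]
    GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$start, tab$end),
                           nVariants = tab$nVariants,
                           meanProportion = tab$meanProportion,
                           meanDelta = tab$meanDelta)
}
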