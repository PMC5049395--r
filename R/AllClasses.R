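#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges
#' @importFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom IRanges IRanges
#' @importClassesFrom Biostrings DNAStringSet
NULL

## ---------------------------------------------------------------------------
## EmsGenome: a reference genome plus the genetic map scale used for meiosis
## ---------------------------------------------------------------------------

#' EmsGenome: reference sequence with a genetic-map scale
#'
#' A set of named chromosome sequences together with a uniform genetic-map
#' density (centimorgans per megabase) used when simulating meioses. The
#' default density of 4 cM/Mb is an Arabidopsis-like genome-wide average.
#'
#' @slot seq a [Biostrings::DNAStringSet] of chromosome sequences with
#'   unique, non-empty names.
#' @slot mapDensity numeric(1), centimorgans per megabase, > 0.
#'
#' @aliases EmsGenome
#' @export
setClass("EmsGenome",
    representation(seq = "DNAStringSet", mapDensity = "numeric"))

setValidity("EmsGenome", function(object) {
    msg <- NULL
    if (length(object@seq) < 1L)
        msg <- c(msg, "genome must contain at least one chromosome")
    if (any(Biostrings::width(object@seq) < 1L))
        msg <- c(msg, "chromosome sequences must be non-empty")
    nm <- names(object@seq)
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
        msg <- c(msg, "chromosome names must be present and unique")
    if (length(object@mapDensity) != 1L || is.na(object@mapDensity) ||
        object@mapDensity <= 0)
        msg <- c(msg, "mapDensity must be a single positive number")
    if (is.null(msg)) TRUE else msg
})

#' Construct an EmsGenome
#'
#' @param seq a named [Biostrings::DNAStringSet].
#' @param mapDensity centimorgans per megabase (default 4).
#' @return An [EmsGenome-class] object.
#' @export
#' @examples
#' g <- EmsGenome(Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC")))
#' mapDensity(g)
EmsGenome <- function(seq, mapDensity = 4) {
    new("EmsGenome", seq = seq, mapDensity = as.numeric(mapDensity))
}

setMethod("show", "EmsGenome", function(object) {
    cat("EmsGenome with", length(object@seq), "chromosome(s),",
        format(sum(Biostrings::width(object@seq)), big.mark = ","),
        "bp total;", object@mapDensity, "cM/Mb\n")
})

## ---------------------------------------------------------------------------
## GeneModel: a single transcript model on the genome
## ---------------------------------------------------------------------------

#' GeneModel: one transcript model
#'
#' Exon and CDS structure of a single transcript, stored in genomic order as
#' 1-based closed intervals regardless of strand.
#'
#' @slot geneId character(1) identifier.
#' @slot chrom character(1) chromosome name.
#' @slot strand character(1), "+" or "-".
#' @slot exons an [IRanges::IRanges] of exon intervals, sorted and disjoint.
#' @slot cds an [IRanges::IRanges] of CDS intervals; each CDS interval lies
#'   within an exon and the total CDS length is a multiple of 3.
#'
#' @aliases GeneModel
#' @export
setClass("GeneModel",
    representation(geneId = "character", chrom = "character",
                   strand = "character", exons = "IRanges", cds = "IRanges"))

setValidity("GeneModel", function(object) {
    msg <- NULL
    if (length(object@geneId) != 1L || !nzchar(object@geneId))
        msg <- c(msg, "geneId must be a non-empty string")
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    ex <- object@exons
    if (length(ex) < 1L)
        msg <- c(msg, "at least one exon is required")
    st <- IRanges::start(ex); en <- IRanges::end(ex)
    if (is.unsorted(st, strictly = TRUE) ||
        (length(ex) > 1L && any(st[-1L] <= en[-length(ex)])))
        msg <- c(msg, "exons must be sorted and non-overlapping")
    cds <- object@cds
    if (length(cds)) {
        within <- vapply(seq_along(cds), function(i) {
            any(IRanges::start(cds)[i] >= st & IRanges::end(cds)[i] <= en)
        }, logical(1L))
        if (!all(within))
            msg <- c(msg, sprintf("gene %s: CDS intervals must lie within exons",
                                  object@geneId))
        if (sum(IRanges::width(cds)) %% 3L != 0L)
            msg <- c(msg, sprintf("gene %s: CDS length must be a multiple of 3",
                                  object@geneId))
        cst <- IRanges::start(cds)
        if (is.unsorted(cst, strictly = length(cds) > 1L))
            msg <- c(msg, "CDS intervals must be sorted")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a GeneModel
#'
#' @param geneId gene/transcript identifier.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons [IRanges::IRanges] of exons (genomic order).
#' @param cds [IRanges::IRanges] of CDS intervals (genomic order).
#' @return A [GeneModel-class] object.
#' @export
GeneModel <- function(geneId, chrom, strand, exons, cds) {
    new("GeneModel", geneId = as.character(geneId), chrom = as.character(chrom),
        strand = as.character(strand), exons = exons, cds = cds)
}

setMethod("show", "GeneModel", function(object) {
    cat(sprintf("GeneModel %s (%s:%d-%d, %s): %d exon(s), CDS %d bp\n",
                object@geneId, object@chrom,
                min(IRanges::start(object@exons)),
                max(IRanges::end(object@exons)),
                object@strand, length(object@exons),
                sum(IRanges::width(object@cds))))
})

## ---------------------------------------------------------------------------
## BsaExperiment: pooled allele counts per variant, one column per pool
## ---------------------------------------------------------------------------

#' BsaExperiment: per-variant pooled allele depths
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] holding one row per
#' single-nucleotide variant and one column per sequenced pool, with assays
#' `refDepth` and `altDepth` (reads supporting the reference and alternative
#' base). Row ranges carry `ref`, `alt` and, for simulated data, an `origin`
#' label (`"causal"` or `"background"`). Rows are kept sorted by
#' (chromosome, position) and are unique on (chromosome, position, ref, alt).
#'
#' @aliases BsaExperiment
#' @export
setClass("BsaExperiment",
    contains = "RangedSummarizedExperiment")

setValidity("BsaExperiment", function(object) {
    msg <- NULL
    rr <- SummarizedExperiment::rowRanges(object)
    mc <- S4Vectors::mcols(rr)
    if (!all(c("ref", "alt") %in% colnames(mc)))
        return("rowRanges must carry 'ref' and 'alt' columns")
    if (!all(c("refDepth", "altDepth") %in%
             SummarizedExperiment::assayNames(object)))
        return("assays 'refDepth' and 'altDepth' are required")
    if (length(rr)) {
        bases <- c("A", "C", "G", "T")
        if (!all(mc$ref %in% bases) || !all(mc$alt %in% bases))
            msg <- c(msg, "ref and alt must be single bases (SNVs only)")
        if (any(mc$ref == mc$alt))
            msg <- c(msg, "ref must differ from alt")
        key <- paste(GenomeInfoDb::seqnames(rr), GenomicRanges::start(rr),
                     mc$ref, mc$alt)
        if (anyDuplicated(key))
            msg <- c(msg, "(chrom, pos, ref, alt) must be unique")
        o <- order(as.character(GenomeInfoDb::seqnames(rr)),
                   GenomicRanges::start(rr))
        if (!identical(o, seq_along(rr)))
            msg <- c(msg, "rows must be sorted by (chrom, pos)")
    }
    rd <- SummarizedExperiment::assay(object, "refDepth")
    ad <- SummarizedExperiment::assay(object, "altDepth")
    if (any(rd < 0) || any(ad < 0))
        msg <- c(msg, "depths must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' Construct a BsaExperiment
#'
#' Rows are sorted by (chromosome, position) on construction.
#'
#' @param variants a [GenomicRanges::GRanges] of width-1 SNV positions with
#'   metadata columns `ref` and `alt` (and optionally `origin`).
#' @param refDepth,altDepth integer matrices, variants x pools.
#' @param colData optional [S4Vectors::DataFrame] describing the pools; row
#'   names become pool labels.
#' @return A [BsaExperiment-class].
#' @export
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 50), width = 1),
#'                              ref = c("G", "C"), alt = c("A", "T"))
#' x <- BsaExperiment(gr, refDepth = matrix(c(1L, 5L), ncol = 1),
#'                    altDepth = matrix(c(9L, 5L), ncol = 1))
#' snpProportion(x)
BsaExperiment <- function(variants, refDepth, altDepth, colData = NULL) {
    refDepth <- as.matrix(refDepth)
    altDepth <- as.matrix(altDepth)
    storage.mode(refDepth) <- "integer"
    storage.mode(altDepth) <- "integer"
    if (is.null(colData)) {
        labs <- colnames(refDepth)
        if (is.null(labs)) labs <- paste0("pool", seq_len(ncol(refDepth)))
        colData <- S4Vectors::DataFrame(row.names = labs)
    }
    o <- order(as.character(GenomeInfoDb::seqnames(variants)),
               GenomicRanges::start(variants))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(refDepth = refDepth[o, , drop = FALSE],
                      altDepth = altDepth[o, , drop = FALSE]),
        rowRanges = variants[o], colData = colData)
    new("BsaExperiment", se)
}

setMethod("show", "BsaExperiment", function(object) {
    callNextMethod()
    mc <- S4Vectors::mcols(SummarizedExperiment::rowRanges(object))
    if ("origin" %in% colnames(mc) && any(mc$origin == "causal", na.rm = TRUE))
        cat("contains 1 causal variant (simulated truth)\n")
})
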