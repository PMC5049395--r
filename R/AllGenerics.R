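#' @include AllClasses.R
NULL

#' Accessors for bsaMapper classes
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname accessors
#' @export
setGeneric("mapDensity", function(x) standardGeneric("mapDensity"))

#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname accessors
#' @export
setGeneric("exons", function(x, ...) standardGeneric("exons"))

#' @rdname accessors
#' @export
setGeneric("cds", function(x, ...) standardGeneric("cds"))

#' @rdname accessors
#' @export
setGeneric("introns", function(x, ...) standardGeneric("introns"))

#' @rdname accessors
#' @export
setGeneric("refDepth", function(x) standardGeneric("refDepth"))

#' @rdname accessors
#' @export
setGeneric("altDepth", function(x) standardGeneric("altDepth"))

#' @rdname accessors
#' @export
setGeneric("totalDepth", function(x) standardGeneric("totalDepth"))

#' @rdname accessors
#' @export
setGeneric("causalVariant", function(x) standardGeneric("causalVariant"))

#' Pooled SNP proportion
#'
#' @param x a [BsaExperiment-class] or a pair of depth vectors.
#' @param ... further arguments for methods.
#' @export
setGeneric("snpProportion", function(x, ...) standardGeneric("snpProportion"))

#' @rdname emsFilter
#' @export
setGeneric("emsFilter", function(x, ...) standardGeneric("emsFilter"))

#' @rdname accessors
#' @export
setMethod("genomeSeq", "EmsGenome", function(x) x@seq)

#' @rdname accessors
#' @export
setMethod("mapDensity", "EmsGenome", function(x) x@mapDensity)

#' @rdname accessors
#' @export
setMethod("geneId", "GeneModel", function(x) x@geneId)

#' @rdname accessors
#' @export
setMethod("exons", "GeneModel", function(x, ...) x@exons)

#' @rdname accessors
#' @export
setMethod("cds", "GeneModel", function(x, ...) x@cds)

#' Introns of a gene model
#'
#' Gaps between consecutive exons, in genomic order.
#' @rdname accessors
#' @export
setMethod("introns", "GeneModel", function(x, ...) {
    ex <- x@exons
    if (length(ex) < 2L) return(IRanges::IRanges())
    IRanges::IRanges(start = IRanges::end(ex)[-length(ex)] + 1L,
                     end = IRanges::start(ex)[-1L] - 1L)
})

#' @rdname accessors
#' @export
setMethod("refDepth", "BsaExperiment", function(x)
    SummarizedExperiment::assay(x, "refDepth"))

#' @rdname accessors
#' @export
setMethod("altDepth", "BsaExperiment", function(x)
    SummarizedExperiment::assay(x, "altDepth"))

#' @rdname accessors
#' @export
setMethod("totalDepth", "BsaExperiment", function(x)
    refDepth(x) + altDepth(x))

#' Row index and range of the causal variant, if the truth is known
#'
#' @rdname accessors
#' @export
setMethod("causalVariant", "BsaExperiment", function(x) {
    rr <- SummarizedExperiment::rowRanges(x)
    mc <- S4Vectors::mcols(rr)
    if (!"origin" %in% colnames(mc)) return(rr[0])
    rr[which(mc$origin == "causal")]
})
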