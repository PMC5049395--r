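#' Apply EMS mutagenesis to a genome
#'
#' Draws induced point mutations uniformly among G/C sites. EMS alkylates
#' guanine, so essentially all induced changes are G:C -> A:T transitions;
#' on the reference strand a mutation therefore reads as G>A or C>T. One
#' mutation, chosen uniformly among the induced set, is labelled the causal
#' suppressor mutation; all others are background.
#'
#' @param genome an [EmsGenome-class].
#' @param nMutations number of induced mutations (>= 1).
#' @param seed integer seed.
#' @return A [GenomicRanges::GRanges] of width-1 variants sorted by
#'   position, with metadata columns `ref`, `alt` and `origin`
#'   (`"causal"` for exactly one variant, `"background"` otherwise).
#' @export
#' @examples
#' g <- makeGenome(1, 50000, seed = 1)
#' v <- applyEms(g, 20, seed = 2)
#' table(v$origin)
applyEms <- function(genome, nMutations, seed) {
    stopifnot(is(genome, "EmsGenome"))
    nMutations <- as.integer(nMutations)
    if (is.na(nMutations) || nMutations < 1L)
        bsaStop("invalid_argument",
                "nMutations must be >= 1 (a causal mutation must exist)")
    seqs <- genomeSeq(genome)
    sites <- lapply(seq_along(seqs), function(i) gcSites(seqs[[i]]))
    total <- sum(lengths(sites))
    if (total < nMutations)
        bsaStop("infeasible_request",
                "genome has only %d G/C sites; %d mutations requested",
                total, nMutations)
    withSeed(seed, {
        idx <- sample.int(total, nMutations)
        chromOf <- rep.int(seq_along(seqs), lengths(sites))
        posAll <- unlist(sites, use.names = FALSE)
        chrom <- names(seqs)[chromOf[idx]]
        pos <- posAll[idx]
        gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
        ref <- refBaseAt(genome, gr)
        alt <- ifelse(ref == "G", "A", "T")
        origin <- rep("background", nMutations)
        origin[sample.int(nMutations, 1L)] <- "causal"
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(ref = ref, alt = alt,
                                                     origin = origin)
        GenomeInfoDb::seqlevels(gr) <- names(seqs)
        GenomicRanges::sort(gr)
    })
}
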