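#' Generate a random reference genome
#'
#' Draws chromosome sequences i.i.d. per base with the requested G+C
#' fraction. Stands in for a real reference when simulating a mutagenesis
#' experiment end to end.
#'
#' @param nChrom number of chromosomes (>= 1).
#' @param lengths integer vector of chromosome lengths in bp (each >= 1000).
#' @param gcFraction target G+C fraction in (0, 1).
#' @param seed integer seed; identical seeds give identical genomes.
#' @param mapDensity genetic-map density in cM/Mb (default 4, an
#'   Arabidopsis-like genome-wide average).
#' @return An [EmsGenome-class] with chromosomes named `chr1`, `chr2`, ...
#' @export
#' @examples
#' g <- makeGenome(1, 10000, gcFraction = 0.4, seed = 7)
#' Biostrings::width(genomeSeq(g))
makeGenome <- function(nChrom, lengths, gcFraction = 0.36, seed,
                       mapDensity = 4) {
    if (nChrom < 1L)
        bsaStop("invalid_argument", "nChrom must be >= 1")
    lengths <- as.integer(lengths)
    if (length(lengths) != nChrom)
        bsaStop("invalid_argument", "need one length per chromosome")
    if (any(is.na(lengths)) || any(lengths < 1000L))
        bsaStop("invalid_argument", "chromosome lengths must be >= 1000 bp")
    if (gcFraction <= 0 || gcFraction >= 1)
        bsaStop("invalid_argument", "gcFraction must be in (0, 1)")
    prob <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
              G = gcFraction / 2, T = (1 - gcFraction) / 2)
    codes <- utf8ToInt("ACGT")
    seqs <- withSeed(seed, lapply(lengths, function(n) {
        intToUtf8(codes[sample.int(4L, n, replace = TRUE, prob = prob)])
    }))
    dss <- Biostrings::DNAStringSet(unlist(seqs))
    names(dss) <- paste0("chr", seq_len(nChrom))
    EmsGenome(dss, mapDensity = mapDensity)
}

## internal: 1-based positions of G or C on one chromosome, via raw bytes
gcSites <- function(chromSeq) {
    b <- charToRaw(as.character(chromSeq))
    which(b == charToRaw("G") | b == charToRaw("C"))
}

#' Extract reference bases at variant positions
#'
#' @param genome an [EmsGenome-class].
#' @param gr a GRanges of width-1 positions.
#' @return character vector of bases.
#' @keywords internal
refBaseAt <- function(genome, gr) {
    vapply(seq_along(gr), function(i) {
        chr <- as.character(GenomeInfoDb::seqnames(gr))[i]
        as.character(Biostrings::subseq(genomeSeq(genome)[[chr]],
                                        GenomicRanges::start(gr)[i],
                                        GenomicRanges::start(gr)[i]))
    }, character(1L))
}
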