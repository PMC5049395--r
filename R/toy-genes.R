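STOP_CODONS <- c("TAA", "TAG", "TGA")

## random coding sequence: ATG + (nCodons - 2) non-stop codons + stop
randomCodingSeq <- function(nCodons) {
    bases <- c("A", "C", "G", "T")
    mid <- character(nCodons - 2L)
    for (i in seq_along(mid)) {
        repeat {
            cdn <- paste(sample(bases, 3L, replace = TRUE), collapse = "")
            if (!cdn %in% STOP_CODONS) break
        }
        mid[i] <- cdn
    }
    paste0("ATG", paste(mid, collapse = ""), sample(STOP_CODONS, 1L))
}

#' Generate toy gene models on a genome
#'
#' Writes small multi-exon protein-coding genes (ATG start, stop codon
#' end, GT..AG introns, no internal stop codons, CDS identical to the
#' exons) into non-overlapping slots of the genome, on random strands,
#' and returns the matching [GeneModel-class] objects. The genome sequence
#' is modified in place so that models and sequence agree, which makes the
#' models usable for coding-effect and splice-consequence prediction.
#'
#' @param genome an [EmsGenome-class].
#' @param nGenes number of genes to place.
#' @param seed integer seed.
#' @param nExonRange integer range of exon counts per gene.
#' @param codonRange integer range of CDS lengths in codons.
#' @param intronRange integer range of intron lengths in bp.
#' @return list with elements `genome` (modified [EmsGenome-class]) and
#'   `models` (named list of [GeneModel-class]).
#' @export
#' @examples
#' g <- makeGenome(1, 50000, seed = 1)
#' toy <- makeToyGeneModels(g, 3, seed = 2)
#' toy$models[[1]]
makeToyGeneModels <- function(genome, nGenes, seed, nExonRange = c(2L, 4L),
                              codonRange = c(40L, 80L),
                              intronRange = c(60L, 150L)) {
    stopifnot(is(genome, "EmsGenome"))
    nGenes <- as.integer(nGenes)
    if (nGenes < 1L) bsaStop("invalid_argument", "nGenes must be >= 1")
    seqs <- genomeSeq(genome)
    lens <- Biostrings::width(seqs)
    maxGene <- codonRange[2L] * 3L + (nExonRange[2L] - 1L) * intronRange[2L]
    ## round-robin slots across chromosomes
    perChrom <- pmax(0L, lens %/% (maxGene + 200L))
    if (sum(perChrom) < nGenes)
        bsaStop("infeasible_request",
                "genome too small for %d toy genes", nGenes)
    slots <- do.call(rbind, lapply(seq_along(seqs), function(ci) {
        k <- perChrom[ci]
        if (k == 0L) return(NULL)
        data.frame(chrom = names(seqs)[ci],
                   start = 100L + (seq_len(k) - 1L) * (maxGene + 200L))
    }))
    chromChar <- as.list(as.character(seqs))
    names(chromChar) <- names(seqs)
    models <- withSeed(seed, {
        slotIdx <- sort(sample.int(nrow(slots), nGenes))
        lapply(seq_len(nGenes), function(gi) {
            ch <- slots$chrom[slotIdx[gi]]
            gStart <- slots$start[slotIdx[gi]]
            nEx <- sample(nExonRange[1L]:nExonRange[2L], 1L)
            nCod <- sample(codonRange[1L]:codonRange[2L], 1L)
            cdsSeq <- randomCodingSeq(nCod)
            cdsLen <- nchar(cdsSeq)
            ## split the CDS into nEx chunks of >= 10 nt
            cuts <- sort(sample(10:(cdsLen - 10L), nEx - 1L))
            while (anyDuplicated(cuts) || any(diff(c(0L, cuts, cdsLen)) < 10L))
                cuts <- sort(sample(10:(cdsLen - 10L), nEx - 1L))
            chunkStart <- c(1L, cuts + 1L)
            chunkEnd <- c(cuts, cdsLen)
            intrSeqs <- vapply(seq_len(nEx - 1L), function(i) {
                mid <- paste(sample(c("A", "C", "G", "T"),
                                    sample(intronRange[1L]:intronRange[2L], 1L) - 4L,
                                    replace = TRUE), collapse = "")
                paste0("GT", mid, "AG")
            }, character(1L))
            strand <- sample(c("+", "-"), 1L)
            ## assemble gene sequence in transcript orientation
            pieces <- character(0L); types <- character(0L)
            for (i in seq_len(nEx)) {
                pieces <- c(pieces, substr(cdsSeq, chunkStart[i], chunkEnd[i]))
                types <- c(types, "exon")
                if (i < nEx) { pieces <- c(pieces, intrSeqs[i]); types <- c(types, "intron") }
            }
            geneTx <- paste(pieces, collapse = "")
            if (strand == "+") {
                genomicSeq <- geneTx
                w <- nchar(pieces); t2 <- types
            } else {
                genomicSeq <- as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(geneTx)))
                w <- rev(nchar(pieces)); t2 <- rev(types)
            }
            ## write into the chromosome
            s <- chromChar[[ch]]
            substr(s, gStart, gStart + nchar(genomicSeq) - 1L) <- genomicSeq
            chromChar[[ch]] <<- s
            ends <- gStart - 1L + cumsum(w)
            starts <- ends - w + 1L
            exIdx <- t2 == "exon"
            exons <- IRanges::IRanges(starts[exIdx], ends[exIdx])
            GeneModel(geneId = sprintf("toy%03d", gi), chrom = ch,
                      strand = strand, exons = exons, cds = exons)
        })
    })
    names(models) <- vapply(models, geneId, character(1L))
    newSeqs <- Biostrings::DNAStringSet(unlist(chromChar))
    names(newSeqs) <- names(seqs)
    list(genome = EmsGenome(newSeqs, mapDensity = mapDensity(genome)),
         models = models)
}
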