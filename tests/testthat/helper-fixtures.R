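## Shared fixtures, all built in code at test time.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(Biostrings)
    library(SummarizedExperiment)
})

## a BsaExperiment straight from depth vectors (single pool)
quickBsa <- function(chrom, pos, ref, alt, refDepth, altDepth,
                     pool = "suppressed", origin = NULL) {
    gr <- GRanges(chrom, IRanges(pos, width = 1L), ref = ref, alt = alt)
    if (!is.null(origin)) mcols(gr)$origin <- origin
    rd <- matrix(as.integer(refDepth), ncol = 1,
                 dimnames = list(NULL, pool))
    ad <- matrix(as.integer(altDepth), ncol = 1,
                 dimnames = list(NULL, pool))
    BsaExperiment(gr, rd, ad)
}

## a genome with a hand-written plus-strand gene whose CDS is known exactly.
## layout on a 600 bp chromosome of 'A's:
##   exon1 = CDS part 1 at 101..130 (30 bp), intron 131..220 (90 bp,
##   GT..AG, no stop codon in any frame), exon2 = CDS part 2 at 221..280
##   (60 bp, ends in TAA)
handGene <- function(strand = "+") {
    cds1 <- "ATGCCACTGCGACATCATGAAGATCATTGG"           # 10 codons, incl.
    stopifnot(nchar(cds1) == 30)                        # CCA, CTG, CGA
    intron <- paste0("GT", "CC", strrep("CAC", 28), "AG")
    stopifnot(nchar(intron) == 90)
    ## in frame: no internal stop; shifted by -22, an out-of-frame TAA
    ## (chars 26-28) terminates translation early
    cds2 <- "ATGGATCATGAAGATCATCACGGACTAAGCCATCACGATCATGAAGATCATGGATAA"
    stopifnot(nchar(cds2) == 57)
    pad <- function(n) strrep("A", n)
    if (strand == "+") {
        geneSeq <- paste0(cds1, intron, cds2)
        chromSeq <- paste0(pad(100), geneSeq, pad(600 - 100 - nchar(geneSeq)))
        exons <- IRanges(c(101, 221), c(130, 277))
    } else {
        geneSeq <- as.character(reverseComplement(DNAString(
            paste0(cds1, intron, cds2))))
        chromSeq <- paste0(pad(100), geneSeq, pad(600 - 100 - nchar(geneSeq)))
        ## genomic-order exons: transcript exon2 first (reverse complemented)
        exons <- IRanges(c(101, 101 + 57 + 90), c(101 + 56, 101 + 57 + 90 + 29))
    }
    genome <- EmsGenome(DNAStringSet(c(chrT = chromSeq)))
    model <- GeneModel("handgene", "chrT", strand, exons = exons, cds = exons)
    list(genome = genome, model = model,
         cds1 = cds1, intron = intron, cds2 = cds2)
}

## independent oracle: translate a CDS string, return aa before first stop
translateToStop <- function(cdsStr) {
    cdsStr <- substr(cdsStr, 1, (nchar(cdsStr) %/% 3) * 3)
    aa <- as.character(translate(DNAString(cdsStr), if.fuzzy.codon = "X"))
    star <- regexpr("*", aa, fixed = TRUE)
    if (star > 0) substr(aa, 1, star - 1) else aa
}

## independent exhaustive window-scan oracle for linked-region detection:
## direct double loop over windows, then interval merging on indices
oracleLinkedRegions <- function(x, pool, control = NULL, windowN = 15,
                                tLink = 0.75, deltaMin = 0.2, minSnps = 10) {
    rr <- rowRanges(x)
    pS <- snpProportion(x, pool = pool)
    pC <- if (!is.null(control)) snpProportion(x, pool = control) else NULL
    res <- list()
    for (ch in unique(as.character(seqnames(rr)))) {
        idx <- which(as.character(seqnames(rr)) == ch & !is.na(pS))
        idx <- idx[order(start(rr)[idx])]
        if (length(idx) < windowN) next
        qual <- list()
        for (w in seq_len(length(idx) - windowN + 1)) {
            win <- idx[w:(w + windowN - 1)]
            ok <- mean(pS[win]) > tLink
            if (ok && !is.null(pC)) {
                sh <- win[!is.na(pC[win])]
                ok <- length(sh) > 0 && mean(pS[sh]) - mean(pC[sh]) > deltaMin
            }
            if (ok) qual[[length(qual) + 1]] <- c(w, w + windowN - 1)
        }
        if (!length(qual)) next
        ## merge windows overlapping on the index axis
        qual <- do.call(rbind, qual)
        qual <- qual[order(qual[, 1]), , drop = FALSE]
        cur <- qual[1, ]
        flush <- function(cur) {
            memb <- idx[cur[1]:cur[2]]
            if (length(memb) < minSnps) return(NULL)
            data.frame(chrom = ch, start = min(start(rr)[memb]),
                       end = max(start(rr)[memb]), nVariants = length(memb),
                       meanProportion = mean(pS[memb]))
        }
        if (nrow(qual) > 1) for (k in 2:nrow(qual)) {
            if (qual[k, 1] <= cur[2]) cur[2] <- max(cur[2], qual[k, 2])
            else { res[[length(res) + 1]] <- flush(cur); cur <- qual[k, ] }
        }
        res[[length(res) + 1]] <- flush(cur)
    }
    res <- res[!vapply(res, is.null, logical(1))]
    if (!length(res)) return(NULL)
    out <- do.call(rbind, res)
    out[order(-out$meanProportion, -out$nVariants, out$chrom, out$start), ,
        drop = FALSE]
}

## small sorted variant set placed by hand (all EMS-consistent G>A)
handVariants <- function(chrom, pos, causalAt = 1L) {
    origin <- rep("background", length(pos))
    origin[causalAt] <- "causal"
    o <- order(pos)
    GRanges(chrom, IRanges(pos[o], width = 1L),
            ref = "G", alt = "A", origin = origin[o])
}
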