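#' Predict the consequence of a splice-site defect
#'
#' Models the two transcript outcomes observed when a canonical splice
#' site is mutated: retention of the affected intron in the mature mRNA,
#' or activation of a cryptic splice site that removes the intron together
#' with a stated number of additional bases from the start (in transcript
#' orientation) of the following exon. The edited CDS is rebuilt, the
#' frame checked (an insertion or deletion whose length is not a multiple
#' of 3 shifts the reading frame), and the edited sequence translated to
#' locate the first stop codon.
#'
#' @param model a [GeneModel-class]; its CDS must span the edited intron.
#' @param genome the [EmsGenome-class].
#' @param kind `"intron_retention"` or `"cryptic_splice"`.
#' @param intronIndex 1-based intron number in transcript orientation.
#' @param extraExonicBasesRemoved for `"cryptic_splice"`, how many bases of
#'   the following exon are also removed (>= 0; 0 reproduces normal
#'   splicing).
#' @return list with `framePreserved` (logical), `prematureStop` (logical:
#'   is there a stop codon upstream of where the reference stop now sits),
#'   and `proteinLength` (amino acids before the first stop).
#' @export
#' @examples
#' ## see the package vignette for a worked splice-defect example
spliceConsequence <- function(model, genome, kind = c("intron_retention",
                                                      "cryptic_splice"),
                              intronIndex, extraExonicBasesRemoved = 0L) {
    kind <- match.arg(kind)
    intr <- introns(model)
    nIntr <- length(intr)
    if (intronIndex < 1L || intronIndex > nIntr)
        bsaStop("unsupported_edit", "gene %s has %d introns; index %d invalid",
                geneId(model), nIntr, intronIndex)
    ## transcript intron i corresponds to genomic intron i on "+", and to
    ## genomic intron (n - i + 1) on "-"
    gIdx <- if (model@strand == "+") intronIndex else nIntr - intronIndex + 1L
    iv <- intr[gIdx]
    cd <- cds(model)
    leftCds <- which(IRanges::end(cd) == IRanges::start(iv) - 1L)
    rightCds <- which(IRanges::start(cd) == IRanges::end(iv) + 1L)
    if (!length(leftCds) || !length(rightCds))
        bsaStop("unsupported_edit",
                "CDS of %s does not span intron %d", geneId(model), intronIndex)
    chrSeq <- genomeSeq(genome)[[model@chrom]]
    refCds <- cdsSequence(model, genome)
    extraExonicBasesRemoved <- as.integer(extraExonicBasesRemoved)

    if (kind == "intron_retention") {
        indel <- IRanges::width(iv)             # inserted bases
        ivSeq <- Biostrings::subseq(chrSeq, IRanges::start(iv), IRanges::end(iv))
        ## insertion point in transcript coordinates = CDS bases upstream of
        ## the intron in transcript orientation
        upGenomic <- sum(IRanges::width(cd)[seq_len(leftCds)])
        at <- if (model@strand == "+") upGenomic
              else sum(IRanges::width(cd)) -
                   sum(IRanges::width(cd)[seq_len(rightCds - 1L)])
        ins <- if (model@strand == "+") ivSeq
               else Biostrings::reverseComplement(ivSeq)
        edited <- Biostrings::xscat(Biostrings::subseq(refCds, 1L, at), ins,
                                    Biostrings::subseq(refCds, at + 1L))
        shift <- indel
    } else {
        indel <- -extraExonicBasesRemoved       # deleted bases
        ## the "following exon" in transcript orientation
        folIdx <- if (model@strand == "+") rightCds else leftCds
        if (extraExonicBasesRemoved >= IRanges::width(cd)[folIdx])
            bsaStop("unsupported_edit",
                    "cannot remove %d bases from a %d-base exon",
                    extraExonicBasesRemoved, IRanges::width(cd)[folIdx])
        st <- IRanges::start(cd); en <- IRanges::end(cd)
        if (model@strand == "+") st[folIdx] <- st[folIdx] + extraExonicBasesRemoved
        else en[folIdx] <- en[folIdx] - extraExonicBasesRemoved
        pieces <- lapply(seq_along(cd), function(i)
            Biostrings::subseq(chrSeq, st[i], en[i]))
        edited <- do.call(Biostrings::xscat, pieces)
        if (model@strand == "-") edited <- Biostrings::reverseComplement(edited)
        shift <- indel
    }

    framePreserved <- (abs(shift) %% 3L) == 0L
    refStopNt <- firstStopNt(refCds)
    ## where the reference stop codon now starts in the edited transcript:
    ## edits upstream of it shift it by the net inserted length
    refStopInEdited <- if (is.na(refStopNt)) NA_integer_ else refStopNt + shift
    edStopNt <- firstStopNt(edited)
    prematureStop <- !is.na(edStopNt) &&
        (!is.na(refStopInEdited) && edStopNt < refStopInEdited)
    proteinLength <- if (is.na(edStopNt))
        length(edited) %/% 3L else (edStopNt - 1L) %/% 3L
    list(framePreserved = framePreserved, prematureStop = prematureStop,
         proteinLength = as.integer(proteinLength))
}

## 1-based nt position of the first in-frame stop codon, NA if none
firstStopNt <- function(dna) {
    n <- (length(dna) %/% 3L) * 3L
    if (n < 3L) return(NA_integer_)
    codons <- substring(as.character(Biostrings::subseq(dna, 1L, n)),
                        seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
    aa <- Biostrings::GENETIC_CODE[codons]
    hit <- which(aa == "*")
    if (!length(hit)) NA_integer_ else (hit[1L] - 1L) * 3L + 1L
}
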