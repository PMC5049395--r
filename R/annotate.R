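LOCATION_PRECEDENCE <- c("splice_junction", "cds", "utr_or_noncoding_exon",
                         "intron", "intergenic")

## classify one position against one gene model; NA if outside the gene span
locationInModel <- function(pos, model) {
    ex <- exons(model)
    if (pos < min(IRanges::start(ex)) || pos > max(IRanges::end(ex)))
        return(NA_character_)
    intr <- introns(model)
    if (length(intr)) {
        is <- IRanges::start(intr); ie <- IRanges::end(intr)
        if (any((pos >= is & pos <= is + 1L) | (pos >= ie - 1L & pos <= ie)))
            return("splice_junction")
    }
    cd <- cds(model)
    if (length(cd) &&
        any(pos >= IRanges::start(cd) & pos <= IRanges::end(cd)))
        return("cds")
    if (any(pos >= IRanges::start(ex) & pos <= IRanges::end(ex)))
        return("utr_or_noncoding_exon")
    "intron"
}

#' Classify variant positions against gene models
#'
#' Assigns each variant a location class with precedence
#' splice junction > CDS > UTR/non-coding exon > intron > intergenic.
#' "Splice junction" means the two canonical intronic bases at either end
#' of an intron (the GT donor / AG acceptor positions). When a position
#' falls in several genes, the gene giving the highest-precedence class is
#' reported (all hits with `all = TRUE`).
#'
#' @param variants a `GRanges` of width-1 positions.
#' @param models list of [GeneModel-class] objects.
#' @param all if `TRUE`, return one row per (variant, overlapping gene).
#' @return data.frame with columns `variant` (row index), `geneId` (`NA`
#'   for intergenic) and `locationClass`.
#' @export
classifyLocation <- function(variants, models, all = FALSE) {
    chroms <- vapply(models, function(m) m@chrom, character(1L))
    out <- lapply(seq_along(variants), function(i) {
        pos <- GenomicRanges::start(variants)[i]
        ch <- as.character(GenomeInfoDb::seqnames(variants))[i]
        hits <- data.frame(variant = integer(), geneId = character(),
                           locationClass = character())
        for (m in models[chroms == ch]) {
            cl <- locationInModel(pos, m)
            if (!is.na(cl))
                hits <- rbind(hits, data.frame(variant = i, geneId = geneId(m),
                                               locationClass = cl))
        }
        if (!nrow(hits))
            return(data.frame(variant = i, geneId = NA_character_,
                              locationClass = "intergenic"))
        hits <- hits[order(match(hits$locationClass, LOCATION_PRECEDENCE)), ,
                     drop = FALSE]
        if (all) hits else hits[1L, , drop = FALSE]
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

## CDS-coordinate (1-based, transcript orientation) of a genomic position,
## or NA if the position is not in the CDS
cdsCoordinate <- function(pos, model) {
    cd <- cds(model)
    st <- IRanges::start(cd); en <- IRanges::end(cd)
    hit <- which(pos >= st & pos <= en)
    if (!length(hit)) return(NA_integer_)
    before <- if (hit > 1L) sum(en[seq_len(hit - 1L)] - st[seq_len(hit - 1L)] + 1L) else 0L
    g <- before + (pos - st[hit]) + 1L
    if (model@strand == "+") g else sum(en - st + 1L) - g + 1L
}

## CDS nucleotide sequence in transcript orientation
cdsSequence <- function(model, genome) {
    chrSeq <- genomeSeq(genome)[[model@chrom]]
    cd <- cds(model)
    pieces <- lapply(seq_along(cd), function(i)
        Biostrings::subseq(chrSeq, IRanges::start(cd)[i], IRanges::end(cd)[i]))
    s <- do.call(Biostrings::xscat, pieces)
    if (model@strand == "-") s <- Biostrings::reverseComplement(s)
    s
}

complementBase <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

#' Predict the coding effect of a CDS variant
#'
#' Rebuilds the affected codon from the gene model's CDS coordinates
#' (strand-aware: on minus-strand genes the variant base is complemented),
#' translates reference and alternative codons with the standard genetic
#' code, and classifies the substitution.
#'
#' @param variant a single-row `GRanges` with `ref` and `alt` metadata.
#' @param model a [GeneModel-class] whose CDS contains the variant.
#' @param genome the [EmsGenome-class].
#' @return list with `effect` (`"synonymous"`, `"nonsynonymous"` or
#'   `"stop_gained"`) and `aaChange` (e.g. `"P404L"`).
#' @export
codingEffect <- function(variant, model, genome) {
    pos <- GenomicRanges::start(variant)[1L]
    cpos <- cdsCoordinate(pos, model)
    if (is.na(cpos))
        bsaStop("contract_violation",
                "position %s:%d is not in the CDS of %s",
                as.character(GenomeInfoDb::seqnames(variant))[1L], pos,
                geneId(model))
    cdsSeq <- cdsSequence(model, genome)
    ref <- variant$ref[1L]; alt <- variant$alt[1L]
    refTx <- if (model@strand == "+") ref else unname(complementBase(ref))
    altTx <- if (model@strand == "+") alt else unname(complementBase(alt))
    if (as.character(Biostrings::subseq(cdsSeq, cpos, cpos)) != refTx)
        bsaStop("contract_violation",
                "reference base mismatch at CDS position %d of %s",
                cpos, geneId(model))
    codonIdx <- (cpos - 1L) %/% 3L + 1L
    off <- (codonIdx - 1L) * 3L
    refCodon <- as.character(Biostrings::subseq(cdsSeq, off + 1L, off + 3L))
    altCodon <- refCodon
    substr(altCodon, cpos - off, cpos - off) <- altTx
    refAA <- unname(Biostrings::GENETIC_CODE[refCodon])
    altAA <- unname(Biostrings::GENETIC_CODE[altCodon])
    effect <- if (refAA == altAA) "synonymous"
              else if (altAA == "*") "stop_gained"
              else "nonsynonymous"
    list(effect = effect, aaChange = paste0(refAA, codonIdx, altAA))
}

#' Candidate-gene funnel
#'
#' Reduces a set of high-proportion, EMS-consistent variants to gene
#' candidates: variants are kept when they are non-synonymous or
#' stop-gained in a CDS, or sit at an exon-intron junction. Output is
#' sorted by SNP proportion (descending), then position.
#'
#' @param x a [BsaExperiment-class] (typically after [emsFilter()] and
#'   [thresholdFilter()]).
#' @param models list of [GeneModel-class] objects.
#' @param genome the [EmsGenome-class].
#' @param pool pool label/index whose proportions are reported.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `proportion`, `geneId`, `locationClass`, `effect`, `aaChange`.
#' @export
candidateFunnel <- function(x, models, genome, pool = 1L) {
    stopifnot(is(x, "BsaExperiment"))
    rr <- SummarizedExperiment::rowRanges(x)
    if (!length(rr))
        return(data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          proportion = numeric(), geneId = character(),
                          locationClass = character(), effect = character(),
                          aaChange = character()))
    loc <- classifyLocation(rr, models)
    p <- snpProportion(x, pool = pool)
    rows <- lapply(seq_along(rr), function(i) {
        cl <- loc$locationClass[i]
        effect <- "not_applicable"; aa <- ""
        if (cl == "cds") {
            ce <- codingEffect(rr[i], models[[loc$geneId[i]]], genome)
            effect <- ce$effect; aa <- ce$aaChange
        }
        keep <- (cl == "cds" && effect %in% c("nonsynonymous", "stop_gained")) ||
                cl == "splice_junction"
        if (!keep) return(NULL)
        data.frame(chrom = as.character(GenomeInfoDb::seqnames(rr))[i],
                   pos = GenomicRanges::start(rr)[i],
                   ref = rr$ref[i], alt = rr$alt[i],
                   proportion = unname(p[i]),
                   geneId = loc$geneId[i], locationClass = cl,
                   effect = effect, aaChange = aa)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(candidateFunnel(x[0, ], models, genome, pool))
    out <- out[order(-out$proportion, out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
}
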