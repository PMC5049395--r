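#' Read pooled allele depths from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) whose per-sample FORMAT includes
#' `AD` (allelic depths, ref then alt) and returns one [BsaExperiment-class]
#' column per sample. Only single-nucleotide variants are kept: rows whose
#' REF or ALT allele is longer than one base are skipped and counted
#' (`metadata(x)$nSkipped`), never silently dropped. Multi-allelic SNV rows
#' are split into one record per alternative allele, pairing the reference
#' depth with that allele's depth. An `ORIGIN` INFO key, if present, is
#' restored into the `origin` metadata column so simulated truth survives a
#' round trip.
#'
#' @param path VCF file (plain or gzipped).
#' @return A [BsaExperiment-class]; `metadata()` carries `nSkipped`.
#' @export
readPoolVcf <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v, getINFO = TRUE)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    gt <- v@gt
    if (nrow(fix) == 0L) {
        gr <- GenomicRanges::GRanges(ref = character(), alt = character())
        return(BsaExperiment(gr,
            refDepth = matrix(integer(), 0, max(0L, ncol(gt) - 1L)),
            altDepth = matrix(integer(), 0, max(0L, ncol(gt) - 1L))))
    }
    samples <- colnames(gt)[-1L]
    fmt <- gt[, 1L]
    adIdx <- lapply(strsplit(fmt, ":", fixed = TRUE), function(k) match("AD", k))
    recs <- list(); nSkipped <- 0L
    for (i in seq_len(nrow(fix))) {
        ref <- fix[i, "REF"]
        alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
        if (nchar(ref) != 1L || any(nchar(alts) != 1L) ||
            !ref %in% c("A", "C", "G", "T")) {
            nSkipped <- nSkipped + 1L
            next
        }
        if (is.na(adIdx[[i]]))
            bsaStop("format_error",
                    "record %s:%s has no AD in FORMAT", fix[i, "CHROM"],
                    fix[i, "POS"])
        adStr <- vapply(strsplit(gt[i, -1L], ":", fixed = TRUE),
                        `[`, character(1L), adIdx[[i]])
        ad <- lapply(strsplit(adStr, ",", fixed = TRUE), as.integer)
        origin <- NA_character_
        info <- fix[i, "INFO"]
        if (!is.na(info) && grepl("ORIGIN=", info, fixed = TRUE))
            origin <- sub(".*ORIGIN=([^;]+).*", "\\1", info)
        for (a in seq_along(alts)) {
            recs[[length(recs) + 1L]] <- list(
                chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
                ref = ref, alt = alts[a], origin = origin,
                refDepth = vapply(ad, `[`, integer(1L), 1L),
                altDepth = vapply(ad, `[`, integer(1L), a + 1L))
        }
    }
    if (nSkipped > 0L)
        message(nSkipped, " non-SNV record(s) skipped")
    gr <- GenomicRanges::GRanges(
        vapply(recs, `[[`, character(1L), "chrom"),
        IRanges::IRanges(vapply(recs, `[[`, integer(1L), "pos"), width = 1L),
        ref = vapply(recs, `[[`, character(1L), "ref"),
        alt = vapply(recs, `[[`, character(1L), "alt"))
    origin <- vapply(recs, `[[`, character(1L), "origin")
    if (!all(is.na(origin))) S4Vectors::mcols(gr)$origin <- origin
    rd <- t(vapply(recs, `[[`, integer(length(samples)), "refDepth"))
    ad <- t(vapply(recs, `[[`, integer(length(samples)), "altDepth"))
    if (length(samples) == 1L) { rd <- matrix(rd, ncol = 1L); ad <- matrix(ad, ncol = 1L) }
    colnames(rd) <- colnames(ad) <- samples
    x <- BsaExperiment(gr, rd, ad)
    S4Vectors::metadata(x)$nSkipped <- nSkipped
    x
}

#' Write pooled allele depths as a minimal VCF 4.2 file
#'
#' Emits one line per SNV record with FORMAT `AD:DP`, `AD` being
#' `refDepth,altDepth` (the convention is stated in the header). Records
#' are written sorted by (chromosome, position); contig header lines are
#' taken from the row ranges' seqlevels. Simulated `origin` labels are
#' written as an `ORIGIN` INFO key so [readPoolVcf()] can restore them.
#'
#' @param x a [BsaExperiment-class].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
writePoolVcf <- function(x, path) {
    stopifnot(is(x, "BsaExperiment"))
    rr <- SummarizedExperiment::rowRanges(x)
    mc <- S4Vectors::mcols(rr)
    lines <- c(
        "##fileformat=VCFv4.2",
        "##source=bsaMapper",
        '##INFO=<ID=ORIGIN,Number=1,Type=String,Description="Simulated variant origin (causal/background)">',
        '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
        '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
        paste0("##contig=<ID=", GenomeInfoDb::seqlevels(rr), ">"),
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(x)), collapse = "\t"))
    if (length(rr)) {
        info <- rep(".", length(rr))
        if ("origin" %in% colnames(mc) && !all(is.na(mc$origin)))
            info <- ifelse(is.na(mc$origin), ".",
                           paste0("ORIGIN=", mc$origin))
        rd <- refDepth(x); ad <- altDepth(x)
        sampleCols <- vapply(seq_len(nrow(rd)), function(i)
            paste(paste0(rd[i, ], ",", ad[i, ], ":", rd[i, ] + ad[i, ]),
                  collapse = "\t"), character(1L))
        lines <- c(lines, paste(
            as.character(GenomeInfoDb::seqnames(rr)),
            GenomicRanges::start(rr), ".", mc$ref, mc$alt, ".", ".",
            info, "AD:DP", sampleCols, sep = "\t"))
    }
    writeLines(lines, path)
    invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports gene/mRNA/exon/CDS features (via \pkg{rtracklayer}) and builds
#' one [GeneModel-class] per mRNA from its child exon and CDS features.
#' Models violating the class invariants (unsorted or overlapping exons,
#' CDS outside exons, CDS length not a multiple of 3) raise a `model_error`
#' naming the transcript.
#'
#' @param path GFF3 file.
#' @return A named list of [GeneModel-class] objects.
#' @export
readGeneModels <- function(path) {
    g <- rtracklayer::import(path)
    type <- as.character(g$type)
    mrna <- g[type == "mRNA"]
    if (length(mrna) == 0L) mrna <- g[type == "gene"]  # intron-less annotations
    models <- lapply(seq_along(mrna), function(i) {
        id <- mrna$ID[i]
        kids <- g[!is.na(vapply(g$Parent, function(p)
            if (length(p)) p[1L] else NA_character_, character(1L))) &
            vapply(g$Parent, function(p)
                if (length(p)) p[1L] else NA_character_, character(1L)) == id]
        ex <- kids[as.character(kids$type) == "exon"]
        cd <- kids[as.character(kids$type) == "CDS"]
        ex <- GenomicRanges::sort(ex); cd <- GenomicRanges::sort(cd)
        tryCatch(
            GeneModel(geneId = id,
                      chrom = as.character(GenomeInfoDb::seqnames(mrna))[i],
                      strand = as.character(BiocGenerics::strand(mrna))[i],
                      exons = IRanges::IRanges(GenomicRanges::start(ex),
                                               GenomicRanges::end(ex)),
                      cds = IRanges::IRanges(GenomicRanges::start(cd),
                                             GenomicRanges::end(cd))),
            error = function(e) bsaStop("model_error",
                "invalid gene model '%s': %s", id, conditionMessage(e)))
    })
    names(models) <- vapply(models, geneId, character(1L))
    models
}

#' Write gene models as GFF3
#'
#' @param models list of [GeneModel-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(models, path) {
    lines <- "##gff-version 3"
    for (m in models) {
        ex <- exons(m); cd <- cds(m)
        lo <- min(IRanges::start(ex)); hi <- max(IRanges::end(ex))
        gid <- geneId(m)
        row <- function(type, s, e, attrs)
            paste(m@chrom, "bsaMapper", type, s, e, ".", m@strand, ".",
                  attrs, sep = "\t")
        lines <- c(lines,
            row("gene", lo, hi, sprintf("ID=%s_g", gid)),
            row("mRNA", lo, hi, sprintf("ID=%s;Parent=%s_g", gid, gid)),
            vapply(seq_along(ex), function(i)
                row("exon", IRanges::start(ex)[i], IRanges::end(ex)[i],
                    sprintf("ID=%s_exon%d;Parent=%s", gid, i, gid)),
                character(1L)),
            vapply(seq_along(cd), function(i)
                row("CDS", IRanges::start(cd)[i], IRanges::end(cd)[i],
                    sprintf("ID=%s_cds%d;Parent=%s", gid, i, gid)),
                character(1L)))
    }
    writeLines(lines, path)
    invisible(path)
}

#' Read / write the reference genome as FASTA
#'
#' @param path FASTA file.
#' @param mapDensity genetic-map density (cM/Mb) to attach on read.
#' @param genome an [EmsGenome-class] to write.
#' @return `readGenomeFasta` returns an [EmsGenome-class];
#'   `writeGenomeFasta` returns `path` invisibly.
#' @export
readGenomeFasta <- function(path, mapDensity = 4) {
    s <- Biostrings::readDNAStringSet(path)
    names(s) <- sub("\\s.*$", "", names(s))
    EmsGenome(s, mapDensity = mapDensity)
}

#' @rdname readGenomeFasta
#' @export
writeGenomeFasta <- function(genome, path) {
    Biostrings::writeXStringSet(genomeSeq(genome), path)
    invisible(path)
}
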