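#' Run the mapping analysis on a pooled variant table
#'
#' Applies the analysis funnel in order: EMS spectrum filter, SNP
#' proportions, proportion-threshold filter, sliding-window linked-region
#' detection, and the intersection of thresholded variants with the
#' detected regions. Record counts at every step are reported so the
#' funnel shape (total -> EMS -> threshold -> in-region) can be audited.
#'
#' @param x a [BsaExperiment-class].
#' @param pool label/index of the selected (suppressed) pool.
#' @param control optional label/index of an unselected control pool.
#' @param tau SNP-proportion threshold (strict; default 0.85).
#' @param windowN,tLink,deltaMin,minSnps linked-region parameters, see
#'   [detectLinkedRegion()].
#' @param outdir optional directory; when given, proportion and region
#'   TSVs are written there.
#' @param plots also write per-chromosome profile PNGs (needs `outdir`).
#' @return list with `emsTable`, `thresholded`, `regions`, `inRegion`
#'   (thresholded variants overlapping a region), `counts` (named funnel
#'   counts) and `files` (paths written, if any).
#' @export
runMapping <- function(x, pool = "suppressed", control = NULL, tau = 0.85,
                       windowN = 15L, tLink = 0.75, deltaMin = 0.2,
                       minSnps = 10L, outdir = NULL, plots = TRUE) {
    stopifnot(is(x, "BsaExperiment"))
    emsTab <- emsFilter(x)
    thresholded <- thresholdFilter(emsTab, pool = pool, tau = tau)
    regions <- detectLinkedRegion(emsTab, pool = pool, control = control,
                                  windowN = windowN, tLink = tLink,
                                  deltaMin = deltaMin, minSnps = minSnps)
    inRegion <- if (length(regions)) {
        hits <- GenomicRanges::findOverlaps(
            SummarizedExperiment::rowRanges(thresholded), regions)
        thresholded[unique(S4Vectors::queryHits(hits)), ]
    } else thresholded[0, ]
    counts <- c(total = nrow(x), ems = nrow(emsTab),
                threshold = nrow(thresholded), inRegion = nrow(inRegion))
    files <- character(0)
    if (!is.null(outdir)) {
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        rr <- SummarizedExperiment::rowRanges(emsTab)
        p <- snpProportion(emsTab)
        propTab <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(rr)),
                              pos = GenomicRanges::start(rr),
                              ref = rr$ref, alt = rr$alt)
        propTab <- cbind(propTab, as.data.frame(p))
        f1 <- file.path(outdir, "snp_proportions.tsv")
        utils::write.table(propTab, f1, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        regTab <- if (length(regions)) data.frame(
            chrom = as.character(GenomeInfoDb::seqnames(regions)),
            start = GenomicRanges::start(regions),
            end = GenomicRanges::end(regions),
            nVariants = regions$nVariants,
            meanProportion = regions$meanProportion,
            meanDelta = regions$meanDelta)
        else data.frame(chrom = character(), start = integer(),
                        end = integer(), nVariants = integer(),
                        meanProportion = numeric(), meanDelta = numeric())
        f2 <- file.path(outdir, "linked_regions.tsv")
        utils::write.table(regTab, f2, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files <- c(f1, f2)
        if (plots) for (ch in GenomeInfoDb::seqlevels(rr)) {
            fp <- file.path(outdir, sprintf("profile_%s_%s.png", pool, ch))
            grDevices::png(fp, width = 900, height = 420)
            plotProportionProfile(emsTab, pool, ch, regions = regions)
            grDevices::dev.off()
            files <- c(files, fp)
        }
    }
    list(emsTable = emsTab, thresholded = thresholded, regions = regions,
         inRegion = inRegion, counts = counts, files = files)
}

#' Relocate the causal mutation to a splice junction
#'
#' Moves the causal label (and position) of a simulated mutation set to a
#' canonical splice-junction base of a random gene model, mirroring a
#' suppressor screen whose causal lesions disrupt splice sites. The chosen
#' base is a G or C, so the induced change stays within the EMS spectrum.
#'
#' @param variants variant `GRanges` from [applyEms()].
#' @param models list of [GeneModel-class] with at least one intron.
#' @param genome the [EmsGenome-class].
#' @param seed integer seed.
#' @return The updated, sorted variant `GRanges`.
#' @export
placeCausalAtSpliceSite <- function(variants, models, genome, seed) {
    withIntron <- Filter(function(m) length(introns(m)) > 0L, models)
    if (!length(withIntron))
        bsaStop("infeasible_request", "no gene model has an intron")
    withSeed(seed, {
        m <- withIntron[[sample.int(length(withIntron), 1L)]]
        intr <- introns(m)[sample.int(length(introns(m)), 1L)]
        cand <- c(IRanges::start(intr), IRanges::start(intr) + 1L,
                  IRanges::end(intr) - 1L, IRanges::end(intr))
        gr0 <- GenomicRanges::GRanges(m@chrom, IRanges::IRanges(cand, width = 1L))
        bases <- refBaseAt(genome, gr0)
        ok <- which(bases %in% c("G", "C"))
        pick <- ok[sample.int(length(ok), 1L)]
        newCausal <- GenomicRanges::GRanges(
            m@chrom, IRanges::IRanges(cand[pick], width = 1L),
            ref = bases[pick],
            alt = ifelse(bases[pick] == "G", "A", "T"),
            origin = "causal")
        GenomeInfoDb::seqlevels(newCausal) <-
            GenomeInfoDb::seqlevels(variants)
        out <- variants
        out$origin[out$origin == "causal"] <- "background"
        ## drop any background variant colliding with the new position
        clash <- as.character(GenomeInfoDb::seqnames(out)) == m@chrom &
                 GenomicRanges::start(out) == cand[pick]
        out <- out[!clash]
        GenomicRanges::sort(c(out, newCausal))
    })
}

#' Default configuration of a full pipeline run
#'
#' Extends [defaultExperimentConfig()] with the mapping, annotation and
#' reporting parameters of [fullRun()].
#'
#' @return named list.
#' @export
defaultRunConfig <- function() {
    c(defaultExperimentConfig(),
      list(nToyGenes = 8L, causalAtSpliceSite = TRUE,
           tau = 0.85, windowN = 15L, tLink = 0.75, deltaMin = 0.2,
           minSnps = 10L, writePlots = TRUE))
}

#' Read / write a run configuration
#'
#' @param path YAML file of parameters (unknown keys rejected).
#' @param config configuration list to write.
#' @return `readRunConfig` returns the merged configuration list.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path))
        bsaStop("invalid_argument", "config file '%s' does not exist", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    bad <- setdiff(names(user), names(defaultRunConfig()))
    if (length(bad))
        bsaStop("invalid_argument", "unknown config key(s): %s",
                paste(bad, collapse = ", "))
    utils::modifyList(defaultRunConfig(), user)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(config, path, precision = 15L)
    invisible(path)
}

#' Run the whole simulated mapping experiment end to end
#'
#' Simulation, sequencing, mapping funnel and candidate annotation in the
#' order of the real experiment: generate a genome with toy gene models,
#' induce EMS mutations (placing the causal one at a splice junction by
#' default), grow a backcross F2, bulk and sequence phenotyped pools,
#' compute SNP proportions, filter by EMS spectrum and proportion
#' threshold, detect the linked region, and annotate in-region variants
#' into gene candidates. All inputs and outputs (FASTA, GFF3, VCF, truth
#' file, TSV reports, plots, resolved config, log) are written to
#' `outdir`.
#'
#' @param config configuration list (see [defaultRunConfig()]); missing
#'   entries take their defaults.
#' @param seed master integer seed; every stage seed derives from it.
#' @param outdir output directory (required; created if absent).
#' @return Invisibly, a list with the simulation (`sim`), mapping result
#'   (`mapping`), `candidates` data.frame, funnel `counts` and output
#'   `files`.
#' @export
fullRun <- function(config = list(), seed, outdir) {
    if (missing(outdir) || is.null(outdir) || !nzchar(outdir))
        bsaStop("invalid_argument", "an output directory is required")
    cfg <- utils::modifyList(defaultRunConfig(), config)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    logLines <- sprintf("bsaMapper full run; master seed %d", as.integer(seed))

    genome <- makeGenome(cfg$nChrom, cfg$chromLengths, cfg$gcFraction,
                         seed = deriveSeed(seed, "genome"),
                         mapDensity = cfg$mapDensity)
    toy <- makeToyGeneModels(genome, cfg$nToyGenes,
                             seed = deriveSeed(seed, "genes"))
    genome <- toy$genome
    variants <- applyEms(genome, cfg$nMutations, seed = deriveSeed(seed, "ems"))
    if (isTRUE(cfg$causalAtSpliceSite))
        variants <- placeCausalAtSpliceSite(variants, toy$models, genome,
                                            seed = deriveSeed(seed, "causal"))
    sim <- simulateExperiment(cfg, seed, genome = genome, variants = variants)

    fasta <- file.path(outdir, "genome.fasta")
    gff <- file.path(outdir, "genes.gff3")
    vcf <- file.path(outdir, "variants.vcf")
    truthFile <- file.path(outdir, "truth.yaml")
    writeGenomeFasta(genome, fasta)
    writeGeneModels(toy$models, gff)
    writePoolVcf(sim$experiment, vcf)
    writeTruth(sim$truth, truthFile)

    control <- if (isTRUE(cfg$includeControl)) "non_suppressed" else NULL
    mapping <- runMapping(sim$experiment, pool = "suppressed",
                          control = control, tau = cfg$tau,
                          windowN = cfg$windowN, tLink = cfg$tLink,
                          deltaMin = cfg$deltaMin, minSnps = cfg$minSnps,
                          outdir = outdir, plots = isTRUE(cfg$writePlots))
    candidates <- candidateFunnel(mapping$inRegion, toy$models, genome,
                                  pool = "suppressed")
    candFile <- file.path(outdir, "candidates.tsv")
    utils::write.table(candidates, candFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    counts <- c(mapping$counts, candidates = nrow(candidates))
    logLines <- c(logLines,
        sprintf("stage seeds: %s",
                paste(sprintf("%s=%d", c("genome", "genes", "ems", "causal", "f2"),
                              vapply(c("genome", "genes", "ems", "causal", "f2"),
                                     function(s) deriveSeed(seed, s), integer(1L))),
                      collapse = " ")),
        sprintf("funnel: total=%d ems=%d threshold=%d inRegion=%d candidates=%d",
                counts["total"], counts["ems"], counts["threshold"],
                counts["inRegion"], counts["candidates"]))
    cfgFile <- file.path(outdir, "config.yaml")
    writeRunConfig(cfg, cfgFile)
    logFile <- file.path(outdir, "log.txt")
    writeLines(logLines, logFile)
    invisible(list(sim = sim, mapping = mapping, candidates = candidates,
                   counts = counts,
                   files = c(fasta, gff, vcf, truthFile, candFile,
                             mapping$files, cfgFile, logFile)))
}
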