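#' Default parameters of a simulated suppressor-mapping experiment
#'
#' The values define the study conditions the package emulates: an
#' Arabidopsis-like scaled genome (5 chromosomes at 4 cM/Mb), ~200 induced
#' EMS mutations, a backcross F2 of 200 plants, bulks of 30 phenotyped
#' individuals of which up to two may be misscored, and pooled sequencing
#' at 50x mean depth with a 0.5% per-read miscall rate.
#'
#' @return A named list of parameters understood by [simulateExperiment()].
#' @export
defaultExperimentConfig <- function() {
    list(
        nChrom         = 5L,
        chromLengths   = rep(3e6, 5L),
        gcFraction     = 0.36,
        mapDensity     = 4,
        nMutations     = 200L,
        nIndividuals   = 200L,
        poolSize       = 30L,
        nMisclassified = 2L,
        includeControl = TRUE,
        meanDepth      = 50,
        errorRate      = 0.005
    )
}

#' Simulate a complete mapping-by-sequencing experiment
#'
#' Runs the generative model end to end: random reference genome, EMS
#' mutagenesis with one causal recessive suppressor mutation, backcross F2,
#' bulked suppressed pool (optionally with misscored members) and a
#' non-suppressed control pool, and pooled allele counts per variant.
#' Per-stage seeds are derived deterministically from the master seed.
#'
#' @param config parameter list as from [defaultExperimentConfig()];
#'   missing entries take their defaults.
#' @param seed master integer seed.
#' @param genome optional pre-built [EmsGenome-class] (e.g. one carrying
#'   toy gene models); when supplied the genome stage is skipped.
#' @param variants optional pre-built variant `GRanges`; when supplied the
#'   mutagenesis stage is skipped.
#' @return A list with elements `genome` ([EmsGenome-class]), `variants`
#'   (`GRanges`), `population` ([F2Population-class]), `pools` (list of
#'   [Pool-class]), `experiment` ([BsaExperiment-class]) and `truth`
#'   (a `bsaTruth` list; see [writeTruth()]).
#' @export
#' @examples
#' cfg <- defaultExperimentConfig()
#' cfg$nMutations <- 50; cfg$nIndividuals <- 150
#' sim <- simulateExperiment(cfg, seed = 11)
#' sim$experiment
simulateExperiment <- function(config = list(), seed, genome = NULL,
                               variants = NULL) {
    cfg <- utils::modifyList(defaultExperimentConfig(), config)
    if (is.null(genome))
        genome <- makeGenome(cfg$nChrom, cfg$chromLengths, cfg$gcFraction,
                             seed = deriveSeed(seed, "genome"),
                             mapDensity = cfg$mapDensity)
    if (is.null(variants))
        variants <- applyEms(genome, cfg$nMutations,
                             seed = deriveSeed(seed, "ems"))
    population <- simulateF2(variants, genome, cfg$nIndividuals,
                             seed = deriveSeed(seed, "f2"))
    pools <- list(
        suppressed = buildPool(population, cfg$poolSize, "suppressed",
                               cfg$nMisclassified,
                               seed = deriveSeed(seed, "pool_suppressed"),
                               label = "suppressed"))
    if (isTRUE(cfg$includeControl))
        pools$non_suppressed <- buildPool(
            population, cfg$poolSize, "non_suppressed", 0L,
            seed = deriveSeed(seed, "pool_control"),
            label = "non_suppressed")
    counts <- lapply(names(pools), function(nm)
        sequencePool(pools[[nm]], cfg$meanDepth, cfg$errorRate,
                     seed = deriveSeed(seed, paste0("seq_", nm))))
    names(counts) <- names(pools)
    rd <- vapply(counts, `[[`, numeric(length(variants)), "refDepth")
    ad <- vapply(counts, `[[`, numeric(length(variants)), "altDepth")
    cd <- S4Vectors::DataFrame(
        poolClass = vapply(pools, function(p) p@intendedClass, character(1L)),
        nMisclassified = vapply(pools, function(p) p@nMisclassified, integer(1L)),
        row.names = names(pools))
    expt <- BsaExperiment(variants, rd, ad, colData = cd)
    ci <- which(variants$origin == "causal")
    truth <- structure(class = "bsaTruth", list(
        causal = list(chrom = as.character(GenomeInfoDb::seqnames(variants))[ci],
                      pos = GenomicRanges::start(variants)[ci],
                      ref = variants$ref[ci], alt = variants$alt[ci]),
        seed = as.integer(seed),
        params = cfg,
        phenotype = phenotype(population),
        dosageRows = apply(dosage(population), 1L, paste, collapse = "")))
    list(genome = genome, variants = variants, population = population,
         pools = pools, experiment = expt, truth = truth)
}

#' Write / read the simulation truth file
#'
#' The truth file records everything needed to audit a simulated run: the
#' causal variant, the master seed, all parameters, per-individual
#' phenotypes and the full dosage matrix (one compact digit-string per
#' individual). It round-trips losslessly.
#'
#' @param truth a `bsaTruth` list from [simulateExperiment()].
#' @param path file path (YAML, JSON-compatible scalars).
#' @return `writeTruth` returns `path` invisibly; `readTruth` returns the
#'   `bsaTruth` list.
#' @export
writeTruth <- function(truth, path) {
    stopifnot(inherits(truth, "bsaTruth"))
    yaml::write_yaml(unclass(truth), path, precision = 15L)
    invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    x <- yaml::read_yaml(path)
    x$causal$pos <- as.integer(x$causal$pos)
    x$seed <- as.integer(x$seed)
    ip <- c("nChrom", "nMutations", "nIndividuals", "poolSize", "nMisclassified")
    for (p in ip) x$params[[p]] <- as.integer(x$params[[p]])
    x$params$chromLengths <- as.numeric(x$params$chromLengths)
    x$phenotype <- as.character(x$phenotype)
    x$dosageRows <- as.character(x$dosageRows)
    structure(x, class = "bsaTruth")
}
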