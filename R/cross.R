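#' F2Population: simulated backcross F2 genotypes
#'
#' Alt-allele dosages (0/1/2) per individual and variant for an F2 derived
#' by selfing an F1 that is heterozygous at every induced variant, plus the
#' phenotype implied by the recessive rule at the causal variant.
#'
#' @slot dosage integer matrix, individuals x variants.
#' @slot phenotype character vector, `"suppressed"` or `"non_suppressed"`.
#' @slot variants the variant [GenomicRanges::GRanges] the columns refer to.
#'
#' @aliases F2Population
#' @export
setClass("F2Population",
    representation(dosage = "matrix", phenotype = "character",
                   variants = "GRanges"))

setValidity("F2Population", function(object) {
    msg <- NULL
    if (ncol(object@dosage) != length(object@variants))
        msg <- c(msg, "one dosage column per variant required")
    if (nrow(object@dosage) != length(object@phenotype))
        msg <- c(msg, "one phenotype per individual required")
    if (length(object@dosage) && !all(object@dosage %in% 0:2))
        msg <- c(msg, "dosages must be 0, 1 or 2")
    if (!all(object@phenotype %in% c("suppressed", "non_suppressed")))
        msg <- c(msg, "unknown phenotype label")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "F2Population", function(object) {
    cat(sprintf("F2Population: %d individuals x %d variants; %d suppressed (%.3f)\n",
                nrow(object@dosage), ncol(object@dosage),
                sum(object@phenotype == "suppressed"),
                mean(object@phenotype == "suppressed")))
})

## one meiotic gamete: haplotype indicator (1 = mutagenized parent) at each
## variant position, Poisson crossovers with uniform positions (no
## interference, i.e. Haldane's model)
gameteHaplotypes <- function(posByChrom, lenByChrom, morgansByChrom) {
    unlist(lapply(seq_along(posByChrom), function(i) {
        k <- stats::rpois(1L, morgansByChrom[i])
        startHap <- sample.int(2L, 1L) - 1L
        if (k == 0L)
            return(rep.int(startHap, length(posByChrom[[i]])))
        bp <- sort(stats::runif(k, 0, lenByChrom[i]))
        (startHap + findInterval(posByChrom[[i]], bp)) %% 2L
    }), use.names = FALSE)
}

#' Simulate a backcross F2 population
#'
#' The suppressor line (homozygous for every induced variant) is crossed to
#' its non-mutagenized parent; the F1 is uniformly heterozygous. Each F2
#' individual is formed from two independent F1 gametes. Crossovers per
#' chromosome are Poisson with mean equal to the chromosome's genetic length
#' in Morgans (from the genome's `mapDensity`), with positions uniform --
#' Haldane's no-interference model. The phenotype is suppressed iff the
#' individual is homozygous for the alternative allele at the causal
#' variant (single recessive causal mutation), so an F2 segregates
#' ~1 suppressed : 3 non-suppressed.
#'
#' @param variants variant `GRanges` from [applyEms()].
#' @param genome the [EmsGenome-class] the variants lie on.
#' @param nIndividuals F2 population size.
#' @param seed integer seed.
#' @return An [F2Population-class].
#' @export
#' @examples
#' g <- makeGenome(1, 100000, seed = 1)
#' v <- applyEms(g, 10, seed = 2)
#' pop <- simulateF2(v, g, 200, seed = 3)
#' mean(phenotype(pop) == "suppressed")
simulateF2 <- function(variants, genome, nIndividuals, seed) {
    stopifnot(is(genome, "EmsGenome"), is(variants, "GRanges"))
    nIndividuals <- as.integer(nIndividuals)
    if (is.na(nIndividuals) || nIndividuals < 1L)
        bsaStop("invalid_argument", "nIndividuals must be >= 1")
    seqs <- genomeSeq(genome)
    chromNames <- names(seqs)
    vchrom <- as.character(GenomeInfoDb::seqnames(variants))
    if (!all(vchrom %in% chromNames))
        bsaStop("invalid_argument", "variants lie off the genome")
    if (sum(variants$origin == "causal") != 1L)
        bsaStop("invalid_argument", "exactly one causal variant required")
    ## group variant positions by chromosome, preserving row order
    ord <- order(match(vchrom, chromNames), GenomicRanges::start(variants))
    if (!identical(ord, seq_along(variants)))
        bsaStop("invalid_argument", "variants must be sorted (use applyEms output)")
    posByChrom <- split(GenomicRanges::start(variants),
                        factor(vchrom, levels = chromNames))
    lenByChrom <- Biostrings::width(seqs)
    morgans <- lenByChrom / 1e6 * mapDensity(genome) / 100
    m <- length(variants)
    causalIdx <- which(variants$origin == "causal")
    dosage <- withSeed(seed, {
        d <- matrix(0L, nrow = nIndividuals, ncol = m)
        for (i in seq_len(nIndividuals)) {
            d[i, ] <- gameteHaplotypes(posByChrom, lenByChrom, morgans) +
                      gameteHaplotypes(posByChrom, lenByChrom, morgans)
        }
        d
    })
    phen <- ifelse(dosage[, causalIdx] == 2L, "suppressed", "non_suppressed")
    new("F2Population", dosage = dosage, phenotype = phen, variants = variants)
}

#' @rdname accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname accessors
#' @export
setMethod("dosage", "F2Population", function(x) x@dosage)

#' @rdname accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname accessors
#' @export
setMethod("phenotype", "F2Population", function(x) x@phenotype)

#' Pool: phenotyped individuals bulked for sequencing
#'
#' @slot label pool label.
#' @slot intendedClass the phenotype class the pool was scored as.
#' @slot dosage integer dosage matrix, members x variants.
#' @slot memberPhenotype true phenotype of each member.
#' @slot nMisclassified number of members whose true phenotype differs from
#'   the intended class.
#'
#' @aliases Pool
#' @export
setClass("Pool",
    representation(label = "character", intendedClass = "character",
                   dosage = "matrix", memberPhenotype = "character",
                   nMisclassified = "integer"))

setMethod("show", "Pool", function(object) {
    cat(sprintf("Pool '%s': %d %s individuals (%d misclassified)\n",
                object@label, nrow(object@dosage), object@intendedClass,
                object@nMisclassified))
})

#' Build a phenotyped pool from an F2 population
#'
#' Draws `poolSize - nMisclassified` members uniformly from the requested
#' phenotype class and `nMisclassified` members uniformly from the opposite
#' class, emulating occasional misscoring when bulking tissue. Because the
#' misscored members of a suppressed pool come from the genuine
#' non-suppressed F2 class, they are heterozygous : wild-type at the causal
#' locus in the Mendelian ~2:1 proportion.
#'
#' @param population an [F2Population-class].
#' @param poolSize number of individuals to bulk (default 30).
#' @param class `"suppressed"` or `"non_suppressed"`.
#' @param nMisclassified how many members are misscored (default 0).
#' @param seed integer seed.
#' @param label pool label (defaults to the class name).
#' @return A [Pool-class].
#' @export
buildPool <- function(population, poolSize = 30, class = "suppressed",
                      nMisclassified = 0, seed, label = class) {
    stopifnot(is(population, "F2Population"))
    class <- match.arg(class, c("suppressed", "non_suppressed"))
    poolSize <- as.integer(poolSize)
    nMisclassified <- as.integer(nMisclassified)
    if (is.na(poolSize) || poolSize < 1L)
        bsaStop("invalid_argument", "poolSize must be >= 1")
    if (is.na(nMisclassified) || nMisclassified < 0L)
        bsaStop("invalid_argument", "nMisclassified must be >= 0")
    if (nMisclassified > poolSize)
        bsaStop("infeasible_request",
                "cannot misclassify %d of %d pool members",
                nMisclassified, poolSize)
    phen <- phenotype(population)
    inClass <- which(phen == class)
    outClass <- which(phen != class)
    nTrue <- poolSize - nMisclassified
    if (length(inClass) < nTrue || length(outClass) < nMisclassified)
        bsaStop("infeasible_request",
                "population has %d '%s' and %d other individuals; need %d + %d",
                length(inClass), class, length(outClass), nTrue, nMisclassified)
    members <- withSeed(seed, {
        c(inClass[sample.int(length(inClass), nTrue)],
          outClass[sample.int(length(outClass), nMisclassified)])
    })
    new("Pool", label = label, intendedClass = class,
        dosage = dosage(population)[members, , drop = FALSE],
        memberPhenotype = phen[members],
        nMisclassified = nMisclassified)
}

#' Simulate pooled short-read allele counts
#'
#' Total depth at each variant is Poisson with the given mean. The pooled
#' alternative-allele frequency is the mean dosage over members divided
#' by two; each read reports the alternative base with probability
#' `p * (1 - errorRate) + (1 - p) * errorRate` (a symmetric per-read
#' miscall model).
#'
#' @param pool a [Pool-class].
#' @param meanDepth mean sequencing depth per position (> 0; default 50).
#' @param errorRate per-read miscall probability in `[0, 0.5)`
#'   (default 0.005).
#' @param seed integer seed.
#' @return A list with integer vectors `refDepth` and `altDepth`, one entry
#'   per variant.
#' @export
sequencePool <- function(pool, meanDepth = 50, errorRate = 0.005, seed) {
    stopifnot(is(pool, "Pool"))
    if (meanDepth <= 0)
        bsaStop("invalid_argument", "meanDepth must be > 0")
    if (errorRate < 0 || errorRate >= 0.5)
        bsaStop("invalid_argument", "errorRate must be in [0, 0.5)")
    p <- colMeans(pool@dosage) / 2
    pObs <- p * (1 - errorRate) + (1 - p) * errorRate
    withSeed(seed, {
        depth <- stats::rpois(length(p), meanDepth)
        alt <- stats::rbinom(length(p), depth, pObs)
        list(refDepth = depth - alt, altDepth = alt)
    })
}
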