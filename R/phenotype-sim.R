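#' Simulate a floral-organ retention table
#'
#' Generates per-flower retention counts (petals + sepals, 0-8) for floral
#' positions 1-15 of several genotypes, as scored in a brush-treatment
#' abscission assay. Counts are Gaussian around the supplied per-position
#' means, rounded and clamped to the 0-8 range.
#'
#' @param genotypeMeans numeric matrix (genotypes x 15 positions) of mean
#'   retained organs per flower, all in `[0, 8]`; row names are genotype
#'   labels. A vector of length 15 is treated as a single genotype.
#' @param nIndividuals individuals scored per genotype (default 10).
#' @param noiseSd standard deviation of the Gaussian noise before rounding.
#' @param seed integer seed.
#' @return A data.frame with columns `genotype`, `individual`, `position`,
#'   `retained` -- 15 rows per individual.
#' @export
#' @examples
#' m <- rbind(wildtype = rep(0, 15), mutant = rep(8, 15))
#' tab <- simulatePhenotypeTable(m, nIndividuals = 3, noiseSd = 0, seed = 1)
#' retentionSummary(tab, "mutant")$score
simulatePhenotypeTable <- function(genotypeMeans, nIndividuals = 10,
                                   noiseSd = 1, seed) {
    if (is.vector(genotypeMeans))
        genotypeMeans <- matrix(genotypeMeans, nrow = 1,
                                dimnames = list("genotype1", NULL))
    if (ncol(genotypeMeans) != 15L)
        bsaStop("invalid_argument", "need means for all 15 floral positions")
    if (any(genotypeMeans < 0 | genotypeMeans > 8))
        bsaStop("invalid_argument", "per-position means must lie in [0, 8]")
    if (noiseSd < 0)
        bsaStop("invalid_argument", "noiseSd must be >= 0")
    nIndividuals <- as.integer(nIndividuals)
    genos <- rownames(genotypeMeans)
    if (is.null(genos)) genos <- paste0("genotype", seq_len(nrow(genotypeMeans)))
    withSeed(seed, {
        rows <- lapply(seq_along(genos), function(gi) {
            mu <- rep(genotypeMeans[gi, ], times = nIndividuals)
            raw <- stats::rnorm(length(mu), mean = mu, sd = noiseSd)
            data.frame(genotype = genos[gi],
                       individual = rep(seq_len(nIndividuals), each = 15L),
                       position = rep(1:15, times = nIndividuals),
                       retained = pmin(8L, pmax(0L, as.integer(round(raw)))))
        })
        do.call(rbind, rows)
    })
}
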