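#' Score one flower's retained organs
#'
#' A pre-abscission flower has four petals and four sepals, so the maximum
#' retained post-abscission is eight.
#'
#' @param petals retained petals, 0-4.
#' @param sepals retained sepals, 0-4.
#' @return Integer sum in 0-8 (vectorized).
#' @export
#' @examples
#' scoreFlower(4, 4)  # 8
scoreFlower <- function(petals, sepals) {
    if (any(is.na(petals)) || any(is.na(sepals)) ||
        any(petals < 0 | petals > 4) || any(sepals < 0 | sepals > 4) ||
        any(petals != round(petals)) || any(sepals != round(sepals)))
        bsaStop("invalid_argument", "petal and sepal counts must be integers in 0..4")
    as.integer(petals + sepals)
}

## normalize a retention table: accept either a 'retained' column or
## petals + sepals columns
normalizeRetention <- function(tab) {
    need <- c("genotype", "individual", "position")
    if (!all(need %in% names(tab)))
        bsaStop("invalid_argument", "retention table needs columns %s",
                paste(need, collapse = ", "))
    if (!"retained" %in% names(tab)) {
        if (!all(c("petals", "sepals") %in% names(tab)))
            bsaStop("invalid_argument",
                    "need a 'retained' column or 'petals' + 'sepals' columns")
        tab$retained <- scoreFlower(tab$petals, tab$sepals)
    }
    if (any(tab$retained < 0 | tab$retained > 8))
        bsaStop("invalid_argument", "retained counts must lie in 0..8")
    tab
}

#' Summarize floral-organ retention for one genotype
#'
#' Per-position means over individuals for floral positions 1-15, plus the
#' genotype's abscission score: the sum of the position 8-15 means.
#' Abscission is complete by position 8, so the score (0-64) summarizes
#' how many organs a genotype retains post-abscission.
#'
#' @param tab data.frame with columns `genotype`, `individual`, `position`
#'   and either `retained` (0-8) or `petals` + `sepals` (0-4 each).
#' @param genotype genotype label to summarize.
#' @return list with `positionMeans` (named numeric, positions 1-15),
#'   `score` (sum of means over positions 8-15) and `individualScores`
#'   (per-individual position 8-15 sums, the unit of the pairwise tests).
#' @export
retentionSummary <- function(tab, genotype) {
    tab <- normalizeRetention(tab)
    tab <- tab[tab$genotype == genotype, , drop = FALSE]
    if (!nrow(tab))
        bsaStop("invalid_argument", "no rows for genotype '%s'", genotype)
    missing <- setdiff(1:15, unique(tab$position))
    if (length(missing))
        bsaStop("invalid_argument", "genotype '%s' lacks position(s) %s",
                genotype, paste(missing, collapse = ", "))
    posMeans <- tapply(tab$retained, factor(tab$position, levels = 1:15), mean)
    late <- tab[tab$position >= 8, , drop = FALSE]
    indScores <- tapply(late$retained, late$individual, sum)
    list(positionMeans = posMeans,
         score = sum(posMeans[as.character(8:15)]),
         individualScores = as.numeric(indScores))
}

## Welch two-sample t-test with the documented zero-variance conventions
welchPair <- function(x, y) {
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx == 0 && vy == 0) {
        equal <- isTRUE(all.equal(mean(x), mean(y)))
        return(list(t = if (equal) 0 else Inf * sign(mean(x) - mean(y)),
                    df = NA_real_, p = if (equal) 1 else 0))
    }
    ht <- stats::t.test(x, y, var.equal = FALSE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = unname(ht$p.value))
}

#' Pairwise Welch t-tests with Bonferroni correction
#'
#' Compares per-individual abscission scores between every unordered pair
#' of genotypes with a two-sided Welch t-test (unequal variances,
#' Welch-Satterthwaite degrees of freedom). Significance is declared at
#' the Bonferroni-corrected threshold `alpha / nPairs` (with 5 genotypes
#' and `alpha = 0.05`: 10 pairs, threshold 0.005). When both groups have
#' zero variance, p is 1 for equal means and 0 otherwise, by convention.
#'
#' @param scores named list of numeric vectors: per-individual scores per
#'   genotype (each of length >= 2), e.g. the `individualScores` of
#'   [retentionSummary()].
#' @param alpha family-wise significance level (default 0.05).
#' @return list with `pairs` (data.frame: `genotype1`, `genotype2`, `t`,
#'   `df`, `p`, `significant`), `pMatrix` (symmetric matrix of p-values)
#'   and `bonferroniThreshold`.
#' @export
#' @examples
#' s <- list(a = c(1, 2, 3, 4), b = c(3, 4, 5, 6))
#' pairwiseWelch(s)$pairs
pairwiseWelch <- function(scores, alpha = 0.05) {
    if (length(scores) < 2L)
        bsaStop("invalid_argument", "need at least two genotypes")
    if (any(lengths(scores) < 2L))
        bsaStop("invalid_argument", "need >= 2 individuals per genotype")
    g <- names(scores)
    if (is.null(g)) g <- paste0("genotype", seq_along(scores))
    cmb <- utils::combn(length(scores), 2L)
    thr <- alpha / ncol(cmb)
    rows <- lapply(seq_len(ncol(cmb)), function(k) {
        i <- cmb[1L, k]; j <- cmb[2L, k]
        w <- welchPair(scores[[i]], scores[[j]])
        data.frame(genotype1 = g[i], genotype2 = g[j], t = w$t, df = w$df,
                   p = w$p, significant = w$p < thr)
    })
    pairs <- do.call(rbind, rows)
    pm <- matrix(NA_real_, length(g), length(g), dimnames = list(g, g))
    diag(pm) <- 1
    for (k in seq_len(nrow(pairs))) {
        pm[pairs$genotype1[k], pairs$genotype2[k]] <- pairs$p[k]
        pm[pairs$genotype2[k], pairs$genotype1[k]] <- pairs$p[k]
    }
    list(pairs = pairs, pMatrix = pm, bonferroniThreshold = thr)
}

#' Background-correct and normalize a fluorescence measurement
#'
#' Subtracts the mean of exactly three background readings from a region's
#' mean intensity and expresses the result relative to the corrected
#' wild-type signal.
#'
#' @param regionMean mean intensity of the traced region.
#' @param backgroundMeans numeric vector of exactly three background
#'   readings from the same image.
#' @param wtCorrected background-corrected wild-type intensity (> 0).
#' @return list with `corrected` (may be negative; flagged via
#'   `belowBackground`) and `normalized`.
#' @export
#' @examples
#' fluorescenceNormalize(120, c(20, 22, 18), wtCorrected = 50)
fluorescenceNormalize <- function(regionMean, backgroundMeans, wtCorrected) {
    if (length(backgroundMeans) != 3L)
        bsaStop("invalid_argument", "exactly three background readings required")
    if (wtCorrected <= 0)
        bsaStop("invalid_argument", "wtCorrected must be > 0")
    corrected <- regionMean - mean(backgroundMeans)
    list(corrected = corrected,
         normalized = corrected / wtCorrected,
         belowBackground = corrected < 0)
}
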