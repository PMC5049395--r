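test_that("snpProportion is the exact alt-read fraction", {
    expect_equal(snpProportion(c(1, 0, 20), c(9, 25, 0)), c(0.9, 1, 0))
    ## zero depth is excluded (NA), not scored 0
    expect_true(is.na(snpProportion(0, 0)))
    x <- quickBsa("chr1", c(10L, 20L), c("G", "C"), c("A", "T"),
                  c(1L, 0L), c(9L, 0L))
    p <- snpProportion(x)
    expect_equal(unname(p[, 1]), c(0.9, NA))
})

test_that("emsFilter keeps exactly the G>A / C>T spectrum, in order", {
    gr <- GRanges("chr1", IRanges(1:6 * 10L, width = 1),
                  ref = c("G", "C", "G", "T", "A", "C"),
                  alt = c("A", "T", "C", "C", "T", "T"))
    kept <- emsFilter(gr)
    expect_length(kept, 3L)                      # G>A, C>T, C>T
    expect_identical(start(kept), c(10L, 20L, 60L))
    expect_identical(emsFilter(kept), kept)      # idempotent
    ## same through the experiment container
    x <- quickBsa("chr1", 1:6 * 10L, gr$ref, gr$alt, rep(5L, 6), rep(5L, 6))
    expect_identical(nrow(emsFilter(x)), 3L)
})

test_that("thresholdFilter applies a strict > tau cut", {
    x <- quickBsa("chr1", c(10L, 20L, 30L), rep("G", 3), rep("A", 3),
                  refDepth = c(14L, 15L, 0L), altDepth = c(86L, 85L, 100L))
    kept <- thresholdFilter(x, pool = 1L, tau = 0.85)
    pos <- start(SummarizedExperiment::rowRanges(kept))
    expect_setequal(pos, c(10L, 30L))            # 0.86 and 1.0 kept, 0.85 out
    all0 <- thresholdFilter(x, pool = 1L, tau = 0)
    expect_identical(nrow(all0), 3L)             # everything > 0 kept
    expect_error(thresholdFilter(x, 1L, tau = 1.2), class = "invalid_argument")
})

test_that("the candidate funnel is monotone and nested", {
    set.seed(99)
    for (rep in 1:3) {
        n <- 80
        ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
        alt <- vapply(ref, function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        x <- quickBsa("chr1", sample.int(1e5, n), ref, alt,
                      rpois(n, 20), rpois(n, 20))
        e <- emsFilter(x)
        t <- thresholdFilter(e, pool = 1L, tau = 0.5)
        expect_lte(nrow(t), nrow(e))
        expect_lte(nrow(e), nrow(x))
        key <- function(z) paste(seqnames(SummarizedExperiment::rowRanges(z)),
                                 start(SummarizedExperiment::rowRanges(z)))
        expect_true(all(key(t) %in% key(e)))
        expect_true(all(key(e) %in% key(x)))
    }
})

test_that("proportionProfile is position-sorted and empty off-genome", {
    x <- quickBsa("chr1", c(300L, 100L, 200L), rep("G", 3), rep("A", 3),
                  c(5L, 5L, 5L), c(5L, 10L, 15L))
    prof <- proportionProfile(x, pool = 1L, chrom = "chr1")
    expect_identical(prof$pos, c(100L, 200L, 300L))
    expect_false(is.unsorted(prof$pos))
    expect_identical(nrow(proportionProfile(x, 1L, "chrX")), 0L)
    one <- quickBsa("chr1", 50L, "G", "A", 1L, 1L)
    expect_identical(nrow(proportionProfile(one, 1L, "chr1")), 1L)
})

test_that("a high-proportion block is detected as exactly one region", {
    ## 30 consecutive variants at 0.95 embedded in 300 background at ~0.5
    set.seed(7)
    n <- 300
    pos <- sort(sample.int(3e6, n))
    block <- 136:165
    depth <- 100L
    altD <- rbinom(n, depth, 0.5)
    altD[block] <- rbinom(30, depth, 0.95)
    x <- quickBsa("chr1", pos, rep("G", n), rep("A", n), depth - altD, altD)
    reg <- detectLinkedRegion(x, pool = 1L, windowN = 15, tLink = 0.75,
                              minSnps = 10)
    expect_length(reg, 1L)
    expect_lte(start(reg), pos[min(block)])
    expect_gte(end(reg), pos[max(block)])
    ## uniform 0.5 profile: nothing qualifies
    x0 <- quickBsa("chr1", pos, rep("G", n), rep("A", n),
                   depth - rbinom(n, depth, 0.5), rbinom(n, depth, 0.5))
    expect_length(detectLinkedRegion(x0, pool = 1L), 0L)
    ## empty input: empty result with a warning
    expect_warning(r0 <- detectLinkedRegion(x0[0, ], pool = 1L))
    expect_length(r0, 0L)
})

test_that("detectLinkedRegion matches the exhaustive window-scan oracle", {
    set.seed(11)
    for (rep in 1:4) {
        n <- sample(100:500, 1)
        nChrom <- sample(1:3, 1)
        chrom <- sort(sample(paste0("chr", seq_len(nChrom)), n, replace = TRUE))
        pos <- unlist(lapply(split(seq_len(n), chrom), function(i)
            sort(sample.int(2e6, length(i)))))
        depth <- 60L
        p <- runif(n, 0.3, 0.7)
        hot <- sample.int(n - 40, 1); p[hot:(hot + 39)] <- runif(40, 0.85, 1)
        altD <- rbinom(n, depth, p)
        x <- quickBsa(chrom, pos, rep("G", n), rep("A", n), depth - altD, altD)
        got <- detectLinkedRegion(x, pool = 1L)
        want <- oracleLinkedRegions(x, pool = 1L)
        if (is.null(want)) {
            expect_length(got, 0L)
        } else {
            expect_identical(length(got), nrow(want))
            expect_identical(start(got), want$start)
            expect_identical(end(got), want$end)
            expect_identical(got$nVariants, want$nVariants)
            expect_equal(got$meanProportion, want$meanProportion)
        }
    }
})

test_that("the control-pool delta criterion prunes shared-background regions", {
    ## suppressed pool high everywhere on chr1; control equally high:
    ## without a control a region is called, with one the delta kills it
    set.seed(13)
    n <- 60
    pos <- sort(sample.int(1e6, n))
    gr <- GRanges("chr1", IRanges(pos, width = 1), ref = "G", alt = "A")
    altS <- rbinom(n, 80, 0.95); altC <- rbinom(n, 80, 0.93)
    x <- BsaExperiment(gr,
        refDepth = cbind(suppressed = 80L - altS, control = 80L - altC),
        altDepth = cbind(suppressed = altS, control = altC))
    noCtl <- detectLinkedRegion(x, pool = "suppressed")
    withCtl <- detectLinkedRegion(x, pool = "suppressed", control = "control")
    expect_gt(length(noCtl), 0L)
    expect_length(withCtl, 0L)
})

test_that("misclassified pool members depress but do not hide the causal signal", {
    g <- makeGenome(1, 3e5, seed = 31)
    v <- applyEms(g, 10, seed = 32)
    pop <- simulateF2(v, g, 1000, seed = 33)
    ci <- which(v$origin == "causal")
    props <- vapply(1:50, function(k) {
        pool <- buildPool(pop, 30, "suppressed", 2, seed = 1000 + k)
        cnt <- sequencePool(pool, meanDepth = 50, errorRate = 0, seed = 2000 + k)
        cnt$altDepth[ci] / (cnt$refDepth[ci] + cnt$altDepth[ci])
    }, numeric(1))
    expect_gte(mean(props), 0.9)
    ## and a perfectly scored pool is exactly 1
    pool0 <- buildPool(pop, 30, "suppressed", 0, seed = 3)
    cnt0 <- sequencePool(pool0, meanDepth = 50, errorRate = 0, seed = 4)
    expect_identical(cnt0$altDepth[ci] / (cnt0$refDepth[ci] + cnt0$altDepth[ci]), 1)
})

test_that("runMapping reports a coherent funnel and the causal variant in-region", {
    sim <- simulateExperiment(list(nChrom = 2L, chromLengths = c(1e6, 1e6),
                                   nMutations = 80L, nIndividuals = 200L),
                              seed = 77)
    res <- runMapping(sim$experiment, pool = "suppressed",
                      control = "non_suppressed")
    expect_true(all(diff(res$counts[c("total", "ems", "threshold")]) <= 0))
    expect_gt(length(res$regions), 0L)
    cv <- causalVariant(sim$experiment)
    top <- res$regions[1]
    expect_identical(as.character(seqnames(cv)), as.character(seqnames(top)))
    expect_true(start(cv) >= start(top) && start(cv) <= end(top))
    ## determinism of the analysis stage
    res2 <- runMapping(sim$experiment, pool = "suppressed",
                       control = "non_suppressed")
    expect_identical(res$counts, res2$counts)
    expect_identical(start(res$regions), start(res2$regions))
})
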