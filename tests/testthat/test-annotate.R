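test_that("classifyLocation follows the stated precedence", {
    h <- handGene("+")
    models <- list(handgene = h$model)
    at <- function(pos) GRanges("chrT", IRanges(pos, width = 1),
                                ref = "G", alt = "A")
    ## intron runs 131..220; its first two and last two bases are junction
    expect_identical(classifyLocation(at(132), models)$locationClass,
                     "splice_junction")
    expect_identical(classifyLocation(at(131), models)$locationClass,
                     "splice_junction")
    expect_identical(classifyLocation(at(220), models)$locationClass,
                     "splice_junction")
    expect_identical(classifyLocation(at(175), models)$locationClass, "intron")
    expect_identical(classifyLocation(at(110), models)$locationClass, "cds")
    expect_identical(classifyLocation(at(500), models)$locationClass,
                     "intergenic")
    expect_true(is.na(classifyLocation(at(500), models)$geneId))
})

test_that("codingEffect reproduces textbook codon changes", {
    h <- handGene("+")
    ## CDS codon 2 is CCA (Pro) at genomic 104-106; C>T at its 2nd base
    ## gives CTA (Leu): the P>L substitution class
    v <- GRanges("chrT", IRanges(105, width = 1), ref = "C", alt = "T")
    eff <- codingEffect(v, h$model, h$genome)
    expect_identical(eff$effect, "nonsynonymous")
    expect_identical(eff$aaChange, "P2L")
    ## codon 3 CTG (Leu), G>A at 3rd base -> CTA, still Leu: synonymous
    v2 <- GRanges("chrT", IRanges(109, width = 1), ref = "G", alt = "A")
    expect_identical(codingEffect(v2, h$model, h$genome)$effect, "synonymous")
    ## codon 4 CGA (Arg), C>T -> TGA: stop gained
    v3 <- GRanges("chrT", IRanges(110, width = 1), ref = "C", alt = "T")
    eff3 <- codingEffect(v3, h$model, h$genome)
    expect_identical(eff3$effect, "stop_gained")
    expect_identical(eff3$aaChange, "R4*")
    ## outside the CDS: contract violation
    vX <- GRanges("chrT", IRanges(175, width = 1), ref = "C", alt = "T")
    expect_error(codingEffect(vX, h$model, h$genome),
                 class = "contract_violation")
})

test_that("coding effects are strand-symmetric", {
    hp <- handGene("+")
    hm <- handGene("-")
    ## transcript CDS position 5 (codon 2, base 2): on the minus-strand
    ## construction the same transcript base sits at genomic coordinate
    ## end - 4 of the right-hand genomic exon, on the opposite strand
    vP <- GRanges("chrT", IRanges(105, width = 1), ref = "C", alt = "T")
    effP <- codingEffect(vP, hp$model, hp$genome)
    gEnd <- max(end(exons(hm$model)))
    vM <- GRanges("chrT", IRanges(gEnd - 4, width = 1), ref = "G", alt = "A")
    effM <- codingEffect(vM, hm$model, hm$genome)
    expect_identical(effP, effM)
})

test_that("codingEffect agrees with a full-translation oracle at every CDS G/C site", {
    for (strand in c("+", "-")) {
        h <- handGene(strand)
        chromStr <- as.character(genomeSeq(h$genome)[[1]])
        cd <- cds(h$model)
        cdsPositions <- unlist(lapply(seq_along(cd), function(i)
            seq(IRanges::start(cd)[i], IRanges::end(cd)[i])))
        refCds <- paste0(h$cds1, h$cds2)
        for (pos in cdsPositions) {
            base <- substr(chromStr, pos, pos)
            if (!base %in% c("G", "C")) next
            alt <- if (base == "G") "A" else "T"
            v <- GRanges("chrT", IRanges(pos, width = 1), ref = base, alt = alt)
            got <- codingEffect(v, h$model, h$genome)
            ## oracle: edit the chromosome string, rebuild and translate the
            ## whole protein, compare to the reference protein
            edited <- chromStr
            substr(edited, pos, pos) <- alt
            pull <- function(s) paste(vapply(seq_along(cd), function(i)
                substr(s, IRanges::start(cd)[i], IRanges::end(cd)[i]),
                character(1)), collapse = "")
            cdsStr <- pull(edited)
            if (strand == "-")
                cdsStr <- as.character(reverseComplement(DNAString(cdsStr)))
            protRef <- as.character(translate(DNAString(refCds)))
            protAlt <- as.character(translate(DNAString(cdsStr)))
            diff <- which(strsplit(protRef, "")[[1]] != strsplit(protAlt, "")[[1]])
            wantEffect <- if (!length(diff)) "synonymous"
                else if (substr(protAlt, diff, diff) == "*") "stop_gained"
                else "nonsynonymous"
            expect_identical(got$effect, wantEffect)
            if (length(diff))
                expect_identical(got$aaChange,
                                 paste0(substr(protRef, diff, diff), diff,
                                        substr(protAlt, diff, diff)))
        }
    }
})

test_that("candidateFunnel keeps non-synonymous CDS and splice-junction variants only", {
    h <- handGene("+")
    models <- list(handgene = h$model)
    ## 10 variants: 3 nonsyn (CDS), 1 splice junction, 2 synonymous,
    ## 4 intergenic/intronic
    pos <- c(105L, 113L, 116L,      # CCA>CTA (P2L), CAT codon5, CAT codon6
             131L,                  # intron first base (GT donor)
             109L, 241L,            # synonymous third-base changes
             400L, 450L, 500L, 175L)  # intergenic x3, deep intron
    ref <- vapply(pos, function(p) substr(as.character(
        genomeSeq(h$genome)[[1]]), p, p), character(1))
    alt <- ifelse(ref == "G", "A", ifelse(ref == "C", "T", "C"))
    ok <- ref %in% c("G", "C")
    ## keep EMS-consistent fixture: force non-G/C sites to a transition pair
    ref[!ok] <- "G"; alt[!ok] <- "A"
    x <- quickBsa("chrT", pos, ref, alt, rep(2L, 10), 98L - seq_len(10))
    cand <- candidateFunnel(x, models, h$genome, pool = 1L)
    expect_identical(nrow(cand), 4L)
    expect_setequal(cand$locationClass, c("cds", "splice_junction"))
    expect_false(any(cand$effect == "synonymous"))
    expect_true(all(cand$pos %in% c(105L, 113L, 116L, 131L)))
    ## sorted by proportion, descending
    expect_false(is.unsorted(rev(cand$proportion)))
    ## idempotence: the funnel re-applied to its own survivors is identity
    keep <- SummarizedExperiment::rowRanges(x)
    keyAll <- paste(start(keep))
    x2 <- x[keyAll %in% as.character(cand$pos), ]
    cand2 <- candidateFunnel(x2, models, h$genome, pool = 1L)
    expect_identical(cand2[order(cand2$pos), ], cand[order(cand$pos), ])
})

test_that("intron retention of a stop-free in-frame intron extends the protein", {
    for (strand in c("+", "-")) {
        h <- handGene(strand)
        res <- spliceConsequence(h$model, h$genome, "intron_retention",
                                 intronIndex = 1L)
        expect_true(res$framePreserved)          # 90 %% 3 == 0
        expect_false(res$prematureStop)
        ## oracle: translate the concatenated edited transcript directly
        prot <- translateToStop(paste0(h$cds1, h$intron, h$cds2))
        expect_identical(res$proteinLength, nchar(prot))
    }
})

test_that("a cryptic splice removing 22 exonic bases shifts the frame to a premature stop", {
    for (strand in c("+", "-")) {
        h <- handGene(strand)
        res <- spliceConsequence(h$model, h$genome, "cryptic_splice",
                                 intronIndex = 1L,
                                 extraExonicBasesRemoved = 22L)
        expect_false(res$framePreserved)         # 22 %% 3 == 1
        expect_true(res$prematureStop)
        prot <- translateToStop(paste0(h$cds1, substr(h$cds2, 23, nchar(h$cds2))))
        expect_identical(res$proteinLength, nchar(prot))
        expect_lt(res$proteinLength, nchar(paste0(h$cds1, h$cds2)) / 3 - 1)
    }
})

test_that("a cryptic splice removing zero extra bases is the identity transcript", {
    h <- handGene("+")
    res <- spliceConsequence(h$model, h$genome, "cryptic_splice",
                             intronIndex = 1L, extraExonicBasesRemoved = 0L)
    expect_true(res$framePreserved)
    expect_false(res$prematureStop)
    refProt <- translateToStop(paste0(h$cds1, h$cds2))
    expect_identical(res$proteinLength, nchar(refProt))
    ## invalid edits are rejected
    expect_error(spliceConsequence(h$model, h$genome, "intron_retention", 5L),
                 class = "unsupported_edit")
})

test_that("generated toy gene models are valid, translatable and deterministic", {
    g <- makeGenome(1, 60000, seed = 41)
    toy <- makeToyGeneModels(g, 4, seed = 42)
    expect_length(toy$models, 4L)
    for (m in toy$models) {
        expect_true(validObject(m))
        cdsStr <- as.character(bsaMapper:::cdsSequence(m, toy$genome))
        expect_identical(substr(cdsStr, 1, 3), "ATG")
        prot <- as.character(translate(DNAString(cdsStr)))
        ## stop only at the end
        expect_identical(as.integer(regexpr("*", prot, fixed = TRUE)),
                         nchar(prot))
    }
    toy2 <- makeToyGeneModels(g, 4, seed = 42)
    expect_identical(lapply(toy$models, exons), lapply(toy2$models, exons))
    expect_error(makeToyGeneModels(makeGenome(1, 1000, seed = 1), 50, seed = 2),
                 class = "infeasible_request")
})
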