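---
title: "Mapping EMS-induced suppressor mutations by pooled sequencing"
author: "bsaMapper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping EMS-induced suppressor mutations by pooled sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(0)
```

# The experiment this package models

A suppressor screen starts from a mutant with a scorable defect — here an
*Arabidopsis* line whose flowers fail to shed petals and sepals
(abscission-deficient) — mutagenizes it with ethyl methanesulfonate (EMS),
and looks for second-site mutations that restore the wild-type-like
phenotype. EMS alkylates guanine, so nearly all induced lesions are
G:C→A:T transitions; read against the reference strand a variant call is
either G>A or C>T.

To map a recessive suppressor, the suppressed line is backcrossed to its
(non-mutagenized, still abscission-deficient) parent. The F1 is
heterozygous at every induced site; the F2 segregates roughly
1 suppressed : 3 non-suppressed if a single recessive mutation is causal.
Tissue from ~30 suppressed F2 individuals is pooled and sequenced, along
with a non-suppressed control pool. At every variant site the **SNP
proportion** is

$$ p = \frac{\text{reads carrying the alternative base}}
           {\text{total reads at the position}} . $$

Selection on the phenotype forces every suppressed individual to be
homozygous for the causal allele, so $p \to 1$ at the causal site, decays
with genetic distance along the causal chromosome, and stays near 0.5 at
unlinked heterozygous sites. Plotting $p$ by position exposes a *linked
region*; variants above a proportion threshold inside that region are then
classified against gene models, keeping non-synonymous/stop-gained CDS
changes and exon–intron junction hits as gene candidates.

`bsaMapper` implements this pipeline end to end, together with a
generative simulator whose truth files make every stage testable, and the
phenotype statistics used to quantify abscission (per-flower organ
retention, Welch *t*-tests, Bonferroni correction).

# The generative model

`simulateExperiment()` composes five stages, each seeded deterministically
from one master seed (`deriveSeed()`), so a whole experiment is
reproducible bit for bit.

**Genome.** `makeGenome()` draws i.i.d. bases at a target G+C fraction
(default 0.36, Arabidopsis-like). The default genome is 5 chromosomes of
3 Mb. This is a deliberately scaled-down stand-in for a ~120 Mb plant
genome: large enough that unlinked chromosomes provide a genuine null
background, small enough that a full simulation runs in seconds. A
genetic-map density of 4 cM/Mb (an Arabidopsis genome-wide average) is
attached to the genome and used by meiosis.

**Mutagenesis.** `applyEms()` samples mutation positions uniformly among
G/C sites and applies the transition (G>A or C>T). Exactly one induced
mutation, chosen uniformly, is labelled causal: multi-locus suppression is
out of scope. The default load of 200 induced mutations gives ~40
variants per chromosome — enough for 15-variant windows on every
chromosome.

**Meiosis and the F2.** Each F2 individual is the sum of two independent
F1 gametes. Per chromosome, the crossover count is Poisson with mean
equal to the chromosome's length in Morgans and crossover positions are
uniform — Haldane's no-interference model, under which the recombination
fraction at map distance $d$ Morgans is $r = \tfrac12(1-e^{-2d})$. The
expected pooled alternative-allele frequency among suppressed F2 at a
locus at recombination fraction $r$ from the causal locus is $1-r$; the
test suite verifies this decay at 0, 5, 20 and 50 cM against the closed
form. Phenotype follows the recessive rule exactly: suppressed iff
homozygous for the causal allele.

**Pooling and misscoring.** `buildPool()` bulks 30 individuals of the
requested phenotype class. Real pools are imperfect — suppressed and
partially-defective parents can be hard to tell apart — so
`nMisclassified` members (default 2) are drawn from the *actual* opposite
F2 class. For a suppressed pool this matters: misscored individuals are
heterozygous or wild type at the causal locus in the Mendelian ~2:1
proportion, which pins the expected causal-site SNP proportion at
$\frac{2 \cdot 28 + \tfrac{2}{3} \cdot 2 \cdot 2}{2 \cdot 30} \approx 0.96$
rather than 1 — the same order as the ~0.9 plateau seen in real suppressed
pools. With zero misscoring and zero sequencing error the proportion is
exactly 1 at any positive depth, and the tests assert this identity.

**Sequencing.** `sequencePool()` draws total depth per site as
Poisson(`meanDepth`) and alternative reads as binomial with success
probability $p(1-e) + (1-p)e$, a symmetric per-read miscall model with
default error rate $e = 0.005$. The mean depth default of 50 is a typical
pooled-resequencing depth; it is exposed in the configuration because no
single value is canonical. Read-level simulation (FASTQ, mapping,
base-quality) is deliberately out of scope — the pipeline ingests allele
depths, so that is where the simulator stops.

# The analysis funnel and its parameters

| parameter | default | units | role |
|---|---|---|---|
| `tau` | 0.85 | proportion | threshold filter keeps $p > \tau$ (strict) |
| `windowN` | 15 | variants | sliding-window width for region detection |
| `tLink` | 0.75 | proportion | minimum window mean in the suppressed pool |
| `deltaMin` | 0.2 | proportion | minimum window mean difference vs control |
| `minSnps` | 10 | variants | minimum variants per reported region |
| `minDepth` | 1 | reads | below this, the proportion is undefined |

`snpProportion()` is the exact ratio; zero-depth sites are excluded and
counted, never scored 0, because a 0 would be indistinguishable from a
confidently reference-homozygous site. `emsFilter()` accepts both G>A and
C>T so that G:C→A:T events on either strand are covered without strand
inference. `thresholdFilter()` uses a strict inequality at $\tau = 0.85$.

Region detection is the one stage practitioners usually leave informal —
mapping figures tend to bracket the linked region by eye — so the rule
here is the package's own: windows of `windowN` consecutive variants
qualify when their mean proportion exceeds `tLink` and, when a control
pool is present, when the suppressed-minus-control mean over the window's
shared variants exceeds `deltaMin`; overlapping qualifying windows merge;
regions below `minSnps` variants are dropped; ranking is by mean
proportion, ties broken toward more variants, then leftmost. All four
constants are configuration-exposed. The implementation is checked
against an exhaustive window-scan oracle on tables of up to 500 variants,
and across 20 simulated default experiments the causal variant falls in
the top-ranked region in ≥95% of runs.

Two orderings were genuinely open and are fixed as follows: the
proportion threshold is applied genome-wide and then intersected with the
detected regions (equivalent to thresholding within the region whenever
the region is real, and more conservative when it is not); and the
control-pool comparison uses only variants observed in both pools, while
unmatched variants still contribute to window means.

# Candidate annotation

`classifyLocation()` ranks splice junction > CDS > UTR/non-coding exon >
intron > intergenic, reporting the best gene when models overlap. An
"exon–intron junction" is fixed as the two canonical intronic bases at
either intron end (the GT donor / AG acceptor dinucleotides); no wider
splice-region definition is attempted because none is defensible without
splice-strength scoring, which is out of scope. `codingEffect()` rebuilds
the affected codon from CDS coordinates — strand-aware, complementing the
variant base on minus-strand genes — and translates with the standard
code; start-codon loss counts as non-synonymous. `candidateFunnel()` then
keeps exactly the non-synonymous/stop-gained CDS variants and
splice-junction variants, sorted by proportion. Every CDS classification
is validated in the tests against a brute-force oracle that rebuilds and
translates the entire protein.

`spliceConsequence()` models the two transcript outcomes seen when a
canonical splice site is lost: retention of the affected intron, or a
cryptic splice that removes the intron plus a stated number of bases from
the transcript-5' end of the following exon (the observed case removes
22 bases, shifting the frame, since 22 mod 3 = 1). The edited CDS is
rebuilt in genomic coordinates, the frame checked, and translation
locates the first stop; a stop upstream of where the reference stop now
sits is flagged premature. Cryptic-site *discovery* from sequence is not
attempted — the site is an input, as it was experimentally determined.

`makeToyGeneModels()` writes small multi-exon genes (ATG start, stop end,
GT..AG introns, no internal stops, CDS = exons so UTRs never arise) into
the genome so that models and sequence agree; `fullRun()` places the
causal mutation at a splice-junction G/C of one of these genes by
default, mirroring the biology of the screen and making the end-to-end
candidate recovery testable against the truth file.

# Phenotype statistics

Abscission is scored per flower as retained petals + sepals (0–8, since a
flower has four of each), at inflorescence positions 1–15. Abscission is
complete by position 8, so `retentionSummary()` sums the per-position
means over positions 8–15 into a genotype score in [0, 64].
`pairwiseWelch()` compares *per-individual* position-8–15 sums — the
individual, not the position, is the replication unit, which is also what
standard-deviation error bars on summed scores imply — using two-sided
Welch *t*-tests (unequal variances, Welch–Satterthwaite df) at a
Bonferroni threshold of $\alpha$ divided by the number of unordered
genotype pairs: with five genotypes and $\alpha = 0.05$, ten pairs and a
0.005 threshold. Degenerate inputs follow documented conventions: both
groups constant with equal means gives $p = 1$, with unequal means
$p = 0$. Calibration is tested: the empirical type-I rate at
$\alpha = 0.05$ over 1000 null replicates is within Monte-Carlo error,
and the Bonferroni family-wise error under a five-group global null stays
at or below $\alpha$.

`fluorescenceNormalize()` implements the reporter-signal arithmetic:
region mean minus the mean of exactly three background readings, then
division by the corrected wild-type value. Where the upstream imaging
protocol is ambiguous between counting thresholded pixels and averaging
pixel intensities, the mean-intensity reading is implemented; the
function consumes region summaries as numbers and no image processing is
attempted.

# Numerical and design notes

* All randomness flows from one master seed; each stage derives its own
  seed from a label, so stages can be re-run in isolation and runs are
  byte-identical under the same seed and configuration.
* Coordinates are 1-based and closed everywhere (VCF/GFF3 convention);
  no half-open conversions are exposed.
* The VCF layer standardizes on `AD` = (ref, alt) per pool, documented in
  the written header; files carrying depths only in `DP4`-style INFO
  fields need a pre-conversion. Only SNVs are analysed; indel and other
  non-SNV rows are skipped and counted, never silently dropped, and a
  missing `AD` is a hard format error naming the site.
* Region ranking ties break toward more variants, then the leftmost
  start, so reports are total-ordered and deterministic.
* `simulatePhenotypeTable()` rounds and clamps Gaussian noise to the 0–8
  integer scale; at means near the boundaries this induces mild bias,
  which is why calibration checks use central means.

# What the simulations do and do not show

The simulator reproduces the statistical structure the analysis relies
on: Mendelian segregation, Haldane linkage decay, selection-driven allele
-frequency enrichment, pool misscoring, and depth/error sampling noise.
It does not emulate alignment artefacts, mapping bias near structural
variation, uneven coverage, GC bias, duplicated regions, or
multi-mutation complementation groups — so a green test suite shows the
*method* behaves as specified under its stated model, not that any
particular real data set will be as clean. Problem sizes used throughout
the tests (5 × 3 Mb genome, 200 mutations, F2 of 200–10 000, pools of 30
at 50× depth, 20-replicate recovery studies) were chosen as the smallest
scales at which each property is statistically identifiable; all are
configuration parameters, not constants.

# A worked run

```{r, eval = FALSE}
library(bsaMapper)
res <- fullRun(list(writePlots = FALSE), seed = 1, outdir = "run1")
res$counts
#>      total        ems  threshold   inRegion candidates
#>        201        201         41         41          1
res$candidates[, c("chrom", "pos", "ref", "alt", "proportion",
                   "geneId", "locationClass")]
#>   chrom     pos ref alt proportion geneId   locationClass
#> 1  chr4 1902103   G   A   0.974359 toy007 splice_junction
readTruth(file.path("run1", "truth.yaml"))$causal
#> $chrom [1] "chr4"; $pos [1] 1902103; $ref [1] "G"; $alt [1] "A"
```

The funnel narrows 201 induced variants to a single candidate — the
splice-junction lesion the truth file confirms as causal.
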