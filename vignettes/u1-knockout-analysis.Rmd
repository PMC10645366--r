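---
title: "Methods: differential expression and APA analysis of U1 snRNA gene knockouts"
author: "u1apa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression and APA analysis of U1 snRNA gene knockouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(u1apa)
```

## The biological setting

U1 snRNA is the spliceosomal RNA that base-pairs with 5' splice sites to
initiate splicing, and — through telescripting — suppresses premature
cleavage and polyadenylation of nascent transcripts. *Drosophila
melanogaster* carries five U1 genes: `21D` on chromosome arm 2L and
`82Eb`, `95Ca`, `95Cb`, `95Cc` on 3R. Three of them (21D, 95Ca, 95Cb)
encode the canonical U1 sequence; `95Cc` carries a U-to-C variation at
position 123 and `82Eb` a G-to-U variation at position 134, both in or
near the Sm-ring binding site of the 164-nt snRNA. `u1Registry()`
exposes this registry.

Deleting a single U1 gene perturbs the transcriptome of third-instar
larvae in two characteristic ways that this package quantifies from
bulk RNA-seq:

1. **Differential expression** biased toward *down*-regulation of
   genes with few (1–2) introns and short spans;
2. **3'-UTR shortening/lengthening** — alternative polyadenylation
   (APA) shifts between a proximal and a distal polyA site, with the
   distal-activated events carrying U1-binding (5'-splice-site-like)
   motifs near their *proximal* site only.

The package also quantifies trans-spliced isoform usage (the
*mod(mdg4)*/*lola* situation) from isoform-specific junction reads, and
implements the qPCR ΔCt/ΔΔCt validation arithmetic.

## Data model and coordinate conventions

All coordinates inside package objects are **0-based half-open**.
The readers and writers convert at the boundary: GTF is 1-based
inclusive, BED/bedGraph are 0-based half-open. Minus-strand coverage is
stored in genomic orientation; `estimatePdui()` reverses it into
transcript orientation internally. Central containers are S4:
`GeneModels` (spans, exons with introns derived as inter-exon gaps,
3'-UTR, proximal/distal polyA sites, GC fraction), `U1CountSet`
(a `SummarizedExperiment` of counts with strain/replicate colData) and
`CoverageTrack` (per-base 3'-UTR depth for one gene and sample).

GC content is computed over the full gene span (TSS→TES); computing it
over exons or mRNA would be equally defensible, but the span is the
choice made here and it is what the simulator's truth tables assume.
Genes lacking an annotated 3'-UTR but carrying polyA sites get the
transcript-final exon as inferred 3'-UTR; without polyA sites they are
simply excluded from APA analysis.

## Differential expression

Counts are normalized with median-of-ratios size factors (genes with a
zero anywhere are excluded from the reference set). The per-gene test
is a deliberately simple two-group negative-binomial Wald test:

* per-gene dispersion by method of moments,
  $\hat\alpha_g = \max\{0, (s^2_g - \bar m_g)/\bar m_g^2\}$, from the
  pooled within-group variance, with a Poisson fallback at 0;
* these noisy per-gene values are **pooled across genes as the
  median** — with two or three replicates a per-gene dispersion
  estimate is far too unstable to test against, and pooling makes the
  Wald denominator nearly non-random, so the statistic is referred to
  the standard normal;
* log2 fold-changes are ratios of normalized group means with a 0.5
  pseudocount, so zero-count genes stay finite;
* genes below a normalized base mean of 1 are not tested (this floor
  also defines the "transcribed" background for enrichment);
  Benjamini–Hochberg runs across tested genes only.

The published screen is then `screenDEGs()`: fold-change > 2 **and**
FDR < 0.05, split into down and up sets. This stand-in makes no claim
of producing DESeq2-identical p-values; the property surface the suite
verifies is calibration (null p-values near-uniform, KS < 0.1 on 2000
simulated null genes; ≤1% of null genes pass the screen) and power
(planted two-fold effects at base mean ≥ 100 recovered in ≥90% of
genes with three replicates).

`overlapSets()` partitions the five strains' DEG sets into common,
shared-by-k and strain-unique classes by exact membership.

## Feature enrichment

`stratifyGenes()` bins genes by intron count (0 / 1–2 / ≥3), span
length (< 2 kb / ≥ 2 kb), mean intron length (< 0.5 kb / ≥ 0.5 kb /
no-intron) and GC quartile. "Short introns" is read as a gene-level
property via the *mean* intron length; per-intron alternatives (any or
all introns short) would be reasonable too, and the binning is isolated
in one function if a user needs them. For each bin `enrichmentTest()`
builds the 2×2 table against the transcribed background, applies the
two-sided Fisher exact test and BH across the feature's bins. The odds
ratio is the cross-product with Haldane correction when a cell is
empty, and set to 1 by convention when an entire margin is empty (the
no-contrast case). The Fisher p is verified in the suite against an
exact hypergeometric tail-sum enumeration at 1e-12.

## APA: the PDUI change-point estimator

The Percentage of Distal polyA-site Usage Index (PDUI) is the fraction
of transcripts using the distal (long-3'-UTR) site. Per sample and
gene, `estimatePdui()` fits the transcript-oriented 3'-UTR depth vector
with a one-breakpoint piecewise-constant model, scanning **all**
interior breakpoints for the minimum residual sum of squares (O(n) via
cumulative sums; ties break toward the most proximal position, the
conservative choice for shortening calls). PDUI is
`mean_after / mean_before` clamped to [0,1]; if the best fit is not a
drop, the track is flagged degenerate-flat with PDUI 1. Eligibility
floors: mean depth ≥ 5 and UTR ≥ 100 nt, skipped otherwise with a
warning. The estimator is invariant to uniform depth scaling. This is a
transparent change-point surrogate for regression-based 3'-UTR usage
tools; no estimator-level equivalence to them is claimed — only the
screen semantics below.

`callApaEvents()` takes ΔPDUI = knockout − wild-type from replicate
means, so ΔPDUI < −0.25 means a proximal shift (3'-UTR shortening, the
telescripting-loss direction) and ΔPDUI > +0.25 a distal shift.
Significance across replicates is a two-sided Welch t-test with BH
across genes (the replicate-level test is a documented stand-in; the
screen thresholds |ΔPDUI| > 0.25, FDR < 0.05 are the published
constants). Events are classified `three_prime_utr` when both polyA
sites sit in the annotated 3'-UTR, else `terminal_exon_intron`.

## U1-binding sites around polyA sites

A "U1-binding site" is a 5'-splice-site-like motif. The default scanner
slides the 9-mer consensus `CAG|GTAAGT` (3 exonic positions, 6 intronic
with the invariant GT dinucleotide) and accepts ≤1 mismatch outside the
GT; consensus, mismatch budget, or a PWM with threshold are
configurable. `windowSiteCounts()` counts hits whose sense-strand start
falls within ±200 nt of the proximal and the distal site (windows
truncated at chromosome ends; a hit inside both windows — sites closer
than 400 nt — is counted in both, by design, since membership is
per-site). `compareSiteRatios()` then contrasts the proximal-activated
and distal-activated event groups: aggregate proximal/distal hit-count
ratio plus a Wilcoxon signed-rank test on per-event differences; groups
under 5 events are flagged low-n with no p-value.

## Trans-splicing and qPCR arithmetic

Isoform usage is `J_i / common_reads`: since both counts come from the
same library, per-million sequencing-depth normalization cancels in the
ratio, so the CPM of `J_i` is reported alongside for cross-sample
context rather than entering the statistic. `compareUsage()` reports
knockout/wild-type usage ratios with Welch t-tests, BH within a gene.

`deltaCt()` computes Ct_target − Ct_reference per sample (records at
≥40 cycles rejected); `relativeExpression()` normalizes to the
wild-type mean ΔCt and reports fold = 2^(−ΔΔCt) — the plotted
convention is a WT-normalized ΔCt, and 2^(−ΔΔCt) is the standard
transform behind it — plus Welch t-tests per strain.
`distalCommonRatio()` implements the APA validation quantity
(distal/common) / (WT distal/WT common).

## The synthetic-data generator

Every downstream stage is exercised against `simulateAll()`, which
emulates the study design: WT plus five deletion strains, three
replicates each, gene-level NB counts, two-site 3'-UTR coverage and
junction tables, with a complete ground-truth record. Four independent
RNG streams (genome, expression, coverage, junctions) derive from one
master seed, so outputs are individually reproducible and the whole
bundle is byte-deterministic.

Default study conditions, chosen once as a realistic desk-scale analog
of the larval experiment:

* 300 genes (canonical fixture seed 20231102), intron-count bins
  0/1–2/≥3 at 0.20/0.45/0.35, GC 0.43, NB dispersion 0.05, mean library
  size 2e6 with ±30% per-sample spread;
* per-strain affected fractions 0.02–0.12 (largest for `del82Eb`,
  mirroring its strongest phenotype), 80% of effects down-regulated,
  |log2FC| ~ U(1,3), and a 2× sampling multiplier for the 1–2-intron
  stratum among down-regulated genes;
* 40% of genes carry two polyA sites in a 1-kb 3'-UTR (proximal site
  at 35–45% of the UTR — this keeps the two ±200-nt windows disjoint),
  coverage 30×, PDUI shift 0.5 on knockout, APA classes null/proximal/
  distal at 0.40/0.35/0.25;
* motif planting encodes the telescripting logic: distal-shift genes
  get one consensus motif in the proximal window only, proximal-shift
  genes one in each window, stable genes none;
* two trans-spliced loci (4 and 3 isoforms), common-exon depth 1000,
  and a 1.5× usage increase of the first isoform in three strains.

What the simulator does **not** emulate: real 3'-UTR coverage biases
(fragmentation, mappability, 3' bias), dispersion trends over the mean,
correlated effects between strains, more than two polyA sites per gene,
intronic/CDS premature cleavage sites, and genuinely noisy annotations.
Passing the recovery properties therefore demonstrates correctness of
the estimators and screens under the stated generative model, not
performance on real libraries.

## Problem sizes and numerical choices

Test and acceptance runs use desk-scale sizes chosen to make sampling
error small relative to the margins being checked: 250 genes (~100 APA
genes, ~2000 gene×sample PDUI pairs) for PDUI recovery and direction
calls, 2000 genes for null calibration and power of the DEG screen, and
1000 genes with the affected fraction raised to 0.15 for the enrichment
check, where the down-DEG sets of all five strains are pooled so the
2× multiplier is measured on a few hundred genes rather than a few
dozen. Ties in the change-point fit break proximally; Fisher tests use
the exact two-sided tail definition; BH families are: tested genes
(DE), genes (APA), bins within a feature (enrichment), isoforms within
a gene (trans-splicing).

## Worked example

```{r example, eval = FALSE}
cfg <- simConfig(seed = 20231102, nGenes = 120)
sim <- simulateAll(cfg)

res <- testDE(sim$counts, "del82Eb")
screenDEGs(res)

est <- estimatePduiSet(sim$tracks)
ev <- callApaEvents(est, "del82Eb")
table(ev$direction)

report <- runPipeline(pipelineConfig(sim = cfg), outDir = "run1")
report$recovery
```

## Known limitations

The DE and APA replicate-level tests are simple stand-ins (pooled-MoM
NB Wald; Welch t on PDUIs) and should not be expected to match DESeq2
or regression-based APA tools numerically. The motif definition of a
U1-binding site is a configurable 5'SS consensus, not an experimentally
derived binding model. Genome-scale event counts from real libraries
depend on library depth, annotation quality and filtering in ways the
synthetic design deliberately holds fixed.
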