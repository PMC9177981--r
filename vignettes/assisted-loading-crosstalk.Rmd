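---
title: "Hormone crosstalk and assisted loading: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hormone crosstalk and assisted loading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`synergyseq` analyzes factorial two-hormone experiments — untreated,
glucagon, corticosterone, and a dual treatment — across three data layers:
gene expression counts, transcription-factor binding (GR, CREB), and
enhancer state (H3K27ac, DNase accessibility). This vignette is the
package's own account of the underlying models, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the design decisions taken where more than one reasonable
choice existed.

## The negative-binomial differential test

Counts for feature $i$ in sample $j$ are modeled as
$K_{ij} \sim \mathrm{NB}(\mu_{ij}, \alpha_i)$ with
$\mu_{ij} = s_j q_{ij}$ and variance $\mu + \alpha\mu^2$. For a two-group
contrast the group means are fit by Newton iteration on the log scale
(the two group coefficients decouple given fixed dispersion), and the Wald
statistic for the log2 fold change uses the Fisher information
$\sum_j \mu_{ij}/(1+\alpha_i \mu_{ij})$ per group.

**Dispersion.** Gene-wise method-of-moments estimates
$\hat\alpha_i = (\widehat{\mathrm{Var}} - \hat\mu)/\hat\mu^2$ (pooled
within groups) are noisy at 2–3 replicates, so they are shrunk in log space
toward a parametric trend $\alpha(\mu) = a_0 + a_1/\mu$ fitted across
features, with trend weight 0.9. This strong moderation reflects the small
per-gene degrees of freedom; with it, the gene-wise contribution mostly
guards against individual highly variable features.

**Reference distribution.** Because the shrunk dispersion carries
genome-wide information, the Wald statistic is referred to a t distribution
with moderated degrees of freedom $4(m-2)$, where $m$ is the number of
samples in the contrast — the residual df plus prior df contributed by the
trend. This choice was calibrated once against the generator's own null
model (constant dispersion 0.05, 3 vs 3 replicates), where it gives a raw
$p \le 0.05$ fraction of about 4.5%; a plain normal reference is markedly
anti-conservative (about 8%) at these replicate numbers, and the unmoderated
$t_{m-2}$ overcorrects (about 2%).

**Normalization.** Median-of-ratios size factors are the default. With the
strongly asymmetric differential fractions that arise at desk scale (a
quarter of simulated genes induced in the dual arm), the plain median ratio
is pulled off the non-differential mode and fold changes shrink toward
zero; the test therefore re-estimates size factors on features with first
pass $p > 0.2$ and refits. This mirrors what `DESeq2::estimateSizeFactors`
achieves with `controlGenes` and what TMM trimming achieves in edgeR. For
TF-ChIP site counts the windows cover only a tiny, signal-rich part of the
genome, so per-sample *total track tags* are the normalization of choice
(`differential_binding(..., norm = "total_tags")`), matching standard
TF-ChIP practice.

**Calls.** `call_differential` gates on linear fold change $\ge$ 1.5 and
Benjamini–Hochberg adjusted $p \le 0.05$, both boundaries inclusive. The
fold-change gate applies to the point estimate; no shrunken or tested bound
is used.

## Crosstalk classes

*Synergy* requires induction in dual vs all three comparators (each at the
full FC + FDR gate) plus a strict sum criterion on replicate-mean RPKM. Two
wordings of the sum criterion exist and they differ:

- `delta` (default): $(\mathrm{dual}-\mathrm{nt}) >
  (\mathrm{gluc}-\mathrm{nt}) + (\mathrm{cort}-\mathrm{nt})$,
- `raw`: $\mathrm{dual} > \mathrm{gluc} + \mathrm{cort}$.

The raw form implicitly demands an extra margin of one baseline expression
unit; the delta form compares increases directly. Both are implemented and
the choice is a flag, because a gene additive on the delta scale sits
exactly at that rule's boundary and crosses it with probability one half
under noise — the package's tests quantify this rather than hide it.

*Antagonism* (e.g. glucagon-induced, dampened by corticosterone) requires
induction of the single treatment against both the untreated control and
the dual treatment. Synergy and antagonism are provably disjoint: they
demand opposite directions of the same dual-vs-single contrasts.

*Pattern discovery* uses per-gene z-scoring of the four condition means
followed by `stats::kmeans` (k = 5, 10 restarts, fixed seed). Z-scoring
makes the clustering compare response *shapes* rather than expression
levels.

## Assisted and unassisted binding sites

Site classification consumes two site-level contrasts on a shared site
universe: assisted $\Leftrightarrow$ increased in dual vs cort; unassisted
$\Leftrightarrow$ increased in cort vs nt and *not* increased in dual vs
cort ("not increased" meaning failing either gate, the strict complement).
Classes are disjoint and exhaustive (everything else is `other`); both the
assisted count and the unassisted share of cort-increased sites are
reported, since a handful of sites can satisfy both source definitions and
the assisted call takes precedence.

The simplified peak caller tiles the genome with fixed windows, tests each
against a local Poisson background $\lambda = \max(\text{genome-wide},
\text{1 kb flanks}, \text{10 kb flanks}, \text{control})$, adjusts by BH
and merges adjacent significant windows. It is a deliberately simple
stand-in for a full peak caller, validated by null calibration and planted
-peak recovery, and is not intended for real fragment-model data.

## Motifs and enhancer clusters

PWM scanning scores both strands with natural-log odds against a uniform
background (pseudocount $10^{-3}$). The default hit threshold is
$0.7\times$ the consensus score unless the motif file supplies one;
scanning reduces the threshold by `logodds_offset` (default 3) to admit
near-consensus sites, since weaker-than-consensus response elements are
exactly the biology of assisted loading. A hit's *motif score* is its
log-odds divided by the consensus log-odds, so 1 means consensus. For
cluster-level statistics, scanning is restricted to accessible units —
sequence between enhancer units never counts.

Clusters are defined center-to-center: DNase units within $\pm$12.5 kb of a
focal site (boundary inclusive), needing at least 2 units. Sites with no
unit and sites below the minimum are excluded and counted separately,
because published unit-count summaries are reported over sites with at
least one enhancer. `cluster_signal` can exclude the focal unit, which
tests whether activation spans the cluster rather than being a property of
the focal enhancer alone.

## The synthetic-data generator

The generator is first-class, tested code; it defines the study conditions
under which every recovery statement in the test suite holds.

**Counts.** Four conditions $\times$ 3 replicates; NB with a single shared
dispersion (default 0.05, a typical well-controlled in-vitro RNA-seq
value); baseline mean 100; inducing fold change 3; synergy factor 1.5
(dual delta = 1.5 $\times$ sum of single deltas); antagonism residual 0.1
(dual retains 10% of the single-treatment delta). Class mean formulas are
exposed in `class_condition_means` and tested literally.

**Genome.** One synthetic chromosome; enhancer clusters at regular 26 kb
spacing (far enough apart that a $\pm$12.5 kb window can never capture a
neighbor's units); 2–6 DNase units of 400 bp packed into an 8 kb span; one
unit per cluster hosts the GR site. Assisted sites carry a weak GRE
(consensus degraded to a target log-odds by successive cheapest
single-base substitutions) plus a CRE in the focal unit (half the time) and
always in a sibling unit; unassisted sites carry a strong GRE and no
planted CRE; inactive sites carry no motif. CTCF intervals flank cluster
edges only. Each cluster is paired with one flanking gene TSS so
nearest-gene recovery is testable.

**Coverage.** Poisson background (0.05 tags/bp) plus triangular peaks of
height `peak_enrichment` $\times$ background: GR binds unassisted sites
equally in cort and dual, assisted sites at 30% height in cort and fully
only in dual, and nowhere without corticosterone; CREB marks planted CREs
in gluc and dual; H3K27ac has a basal level at every unit and rises across
assisted-cluster units in gluc, further in dual; DNase marks all units in
all conditions. Every (assay, condition, replicate) draws from its own RNG
stream derived from the master seed, so adding an assay never perturbs the
others and equal configs are bit-identical.

**What it does not emulate.** Read-level data (no FASTQ, no fragment-length
model), replicate-specific ChIP efficiency, GC or mappability bias,
expression-level heterogeneity across genes (baselines are constant within
a run), multi-chromosome genomes, and overlapping regulatory domains.
Passing recovery tests therefore demonstrates the *inference chain* is
correct under its stated model, not that the pipeline is robust to every
artifact of real sequencing data.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open everywhere; abutting intervals do not
  overlap; interval centers are `start + floor(length/2)`.
- Distance sign convention: reference minus query; ties break toward the
  smaller coordinate.
- Windows are clipped (not padded) at chromosome edges; aggregate profiles
  average only the anchors that cover a bin.
- All-zero features are flagged `untestable` (log2fc 0, p 1) rather than
  dropped, keeping feature universes aligned across contrasts.
- A group with all-zero counts gets a 0.5-count continuity correction so
  the Wald statistic stays finite.
- Percentages print to the nearest integer, switching to one decimal at
  99% — the convention used for reported overlap shares.
- k-means ties and restarts are controlled by a recorded seed; identical
  profiles always share a label.

## Problem sizes

The test suite and the acceptance script run the full chain at desk scale:
2,000–5,000 null genes for calibration, 200 genes per planted interaction
class over a 2,000-gene null background for recovery (the generator's
default null-majority composition; a transcriptome where 86% of genes
respond would defeat any global normalization and corresponds to no real
experiment), and 150 GR sites across a ~4 Mb synthetic chromosome. The
whole suite completes in well under a minute of compute on one CPU.

## Known limitations

- The dispersion trend is a two-parameter least-squares fit, not an
  empirical-Bayes hierarchical model; it is validated by calibration on
  simulated data rather than by theory.
- The sum criterion for synergy is a point comparison without a standard
  error, faithful to its printed definition; genes near the additive
  boundary are classified with error probability near one half.
- The peak caller ignores duplicate reads, fragment models and input
  subtraction beyond a rate comparison.
- Motif scanning assumes a uniform background; no GC matching is done, so
  background sets for enrichment comparisons must be supplied explicitly.
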