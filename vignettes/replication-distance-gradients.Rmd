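---
title: "Replication-distance gradients on circular multi-origin chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replication-distance gradients on circular multi-origin chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replorg)
```

## The scientific question

Crenarchaea such as *Sulfolobus* replicate their single circular
chromosome from several replication origins that fire in near synchrony
once per cell cycle. Under synchronous firing and constant fork speed,
the shortest arc distance from a locus to its nearest origin is
proportional to the time in the cell cycle at which that locus is
replicated. `replorg` asks how gene expression and genome organisation
vary along this replication-time axis: are highly expressed genes,
essential (archaeal core) genes, dense coding regions and wide
divergent promoters concentrated near origins, and transposons pushed
away from them — and is any expression gradient larger than the trivial
gradient produced by gene dosage in a growing population?

## Coordinate model

All positions live on a circle of length $L$ with origin set
$O = \{o_1, \dots, o_k\}$, 0-based, with modular arithmetic throughout.
The distance of position $x$ to the nearest origin is

$$d(x) = \min_{o \in O} \min(|x - o|,\; L - |x - o|) \in [0, L/2].$$

Genes are half-open intervals $[s, e)$; a gene wrapping across position
0 is encoded with $e < s$. The reference point of a gene is its modular
midpoint. The choice of midpoint (rather than start or closest edge) is
a deliberate design decision: it is unbiased for long genes and makes
window membership and distance annotation consistent with each other.

Divergently transcribed pairs are immediately adjacent genes (no gene
between them, adjacency wrapping around the circle) with the upstream
gene on the minus strand and the downstream gene on the plus strand, so
their 5' ends face each other across a shared intergenic region. The
gap is the modular distance from the upstream gene's end to the
downstream gene's start; overlapping divergent genes get gap 0 rather
than a negative value or exclusion, keeping all pairs on one
non-negative scale. Whether "adjacent" should be strict immediate
adjacency is genuinely open; we chose the strict reading because any
intervening gene means the intergenic region is not shared.

## From two-channel spots to expression

Expression is estimated from two-channel microarrays in which labelled
cDNA is co-hybridised with genomic DNA from stationary-phase cells. In
stationary phase all loci have equal copy number, so the cDNA/gDNA
ratio of a spot estimates relative transcript abundance while
cancelling probe-specific binding efficiencies, which multiply both
channels equally. The pipeline is:

1. **Filter**: keep spots that pass the scanner quality flag and have
   foreground strictly above background in both channels. The detailed
   quality criteria of spot segmentation are upstream of this package;
   the flag is taken as input. Spots with foreground equal to
   background are removed rather than clipped, so the log ratio is
   always defined.
2. **Ratio**: $\log_2((F_c - B_c)/(F_g - B_g))$ per spot.
3. **Normalize**: subtract each array's mean log ratio, so every array
   has mean zero. The mean (not the median) is centred, and no
   intensity-dependent (loess) correction is applied — the gDNA
   reference channel already absorbs sequence-specific effects.
4. **Summarize**: average replicate spots within each array first, then
   average across arrays with equal weight per array regardless of how
   many replicates survived. The two-stage order matters: an array that
   lost a replicate still contributes exactly one vote. How surviving
   replicates should be weighted across arrays is not uniquely
   determined by the measurement model; equal array weights are the
   simplest reading and are what the tests pin down.

A noise-free simulated table is inverted exactly (up to one global
additive constant — absolute abundances are not identifiable from
ratios), which the test suite asserts to $10^{-9}$.

## Core genes, windows and statistics

**Core genes.** A COG (cluster of orthologous groups) is core when it
is present in *exactly one* copy in every genome of a copy-count
matrix, excluding designated reduced-genome symbionts. Multi-copy
families are excluded because not every member of an expanded family
can be assumed essential. Genes inherit the `core` label through their
COG id; orthology itself is always consumed as a precomputed table.

**Windows.** Feature tracks are computed either in sliding windows
(default 100 kb translocated in 1 kb steps, for chromosome-scale
plots) or in non-overlapping windows (default 100 kb, for
window-level correlation tables). Sliding windows share 99% of their
content with their neighbours, so correlations computed on them would
pretend to a sample size they do not have; the correlation table
therefore defaults to non-overlapping windows (a 2.2 Mb chromosome
gives 22 independent windows), with the mode exposed as a
configuration switch. Gene membership is by midpoint, with no
fractional overlap weighting; divergent pairs are assigned by the
midpoint of their intergenic gap.

**Rank statistics.** Spearman's $\rho$ is the Pearson correlation of
mid-ranks. The two-sided p-value is computed by full permutation
enumeration for $n \le 10$ tie-free samples (the null distribution per
$n$ is enumerated once in C and memoised) and otherwise by the
$t$-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$. The Mann–Whitney
$U$ (with half credit for ties) uses the exact null distribution of $U$
when $\min(n_1, n_2) \le 8$ without ties, and otherwise a normal
approximation with tie and continuity corrections. All p-values are
two-sided; values are clamped into $(0, 1]$. These cutoffs trade
exactness against cost: $10!$ permutations is the largest enumeration
that stays interactive, and `stats::cor.test` itself switches to a
series approximation at exactly this point (the package's enumeration
is checked against `cor.test` up to $n = 9$, where both are exact, and
against an independent permutation oracle).

**Binned confound analysis.** To ask whether core genes sit near
origins *independently of expression*, genes are sorted by expression
and cut into 12 equally sized bins (sizes differing by at most one,
earlier bins taking the remainder, ties keeping input order). Within
every bin containing both categories, Mann–Whitney tests compare core
and non-core genes on expression (the binning should have removed any
difference — a built-in negative control) and on origin distance, with
the direction taken from group medians. Bins are counted at a raw
$\alpha = 0.05$ with no multiple-testing correction — the analysis is a
count of concordant bins, not a family of confirmatory tests — and
$\alpha$ is configurable.

**Category subsets.** Gradient correlations can be recomputed excluding
transcription/translation genes (to rule out the bacterial-style
explanation where only those genes cluster near origins) or restricted
to core / non-core genes. The mapping from functional annotation to
the "transcription and translation" label is supplied as gene
category labels (defaulting to a `txn_translation` tag), since no
single COG-category mapping is canonical.

## The gene-dosage null model

In an asynchronous, exponentially growing population the cell-age
density is $f(a) = 2\ln 2 \cdot 2^{-a}$ on $[0,1]$. If all origins fire
at age $s_0$ and forks finish the most distant locus at $s_0 + s$, a
locus at distance fraction $u = d/d_{\max}$ replicates at age
$a(u) = s_0 + s u$ and has mean copy number

$$\bar c(u) = 1 + \Pr(\text{age} \ge a(u)) = 2^{\,1 - a(u)},$$

so the earliest/latest dosage ratio is $2^{s}$ independent of $s_0$.
With an S phase of one third of the generation time — the *Sulfolobus*
value — this is $2^{1/3} \approx 1.26$, "about 1.3-fold". Since
$s \le 1$, dosage alone can never produce more than a 2-fold gradient;
an observed origin-proximal/distal expression ratio above 4-fold
therefore cannot be a pure dosage artefact. The model assumes perfectly
synchronous firing and equal constant fork speeds; stochastic firing
and termination-zone kinetics are out of scope. A Monte-Carlo
population simulator (inverse-CDF sampling of the age density) serves
as an independent oracle for the closed form.

## The synthetic-data generator

The generator builds genomes in which every downstream signal is
injected with known strength, so each pipeline stage can be verified
against ground truth:

* genes are placed around the circle with exponential intergenic gaps
  whose mean grows linearly with origin distance, lognormal lengths
  (median 800 bp), and fair-coin strands — giving roughly one gene per
  kb, archaeal-like coding density;
* true log2 expression is $\beta_0 + \beta_1 d + N(0, \sigma)$;
* core labels are Bernoulli draws from a logistic decreasing in $d$,
  transposon labels from a logistic increasing in $d$, mutually
  exclusive (core drawn first); all genes are protein-coding and a
  distance-independent fraction carries the transcription/translation
  label;
* the spot model applies a shared per-spot probe efficiency to both
  channels, scales the cDNA channel by $2^{\text{expression}}$ times
  the dosage copy number (exponential condition) or 1 (stationary),
  adds a constant recorded background and per-channel lognormal
  measurement noise, and flags a random spot fraction low-quality;
* duplicate spots on triplicate arrays mirror the usual printing
  design.

Randomness uses one seed with per-stage derived sub-seeds, so changing
spot-stage parameters never perturbs the genome draw, and identical
parameters give byte-identical output.

Two presets exist: a scaled-down test genome (200 kb, three unevenly
spaced origins, ~200 genes) keeping the test suite fast, and a
paper-scale preset (2.2 Mb, three origins, ~2,100 genes) for
acceptance-style runs. The expression slope of the paper-scale preset
is calibrated analytically, not by search: for bivariate-normal data
the population Spearman and Pearson correlations are linked by
$\rho_P = 2\sin(\pi\rho_S/6)$, so the slope achieving a target
$\rho_S$ (default $-0.41$, a typical observed exponential-phase
gradient) is $\beta_1 = \rho_P\sigma/(\mathrm{sd}(d)\sqrt{1-\rho_P^2})$
with the dosage slope $-s/d_{\max}$ subtracted in the exponential
condition, $\mathrm{sd}(d)$ taken over a fine position grid.

What the generator does *not* emulate: operon structure, intensity-
dependent dye bias, spatial print-tip artefacts, correlated probe
cross-hybridisation, genome rearrangements, or stochastic origin
firing. Passing tests therefore demonstrate that the pipeline's
arithmetic and statistics are correct and well calibrated under a
clean generative model — not that any particular real dataset is free
of those artefacts.

## Numerical and calibration choices

* Exact rank tests are discrete: with group sizes around 5-vs-11 (12
  bins over ~200 genes) the largest attainable two-sided Mann-Whitney
  p-value below 0.05 is typically near 0.04, so the test's true size is
  below its nominal level. The null-calibration check in the test suite
  accordingly centres its 99% binomial envelope on the *attainable*
  size — the Poisson-binomial mean computed from the exact null
  distribution of $U$ for the observed group sizes — rather than on
  nominal $\alpha$, which would mistake the conservatism of exact tests
  for miscalibration. The correlation test (continuous, $n \approx
  200$, $t$-approximation) is checked against nominal $\alpha$.
* Simulation problem sizes in tests and the acceptance script: 500
  null-calibration seeds at test scale, 20 recovery seeds and 2
  confound seeds at paper scale, $10^6$ Monte-Carlo cells, ~1,000
  brute-force oracle instances. These sizes put the Monte-Carlo error
  of every check well inside its assertion band.
* Empty windows, genes without expression, and genes losing every spot
  propagate as missing values and are dropped pairwise in correlations;
  a gene with no surviving spot is absent from the expression table
  rather than imputed as zero.
* Rotating the whole coordinate system (genes and origins by the same
  shift) leaves every distance, gap and track invariant; the suite uses
  this symmetry as a free correctness oracle.

## Limitations

* Origin positions are inputs; the package does not predict origins
  from sequence or fit replication-timing data.
* The dosage model is a null model, not a fit: no marker-frequency
  estimation from sequencing coverage is attempted.
* GFF3 cannot represent wrap-around genes; the TSV interchange format
  is the lossless one.
* Window-edge assignment is all-or-nothing by midpoint; features whose
  support straddles a window edge are attributed to one window only.
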