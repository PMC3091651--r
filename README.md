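# replorg

Replication-biased genome organisation analysis for circular
chromosomes with multiple replication origins.

## The problem

Crenarchaea such as *Sulfolobus* replicate a single circular chromosome
from three origins that fire in near synchrony. Under constant fork
speed, the shortest arc distance `d(x)` from a locus to its nearest
origin is a proxy for replication time, making it the natural axis for
asking how the genome is organised around replication: whether highly
expressed genes, essential (archaeal core) genes, dense coding regions
and wide divergent promoters concentrate near origins while transposons
accumulate far from them, and whether an expression gradient along this
axis exceeds what gene dosage alone would produce.

`replorg` is for genomicists analysing such genomes. It implements:

* **circular geometry** — origin distances
  `d(x) = min_o min(|x−o|, L−|x−o|)`, modular gene midpoints, coding
  density of circular intervals, intergenic gaps of divergently
  transcribed adjacent gene pairs;
* **two-channel expression** — GenePix-like spot tables (cDNA
  co-hybridised against stationary-phase genomic DNA) filtered,
  converted to `log2((Fc−Bc)/(Fg−Bg))`, mean-centred per array, and
  averaged first over replicate spots, then over arrays;
* **core-genome calling** — COGs present in exactly one copy in every
  non-excluded genome of a copy-count matrix;
* **window tracks** — sliding (100 kb / 1 kb step) or non-overlapping
  windows for six features, exported as bedGraph/TSV;
* **rank statistics** — Spearman's ρ with exact permutation p-values
  (n ≤ 10) or the t-approximation, Mann–Whitney U with exact
  small-sample p-values, the pairwise window correlation table, and the
  expression-binned core/non-core confound analysis;
* **a gene-dosage null model** — mean copy number `2^(1−a)` under the
  steady-state exponential age distribution, giving an earliest/latest
  ratio `2^s` for an S phase lasting a fraction `s` of the generation
  (`2^(1/3) ≈ 1.26`, "about 1.3-fold", for the *Sulfolobus* third);
* **a synthetic-data generator** — genomes and spot tables with known
  injected gradients, so every stage is testable against ground truth.

## Worked example

Simulate a paper-scale chromosome (2.2 Mb, three uneven origins,
~2,100 genes, expression gradient calibrated to a population Spearman
correlation of −0.41), run the spot-to-expression pipeline and the
gradient analyses:

```r
library(replorg)

params <- sim_params_paper_scale(seed = 11)
sim    <- simulate_dataset(params)            # genome + genes + spots
expr   <- normalize_expression(sim$spots)     # filter/ratio/centre/average
genes  <- add_origin_distance(join_expression(sim$genes, expr), sim$genome)

correlate_subset(genes, "expression", "origin_distance")
#> spearman_t_approx: rho = -0.423, two-sided P = 4.211e-92, n = 2104
correlate_subset(genes, "expression", "origin_distance",
                 exclude_categories("txn_translation"))
#> spearman_t_approx: rho = -0.4321, two-sided P = 3.916e-89, n = 1941

bin_confound_analysis(genes)
#> Expression-binned confound analysis: 12 bins, 12 usable (both categories present)
#> Origin distance differs (P < 0.05) in 5 of 12 usable bins (5 with core genes closer to origins)

w   <- make_windows(sim$genome, 1e5, 1e5, "nonoverlapping")
tab <- feature_correlations(window_features(genes, sim$genome, w))
head(tab[order(tab$p), ], 3)
#>         feature_a       feature_b    rho        p  n            method
#> 1 origin_distance mean_expression -0.980 2.15e-15 22 spearman_t_approx
#> 2 origin_distance core_proportion -0.846 7.01e-07 22 spearman_t_approx
#> 6 mean_expression core_proportion  0.832 1.61e-06 22 spearman_t_approx

dosage_ratio(cell_cycle_model(s_start = 0.05, s_duration = 1/3))
#> [1] 1.259921
```

The gene-level correlation recovers the injected gradient; excluding
transcription/translation genes leaves it intact; the window table
shows expression and core-gene density falling with origin distance
while transposon density rises; and the dosage null model caps the
expression fold attributable to replication timing alone at
`2^(1/3) ≈ 1.26` — far below multi-fold observed gradients.

A thin command-line front end wrapping these functions (subcommands
`run`, `simulate`, `normalize`, `distance`, `windows`, `correlate`,
`bins`, `dosage-curve`) ships under `inst/cli/replorg`; YAML run
configurations drive `run_pipeline()`, which writes expression tables,
annotated gene tables, bedGraph tracks, correlation TSVs, the bin
report and a run log.

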