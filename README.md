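# micasm

Community assembly and micropollutant removal analysis for
serial-transfer microcosm experiments.

## The problem

Trace organic micropollutants (bisphenols, triclosan and their analogs)
reach natural waters at sub-microgram-per-litre concentrations and are
re-introduced continuously — a *press disturbance* for the resident
microbial communities. Serial-transfer microcosms probe this: a source
community is incubated with micropollutants for five days, 10% is
transferred into fresh medium with freshly spiked compounds, and the
cycle repeats for seven batches (35 days). `micasm` provides the
downstream analysis for such experiments, for microbial ecologists
working from an OTU count table, a rooted 16S phylogeny, an rrnDB-style
copy-number map and a compound concentration time series:

* **Assembly-process partitioning.** Phylogenetic turnover per
  treatment-vs-control sample pair is measured by the
  abundance-weighted β-mean nearest taxon distance (βMNTD) and
  standardized against a tip-shuffle null (999 randomizations) into the
  β-nearest taxon index, βNTI = (βMNTD_obs − μ_null)/σ_null. Taxonomic
  turnover is located in a Raup–Crick null (RC_bray ∈ [−1, 1]). Each
  pair is classified as variable selection (βNTI > 2), homogeneous
  selection (βNTI < −2), dispersal limitation (RC_bray > 0.95),
  homogenizing dispersal (RC_bray < −0.95) or ecological drift, and
  fractions are reported per growth phase.
* **Dissimilarity–overlap analysis.** Overlap (shared-taxon abundance
  mass) against root Jensen–Shannon divergence of the renormalized
  shared fractions, with an OLS slope above the median-overlap cutoff
  and a sample-bootstrap fraction-negative statistic.
* **Growth phases.** Abundance-weighted mean 16S copy number per
  sample; complete-linkage clustering of per-batch profiles
  (Bray–Curtis) with an exhaustive contiguity-constrained fallback.
* **Ecological grouping.** Sensitive / opportunistic / tolerant OTU
  calls from one-sided phase contrasts on median-of-ratios-normalized
  counts, Benjamini–Hochberg controlled at α = 0.05.
* **Removal statistics.** Per-batch removal 100·(C₀ − C₅)/C₀ with
  rank-sum and Kruskal–Wallis contracts, and turnover regression of
  treatment-vs-control dissimilarity on time.

A seeded synthetic generator (`simulate_experiment()`) reproduces the
whole design — coalescent phylogeny, phylogenetically conserved
tolerance traits, degrader guilds, logistic regrowth, guild-coupled
first-order chemical decay, 10% binomial transfers, multinomial
sequencing — with ground truth for every downstream stage, so the
entire pipeline is testable end to end. See the methods vignette
(`vignettes/microcosm-assembly.Rmd`) for models, parameters and design
choices.

## Worked example

Simulate a two-arm experiment (control vs 1 µg/L triclosan, a stress
compound), rarefy, and partition assembly processes across the three
growth phases:

```r
library(micasm)

cfg <- sim_config(n_otus = 60, sequencing_depth = 5000,
                  treatments = list(Control = c(), TCS = c(TCS = 1)),
                  seed = 42)
sim <- simulate_experiment(cfg)
sim
#> microcosm_sim (selection regime, seed 42)
#> community_table: 42 samples x 60 OTUs
#>   treatments: Control, TCS
#>   batches:    B1, B2, B3, B4, B5, B6, B7
#>   total reads: 211156 (min sample 4504, max 5447)
#>   chemistry records: 63

rar <- rarefy(sim$community, seed = 42)      # to the smallest library
pf <- process_fractions(rar, sim$tree, "TCS", paper_phases(),
                        n_null = 199, seed = 42)
pf
#> assembly_result: TCS vs control, 153 pairs
#>      process
#> phase dispersal_limitation drift homogeneous_selection homogenizing_dispersal
#>     1                0.194 0.778                     0                      0
#>     2                0.028 0.139                     0                      0
#>     3                0.000 0.000                     0                      0
#>      process
#> phase variable_selection
#>     1              0.028
#>     2              0.833
#>     3              1.000
```

Early batches are assembled almost entirely by drift (0.78 in phase 1);
by the late phase every pair is under variable selection — the
stochastic-to-deterministic transition that sustained stress exposure
produces. Shared-taxon dynamics and removal:

```r
doc_analysis(rar, "TCS", n_boot = 200, seed = 42)
#> doc_result (TCS): 210 pairs, cutoff 0.981
#>   slope m = -8.278; fraction of 200 bootstrap slopes < 0: 1.000

summarize_removal(removal_rate(sim$chem))$summary
#>  treatment compound mean_removal sd_removal
#>        TCS      TCS       57.329   2.050637
```

The negative dissimilarity–overlap slope (all bootstrap slopes
negative) says high-overlap sample pairs are also the least dissimilar:
shared taxa behave consistently across batches. TCS removal sits near
57% per batch — the partial, tolerance-gated degradation regime of a
stress compound.

`run_all(run_config(...))` chains every stage (simulate/load → rarefy →
phases → assembly → DOC → turnover → removal → grouping) under one seed
and writes a JSON report plus per-stage TSVs.

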