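---
title: "Community assembly under repeated micropollutant exposure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community assembly under repeated micropollutant exposure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The experimental system

`micasm` analyses serial-transfer microcosm experiments: a source
microbial community is inoculated into bottles containing trace
micropollutants, incubated for five days, and 10% of each bottle (60 mL
of 600 mL) is then transferred into fresh medium with freshly re-spiked
compounds. Repeating this for seven batches (B1-B7, 35 days) imposes a
*press disturbance*: the community is repeatedly diluted, regrows, and
re-encounters the same chemical environment. The reference design has
five arms -- a no-compound control, single compounds BPA (1 ug/L) and
TCS (1 ug/L), and mixtures MI (BPA + TCS) and MII (BPA + BPS + TCS +
TCC, the analogs at one-tenth concentration) -- with three replicate
transfer lines each, i.e. 105 bottles in total. Communities are
characterized by 16S amplicon counts (an OTU table) at the end of every
batch; compound concentrations are measured at days 0, 2 and 5 of every
batch.

Two response types organize the biology. *Subsidy* compounds (BPA, BPS)
can be used as carbon sources by a subset of taxa ("degraders");
*stress* compounds (TCS, TCC) inhibit growth of sensitive taxa. The
package's questions are: how much is removed per batch, how does the
community turn over relative to the controls, which ecological
processes (selection, dispersal, drift) assemble the communities at
each growth phase, whether shared taxa follow shared dynamics, and
which taxa are sensitive, opportunistic, or tolerant.

# Statistics implemented

## Assembly-process partitioning

Phylogenetic turnover between two communities is the abundance-weighted
beta mean nearest taxon distance,

$$\beta MNTD = \frac{1}{2}\left[\sum_{i} x_i \min_j D_{ij} +
\sum_{j} y_j \min_i D_{ji}\right],$$

with $D$ the patristic (cophenetic) distance matrix and sums over taxa
present in each sample. The beta nearest taxon index standardizes the
observed value against a *tip-shuffle* null: taxon identities are
permuted across the tips of the phylogeny (equivalently, rows and
columns of $D$ restricted to the regional pool are permuted), beta-MNTD
is recomputed for `n_null` permutations (999 by default), and

$$\beta NTI = \frac{\beta MNTD_{obs} - \mu_{null}}{\sigma_{null}}.$$

Taxonomic turnover is located within a Raup-Crick null: each replicate
redraws both samples from the regional pool (taxa drawn at the observed
richness with probability proportional to occupancy frequency; one
individual per drawn taxon, the remaining reads allocated multinomially
by regional relative abundance), and

$$RC_{bray} = \frac{2\left[\#(null < obs) + \tfrac12\,\#(null =
obs)\right]}{n_{null}} - 1 \in [-1, 1].$$

Pairs are classified into five processes: $\beta NTI > 2$ variable
selection, $\beta NTI < -2$ homogeneous selection; otherwise
$RC_{bray} > 0.95$ dispersal limitation, $RC_{bray} < -0.95$
homogenizing dispersal; otherwise drift. Process fractions per
(treatment, growth phase) are the proportions of treatment x control
sample pairs carrying each label.

Three genuinely open choices are resolved as follows, each switchable:

* **Sign convention.** The thresholds $\pm 2$ only make sense for a
  z-score, and the framework this statistic comes from maps *positive*
  deviations (more phylogenetic turnover than expected) to variable
  selection. That is the default; `invert_selection = TRUE` swaps it.
* **Regional pool.** The pool for both null models is the union of taxa
  observed in the two compared groups *within the phase*
  (`pool = "phase"`), so phases are self-contained analyses;
  `pool = "global"` uses the whole experiment.
* **Pairing.** All treatment x control cross pairs within a phase are
  scored (the replicate lines are exchangeable under the design);
  turnover regression additionally offers `pairs = "matched"` for the
  physically paired transfer lines.

Degenerate cases are explicit: a null distribution with zero spread
makes the z-score undefined and `bnti()` raises an error (a star
phylogeny is the canonical case). Inside `process_fractions()` one
degenerate case is expected and handled: after rarefaction two samples
can share their entire support, making beta-MNTD identically zero under
every permutation; such pairs carry no phylogenetic deviation, are
assigned $\beta NTI = 0$, and fall through to the $RC_{bray}$ rule.

## Dissimilarity-overlap analysis

For every within-treatment sample pair, the *overlap*
$O = \tfrac12 \sum_{i \in S}(x_i + y_i)$ measures the abundance mass of
shared taxa $S$; the *dissimilarity* is the root Jensen-Shannon
divergence of the shared fractions renormalized to sum to one. Base-2
logarithms bound rJSD in $[0, 1]$ (the base is a convention; base 2
makes the maximum exactly 1). A negative ordinary-least-squares slope
on the points above an overlap cutoff (the median overlap by default)
indicates shared taxon dynamics. Uncertainty is summarized as the
fraction of bootstrap slopes below zero, where the bootstrap resamples
*samples* (not pairs) with replacement: pairs sharing a sample are
dependent, and resampling pairs would understate uncertainty. Bootstrap
replicates that duplicate a sample exclude the self-pair; replicates
with fewer than three points above the cutoff are dropped from the
denominator (the reported `n_boot` is the effective count).

## Growth phases from 16S copy numbers

Fast-growing bacteria carry more rRNA operons, so the
abundance-weighted mean 16S copy number of a sample
($\sum_i f_i c_i$ over the OTUs with an rrnDB-style assignment, with
$f$ renormalized over those OTUs) tracks the community's growth
strategy. Weights are read-based relative abundances, uncorrected for
copy number (the conventional choice for this index; a
copy-number-corrected mode exists). Batches are clustered by
complete-linkage hierarchical clustering of their copy-number profiles
(vector of treated-microcosm means, controls excluded) under
Bray-Curtis dissimilarity, cut at $K = 3$. Because phases must respect
the time continuity of the serial inoculation, a non-contiguous cut is
replaced by the contiguous partition minimizing within-phase sum of
squares -- an exhaustive search over the $\binom{n-1}{K-1}$ contiguous
partitions (15 for 7 batches), with ties broken towards equal sizes and
then earliest boundaries, which makes the rule deterministic. The
reference assignment (B1-B2, B3-B4, B5-B7) is available as
`paper_phases()`.

## Ecological grouping

OTUs are classified from six one-sided phase contrasts (1>2, 1>3, 2>1,
2>3, 3>1, 3>2) on size-factor-normalized counts: *sensitive* peaks in
phase 1, *opportunistic* in phase 2, *tolerant* in phase 3, each
requiring both of its defining contrasts to be significant after
Benjamini-Hochberg adjustment at $\alpha = 0.05$. Adjustment is joint
over all (OTU x contrast) tests within a treatment -- the conservative
choice of family. Size factors are median-of-ratios (per sample, the
median ratio of counts to the OTU-wise geometric mean, over OTUs
present in every sample); a pseudocount mode covers tables with no
universally present OTU. The default per-contrast test is an exact /
Edgeworth-corrected rank-sum test (below); `test_fun` accepts any
replacement, e.g. a negative-binomial Wald p-value, for users who want
a parametric count model. OTUs below 10% prevalence are not tested.
Categories are mutually exclusive by construction since their defining
contrast directions conflict.

## Rank tests

`rank_sum_test()` enumerates the exact permutation distribution of the
Mann-Whitney U statistic -- ties included -- whenever
$n_a + n_b \le 12$, and otherwise uses a normal approximation with tie
correction, continuity correction, and an Edgeworth kurtosis term (the
U distribution is platykurtic; its exact fourth-moment correction,
verified against full enumeration, keeps the approximation within 0.01
of the exact p-value at $n = 6$ per group). Two conventions are fixed:
if every value in both samples is identical, $p = 1$; two-sided
p-values are twice the smaller tail, capped at 1.
`kruskal_wallis()` uses the tie-corrected H statistic with a
chi-squared reference.

## Removal and turnover

Per-batch removal is $100\,(C_0 - C_5)/C_0$ percent -- day 0 (the
fresh spike) against day 5 (the end of the batch); day-2 records are
retained for plotting only. Negative removal is reported as-is; a zero
day-0 concentration skips the record with a warning. Community turnover
is the OLS slope of treatment-vs-control Bray-Curtis dissimilarity on
sampling day, with rank-sum contrasts of each later batch against B1.
Bray-Curtis is computed on rarefied counts (rarefaction to the smallest
library before any beta-diversity work; subsampling is without
replacement and never invents taxa).

# The synthetic generator

`simulate_experiment()` generates the full design with known ground
truth. Its defaults are the reference study conditions; each parameter
below is a modelling choice the downstream statistics are tested
against, not a fit to any data set.

* **Phylogeny and traits.** A random coalescent tree
  (`ape::rcoal`) over 150 OTUs. Stress tolerance evolves by Brownian
  motion (rate 1 per unit branch length) and is mapped to $(0,1)$ by
  its empirical z-score -- phylogenetically conserved, which is what
  makes selection visible to beta-NTI. A random 20% of OTUs are
  degraders. 16S copy numbers are a Brownian trait rank-mapped to
  integers 1-15.
* **Latent dynamics.** Per day, the composition is multiplied by
  $\exp\{s\,(0.5\,\delta_i\,C_{sub} - 1\,(1 - tol_i)\,C_{str})\}$
  (selection strength $s$, degrader indicator $\delta$, compound
  concentrations in ug/L), renormalized, and resampled multinomially at
  an effective size of $10^4$ cells. $s = 0$ is the neutral regime:
  pure demographic drift. The effective size is deliberately far below
  a bottle's census size -- it is the scale of *effective* drift in a
  bottlenecked laboratory community, and `Inf` disables drift entirely
  (used as the no-effect null in tests).
* **Transfers and sequencing.** Transfers binomially thin each OTU's
  cells at 10% and regrow; the B1 inoculum is a multinomial draw from a
  shared lognormal source composition (log-sd 1.5). Sequencing draws
  each sample's reads multinomially at a depth uniform in
  $[0.9, 1.1] \times 36000$, so rarefaction to the minimum library is
  exercised.
* **Chemistry.** Total biomass follows a daily logistic curve from 10%
  of capacity (rate 1.2/day, reaching capacity within a batch).
  Compounds decay as $dC/dt = -k\,a(t)\,C$ with $k = 0.8$/day and
  $a(t)$ the biomass fraction of the responding guild: degrader
  abundance for subsidy compounds; tolerance-weighted abundance scaled
  by 0.45 for the slower, co-metabolic removal of stress compounds.
  These constants place per-batch removal near 85-90% for BPA and
  50-60% for TCS, the regimes the analysis code must distinguish.
  Analog compounds (BPS, TCC) are scaled copies of their parents at
  one-tenth concentration; compound interactions are not modelled.
  Abiotic bottles (`abiotic = TRUE`) contain no cells and leave
  concentrations untouched.

What the generator does *not* emulate: sequence-level artifacts
(chimeras, primer bias), taxon-taxon interactions, dormancy/seed-bank
dynamics, immigration, and compound-compound interactions. Passing
tests therefore demonstrate that the statistics recover the processes
*as modelled* -- selection on a conserved trait, neutral drift,
guild-coupled decay -- not that they would resolve every mechanism in
real data.

# Numerical and testing choices

* All randomness flows from one seed; every exported stochastic
  function takes `seed = NULL` (consume the caller's RNG stream) so
  `run_all()` is bytewise reproducible.
* RC ties take half weight; equality is tested at $10^{-12}$.
* The beta-MNTD permutation loop is compiled (Rcpp); the full reference
  pipeline (150 OTUs, 105 samples, 999 randomizations, 612 pairs) runs
  in under ten minutes on one CPU.
* Null calibration of beta-NTI is assessed at deployment scale (pools
  of ~150 taxa, per-sample richness ~100): for small supports on
  imbalanced coalescent trees the conditional null is strongly skewed
  and z-scores are heavy-tailed, a property of the statistic itself.
  At deployment scale the z-scores are calibrated (mean ~0, sd ~1,
  $P(|z|>2) \approx 0.045$).
* Test problem sizes are scaled down (typically 25-80 OTUs, depths
  2000-10000, 99-199 randomizations) except where a check is about the
  reference scale itself; seed-majority checks use 10-20 seeds.

# Limitations

* The rank-based differential-abundance engine is a documented
  substitute for a negative-binomial Wald test; with three replicates
  per arm its per-OTU power is modest, so borderline taxa differ from
  what a parametric engine would call. The `test_fun` hook exists for
  exactly that comparison.
* The Raup-Crick null conditions on observed richness and regional
  abundances; it does not model library-size variation beyond the
  observed totals.
* Growth-phase inference assumes the copy-number map covers the
  abundant taxa; samples whose assigned OTUs hold little read mass get
  noisy weighted means.
* The simulator's chemistry is first-order and guild-coupled; it is a
  test harness for the statistics, not a calibrated biodegradation
  model.
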