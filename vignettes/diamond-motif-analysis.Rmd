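---
title: "Diamond-motif analysis of tripartite mycorrhizal networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diamond-motif analysis of tripartite mycorrhizal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

Mycoheterotrophic (MH) plants cheat the arbuscular mycorrhizal symbiosis:
they take carbon from fungi that other, autotrophic plants are feeding. For
such cheating to be evolutionarily stable, each antagonistic link must sit
on top of a working mutualistic one, so the natural unit of analysis is the
tripartite network: a binary MH × fungus block **M** and an autotroph ×
fungus block **A** over one shared fungal index. The central hypothesis is
that cheaters preferentially attach to *keystone* fungi — fungi that are
well connected within the autotroph community and therefore a reliable
carbon source.

That hypothesis leaves a fingerprint at the level of a four-node subgraph:
the **diamond module**, an unordered pair of distinct fungi both linked to
the same MH plant and the same autotroph. With fungal co-occurrence
matrices $S^M = M^\top M$ and $S^A = A^\top A$, the observed count is

$$N \;=\; \sum_{f_1 < f_2} S^M_{f_1 f_2} \, S^A_{f_1 f_2},$$

which is algebraically identical to exhaustive enumeration of quadruples
(a property the test suite verifies against a brute-force oracle). A plant
pair sharing only a single fungus is *not* a module; the two fungi must be
distinct.

## The null model and what "overrepresented" means

Observed counts are compared to degree-proportional Bernoulli null
networks: in a block with $R$ plants and $C$ fungi, each cell is an
independent Bernoulli draw with

$$p_{ij} = \tfrac12\!\left(\frac{k_i}{C} + \frac{k_j}{R}\right),$$

the arithmetic mean of the plant's and the fungus's fill fractions. The
probabilities conserve the block's link total exactly
($\sum_{ij} p_{ij} = L$). Because the two guilds have very different sizes,
each block is randomized from its own probabilities and the blocks are
recombined over the unchanged fungal index before counting.

Each test reports the z-score $(N - \bar{N}_{null})/SD_{null}$, a
one-tailed empirical p-value with the +1/+1 convention
$p = (1 + \#\{N_{null} \ge N\})/(1 + n_{null})$ — so the smallest
reportable p is $1/(1+n_{null})$, never 0 — and the 2.5th/97.5th
percentiles of the null counts. The **overrepresentation flag is governed
by the percentile interval** (observed above the 97.5th percentile); z and
p are reported alongside and, when the two rules disagree, the percentile
rule wins. Two scopes are run: *all* fungi, and *shared* fungi only, where
the empirical network is first restricted to fungi present in both guilds
and the null probabilities are recomputed on the restricted blocks — the
sharper question of preference *within* the fungi the cheaters actually
use.

### Empty rows and columns in null draws

A surveyed plant always carries at least one fungus, so null draws leaving
a plant row empty are rejected and the whole matrix redrawn (cap 1000;
whole-matrix redraw avoids biasing individual cells). Fungal columns are
deliberately *not* constrained: with only a handful of plants per block, a
low-degree fungus goes extinct in a sizable fraction of faithful null
draws — just as rarefaction removes rare fungi from empirical matrices —
and the aligned blocks of a tripartite network legitimately contain empty
columns (fungi carried only by the other guild). Conditioning columns on
presence would be both infeasible (the clean-draw probability at realistic
sizes is astronomically small) and a misrepresentation of the null.

### A calibration caveat

The null model is a *mean-field* model: refitting it to one of its own
draws halves marginal deviations ($\hat p = \tfrac12 p + \tfrac12 \bar p$).
Consequently the test is exactly calibrated when the data-generating
process really is degree-proportional with homogeneous fill (the
calibration test in the suite draws from exactly that case and recovers
the nominal 2.5% flag rate and a zero-centered z), but for data with
strong multiplicative row × column structure the plug-in null is flatter
than the generator and z-scores shift upward. This is a known property of
Bernoulli cell-probability nulls, shared with the original formulation;
conclusions should therefore lean on the magnitude of z and on robustness
across rarefactions, resamplings and depths, not on a single marginal
flag.

## Preprocessing

The chain is fixed, in this order, because reordering changes results:

1. **Cell mask** (`min_otu_reads`, default 6 reads): cells with fewer
   reads are set to zero — the standard guard against tag switching in
   amplicon sequencing. This is deliberately a per-cell rule, not global
   OTU deletion: an OTU genuinely abundant in one sample survives a
   trickle in another. OTU columns emptied by the mask are dropped.
2. **Sample filter** (`min_sample_reads`, default 500 reads): samples with
   fewer total reads are discarded (strict `<`).
3. **Species pooling**: samples of one plant species are summed into its
   community.
4. **Species filter** (`min_species_reads`, default 500 reads): species
   pools below the threshold are discarded; a guild losing all species is
   an error because every downstream analysis needs both guilds.
5. **Rarefaction** (`rarefy_depth`, default 844 reads; `n_rarefactions`,
   default 100): each species pool is subsampled to the common depth
   *without replacement* (multivariate hypergeometric — the standard
   ecological meaning of rarefaction), removing read-depth bias. A species
   below the depth raises an error naming it rather than silently
   dropping, since the depth is meant to be chosen at or below the
   smallest pool.
6. **Binarization**: presence/absence only. Read abundance does not track
   fungal abundance when whole root systems (MH) and root fragments
   (autotrophs) are sampled side by side, so only *which* interactions
   exist is interpretable.

## Phylogenetic components

Phylogenetic species variability (psv) summarizes how phylogenetically
spread a plant's fungal community is: $1$ for a star-like set of
unrelated fungi, approaching $0$ as relatedness increases. We compute the
tip correlation as shared root-to-MRCA path length over the geometric mean
of tip depths, which reduces to the classic covariance formulation on
ultrametric trees and stays defined on non-ultrametric ones; psv is then
one minus the mean off-diagonal correlation. Communities of fewer than two
fungi yield `NA` with a warning, not an error.

Phylogenetic signal uses Mantel tests between cophenetic distances and
Jaccard dissimilarity of partner sets; cross-guild coupling uses Mantel
tests between the two guilds' fungal similarity matrices, and a partial
Mantel controlling fungal relatedness. All tests are one-tailed for
positive association (the directional ecological hypothesis, and the
convention of the standard implementations), use `n_perm = 999` by default
(a conventional choice; the count is configurable), and permute the second
matrix's labels. For the partial statistic the controlling correlations
are held fixed and the partial r is recomputed per permutation.
Degenerate inputs (zero-variance triangles, collinear controls) signal
`NA` results with warnings instead of crashing. Because similarity
matrices of the two guilds are only conformable on fungi present in both,
cross-guild tests are computed on the shared-fungi restriction — the only
choice that makes the matrices comparable.

## The synthetic-data generator

The generator produces datasets with the shape of a root-tip OTU survey
of a species-rich AM community, and is itself tested code:

- 21 autotroph and 5 MH species, 115 fungal OTUs, 1–9 samples per species
  (defaults; all configurable).
- Per-sample read totals are lognormal (median ≈ 3000 reads) floored at
  1200 reads, so default datasets clear the 500-read filters and every
  species pool exceeds the 844-read rarefaction depth — mirroring a study
  design in which the depth is the smallest species pool. A `stress`
  switch generates sub-filter samples for testing the filters themselves.
- Each fungus carries a latent attachment score mixing a Brownian trait
  evolved on the fungal tree (weight `phylo_signal`, default 0.5) with an
  independent component, scaled by `heterogeneity` (default 1.5, giving
  realistically skewed fungal degree distributions). Autotroph–fungus
  probabilities are logistic in that score plus a plant effect around a
  baseline fill of 0.15.
- MH attachment scales with the fungus's expected autotroph degree raised
  to `gamma` — the keystone-preference knob. `gamma = 0` is exactly
  degree-independent; the default `gamma = 1` encodes the moderate
  preference regime the analysis is designed to detect; power tests use
  `gamma = 2`.
- Within a sample, realized fungi (Bernoulli from the species'
  probability row) each receive at least one read, with the remainder
  spread by a symmetric-Dirichlet multinomial (`alpha = 0.3`, skewed read
  counts), so read-level incidence reproduces the probability matrix
  exactly.

What the generator does *not* emulate: OTU-clustering noise, chimeras and
cross-run batch effects; spatial structure beyond a nominal subplot label;
abundance-dependent detection; and, importantly, *identity-level*
phylogenetic niche conservatism — the injected fungal signal acts on
attachment propensity (how many plants a fungus reaches), so related fungi
get similar degrees rather than similar plant *sets*. Profile-distance
recovery of that signal is strong, but the pipeline's incidence-Jaccard
Mantel has little power against it; passing tests on synthetic data
therefore demonstrate the machinery's correctness and calibration, not
that any particular real community will show signal.

## Reproducibility and problem sizes

Every top-level entry point seeds R's RNG from an explicit integer
(`run_config(seed = ...)`, `sim_config(seed = ...)`), with fixed per-stage
offsets inside `run_full_analysis()`, so a full run is bit-reproducible
from its configuration alone — the suite asserts byte-identical serialized
reports and result files.

Default replicate counts follow the field's conventions (100 rarefactions,
1000 null networks, 1000 resamplings, k = 3 samples per species). The
package's own test suite and the acceptance script run the same code at
desk scale — e.g. 200-network nulls, 199 permutations, 25 rarefactions, a
200 × 200 calibration grid — sizes chosen so the whole battery runs in
minutes while the Monte-Carlo error of each check stays well inside its
assertion bounds; full-size runs are one configuration flag away.

## Known limitations

- Null model 2 fixes degrees only in expectation; for strongly
  non-additive interaction structure the plug-in null is anti-conservative
  (see the calibration caveat above).
- Empirical p-values are bounded below by $1/(1+n_{null})$; exact zeros
  are never reported.
- The percentile-interval flag at 95% has the usual discreteness of
  small-sample quantiles when `n_null` is small; `n_null >= 200` is
  recommended.
- The sample-resampling ensemble must choose a rarefaction depth per
  replicate; we use the replicate's minimum species pool (logged per
  replicate) to keep depth comparable within a replicate. Other choices
  (a fixed global depth) are defensible and would change absolute counts,
  though not the machinery.
- Mantel tests inherit the usual caveats of distance-matrix permutation
  tests (non-independence of pairs; power depends on how signal maps onto
  distances).
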