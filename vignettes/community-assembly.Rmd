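---
title: "Assessing community assembly in activated-sludge time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing community assembly in activated-sludge time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sludgenet)
```

## The question

Activated-sludge bioreactors host dense microbial communities whose
composition drifts with season, operation and start-up history. Two forces
shape that drift: deterministic habitat filtering (taxa tracking their
environmental niches) and stochastic assembly (drift, dispersal, priority
effects). `sludgenet` implements a network-and-null-model framework for
telling them apart in ASV time series from such plants:

1. a probabilistic **co-occurrence/co-exclusion metaweb** over all samples,
2. **walktrap modules** of the co-occurrence layer and their per-sample
   **completeness**,
3. per-sample **timepoint networks** with topology metrics standardized
   against **stochastic block model (SBM) nulls**,
4. **phylogenetic dispersion** (NRI/NTI) against taxa-shuffle nulls,
5. **Hill-number** alpha diversity and Bray-Curtis beta diversity,
6. **pollutant-removal correlations** (BOD, TN, TP) with FDR control.

## The pair model

For two ASVs present in `n_a` and `n_b` of `N` samples, the number of shared
samples under random, independent placement is hypergeometric:

$$P(J = j) = \frac{\binom{n_a}{j}\binom{N-n_a}{n_b-j}}{\binom{N}{n_b}}.$$

The probability that a random pair would share *fewer* samples than observed,
`p_lt = P(J < j_obs)`, is the co-occurrence probability; `p_gt = P(J > j_obs)`
is the co-exclusion probability. A pair is classified co-occurring when
`p_lt >= 0.95` (co-excluding symmetrically). Choices worth knowing:

* **No multiple-testing correction** is applied to pair tests: the fixed 0.95
  rule *is* the classifier. Its two-tailed type-I error on independent
  presence vectors is about 0.057 at `N = 60` (the discreteness of the
  hypergeometric keeps each tail well below 0.05).
* Pairs whose feasible support is a single point (e.g. `n_a = N`) carry no
  information and are classified `none`.
* The inclusive boundary (`>=`) is the default; a strict `>` is available via
  `run_config(inclusive = FALSE)`. The two differ only when a tail equals the
  threshold exactly, which does not occur at these sample sizes.
* Occupancy for the **occurrence filter** (keep ASVs present in more than one
  but not every timepoint) is counted at the *timepoint* level — present in at
  least one replicate — while the association model runs over *individual
  samples* (`N` = all replicates), because per-sample networks are what the
  dynamics track. Whether to pool replicates before the pair model was an
  open design point; we kept all samples (configurable by collapsing the
  sample map).

## Modules, timepoint networks, and SBM nulls

Modules are found by walktrap (walk length 4) on the co-occurrence layer;
vertices are sorted by ASV id first, so a seed makes results byte-identical.
Isolated nodes become singleton modules, and labels are renumbered largest
first. Each sample's timepoint network is the induced subgraph of both layers
on the ASVs present in that sample; from it we compute

* **modularity** (Newman-Girvan Q) of a *fresh* walktrap partition of the
  induced co-occurrence subgraph — the per-sample structure is what the time
  series tracks; scoring the inherited metaweb partition instead is available
  via `fresh_partition = FALSE`;
* **clustering coefficient** = global transitivity (ratio of closed to
  connected triples); average-local is behind a flag;
* **co-exclusion proportion** = co-exclusion edges / all induced edges. The
  phrase is ambiguous between edge- and node-based readings; the node-based
  variant (fraction of present nodes touched by a co-exclusion edge) is
  implemented behind `basis = "nodes"`.

Graphs with no edges (or no triples) yield `NA`, never 0: an undefined metric
must not masquerade as "no structure".

The null model is a plain Bernoulli SBM fitted once on the metaweb:
`p_kl` = observed edges between blocks k and l over possible pairs, per layer
independently (so the null co-exclusion proportion is defined). Each null
draw builds a *fresh* synthetic network with the observed per-module node
counts of the sample — matching node counts, not node identities. Fitting
once on the metaweb (rather than refitting per timepoint) reflects the view
that the metaweb is the regional pool and samples are draws from it.
Undefined null draws are excluded from the null mean/sd rather than imputed;
`z = (obs - mean)/sd` is `NA` whenever the observed value is undefined or the
null sd is 0. By moment-matching, the fitted SBM reproduces per-block edge
counts exactly in expectation, and data generated from the fitted model
itself lands within ±3 null sd essentially always — both are tested.

## Phylogenetic dispersion

ASV environmental optima are abundance-weighted means of the selected
environmental variables (default: temperature and influent BOD/TN/TP; the
set is configurable because the source methods leave it open). Phylogenetic
signal is checked with a Mantel correlogram (Sturges classes, Pearson
statistic, progressive Bonferroni — standard correlogram practice via
`vegan::mantel.correlog`) between Euclidean distances on z-scored optima and
patristic distances.

Weighted MPD and MNTD use per-sample relative abundances:

$$\mathrm{MPD} = \frac{\sum_{i \ne j} f_i f_j d_{ij}}{\sum_{i \ne j} f_i f_j},
\qquad
\mathrm{MNTD} = \sum_i f_i \min_{j \ne i} d_{ij}.$$

Note one convention detail: `picante` keeps self-pairs in the MPD
denominator, so its weighted MPD equals ours times $1 - \sum_i f_i^2$. The
factor is constant across label permutations, so SES, NRI and NTI are
identical under either convention (the test suite pins this).

The null shuffles the distance-matrix labels over the **full analyzed pool**
(all ASVs surviving the occurrence filter, present in a sample or not),
which matches the behavior of `taxa.labels` randomization on a full
community matrix. `SES = (obs - null mean)/null sd`, `NRI = -SES(MPD)`,
`NTI = -SES(MNTD)`; positive values mean phylogenetic clustering (habitat
filtering), negative overdispersion, near zero stochastic assembly. The
default is 999 shuffles; pools of <= 8 taxa support an exact exhaustive null
(`method = "exhaustive"`), which the tests compare against independent
enumeration at 1e-10. NRI/NTI are invariant to rescaling all branch lengths,
since the standardization cancels scale.

## Diversity

Hill numbers `^qD = (sum p_i^q)^{1/(1-q)}` with the entropy limit at
`q = 1` (computed as `exp` of Shannon entropy, not a numerical limit).
The phylogenetic Hill number uses the branch-segment formulation: every
branch carries the summed relative abundance of its descendants, the
abundance-weighted mean depth is `Tbar = sum L_b a_b`, and at `q = 0` the
index reduces to Faith's PD divided by `Tbar` (an effective number of
lineages; a single taxon returns 1 by convention). Diversity is computed on
raw counts normalized to relative abundances — whether the original analyses
rarefied is unstated, and rarefaction is deliberately out of scope.
Bray-Curtis dissimilarity is exported for external ordination; NMDS itself
is out of scope.

## Pollutant links

Removal rate is `100 (in - out)/in` percent; negative values (effluent above
influent) are kept and flagged only by their sign, and non-positive influent
gives `NA`. Node-removal correlations use Spearman's rho on per-sample
*relative* abundances (depths vary, so raw counts would conflate depth with
abundance). P-values: t approximation for `n > 10`; exact enumeration of all
rank permutations for `n <= 7`; seeded Monte-Carlo permutation (10,000
draws) for `8 <= n <= 10` — full enumeration of up to 10! permutations per
node buys nothing at these sizes. Benjamini-Hochberg is applied pooled
across all (node x pollutant) tests by default (per-pollutant behind a
flag), significance at `q <= 0.05`.

## The synthetic generator

The generator produces what a finished amplicon workflow would hand the
analysis — counts, metadata, tree — with the statistical structure the
method assumes, for two scenarios. Defaults state the study conditions:

* **seasonal**: 22 timepoints x 3 replicates, temperature sinusoid spanning
  18.0-27.6 degC (two annual cycles); two planted modules of 60 ASVs.
* **succession**: 23 timepoints x 3 replicates, 11.33-23.50 degC; three
  modules of 30, 30 and 90 ASVs, the third a seeded community that decays.

Shared machinery: a depth-1 pure-birth tree; Brownian niche optima
(`rate = 1`), so optima carry phylogenetic signal at short distances;
lognormal within-module baselines; multinomial counts at depth 5000 per
sample (no overdispersion, keeping the oracles tractable). 15 "rare" ASVs
(one timepoint each) and 15 "ubiquitous" ASVs (constant 0.5% relative
abundance each) exercise the occurrence filter; their shares are held fixed
relative to the rest so they do not drift as module weights change.

Choices that required judgement, made once from detection-limit reasoning
and the biology being emulated (not tuned to test outcomes):

* **Gaussian niche** in temperature, width `sigma = 1.5` degC against a
  ~10-degC seasonal range: at depth 5000 and ~150 ASVs the detection limit
  is ~2e-4 relative abundance, so a taxon drops below detection roughly 4
  degC from its optimum — seasonal turnover in *presence*, which is what the
  pair model sees. Module niche centres sit at the 20%/80% quantiles of the
  range.
* **Modules are clades**: tips are assigned in cladewise order, so module
  membership and phylogeny align, as expected when niches are conserved.
  Within-module optima spread is 1 degC (seasonal).
* **Succession**: the seeded module's weight decays exponentially
  (`rate = 0.35`/timepoint from an initial 6-fold dominance) while the two
  adapted modules rise logistically at staggered midpoints (t = 7 and 15);
  the growth steepness scales with the decay rate so `decay_rate = 0`
  freezes all trends. The seeded module is drawn *scattered across the
  tree* — an exogenous inoculum of mixed phylogenetic origin — and is a
  thermal generalist (`sigma = 6` degC) with even abundances
  (`sdlog = 0.6`), while the rising specialist modules are clades with
  narrow, opposed thermal niches and more uneven, thermally diverse
  memberships (`sdlog = 1.2`, optima spread 2 degC). This is what makes the
  emulated start-up behave like one: diversity falls as the broad seed gives
  way to two specialist clades, per-sample networks grow more modular and
  less transitive, and NTI rises as filtering strengthens. The real
  inoculum's composition is unknown, so this scenario is a stylized
  stand-in, not a calibration.
* **Metadata**: influent concentrations (BOD 400, TN 60, TP 9 mg/L) rise
  25% peak-to-mid with temperature (warm-month loading); removal efficiency
  is constant for the established plant and ramps linearly during start-up
  (e.g. TN 20% to 80%), with 5% lognormal effluent noise. Replicates share
  timepoint-level metadata, as plant-level measurements do.

What the generator does **not** emulate: overdispersed (compound) counts,
sequencing error and chimeras, taxon interactions beyond module membership,
dispersal limitation, or metadata feedbacks. Passing the end-to-end tests
therefore shows the pipeline recovers planted structure of this kind at
realistic sizes — not that real plants satisfy the model.

## Determinism and numerical conventions

Every randomized stage takes a seed and uses it through `withr::with_seed`;
two runs with the same seed write byte-identical tables. Ties in walktrap
are broken by the maximum-modularity cut over a fixed (sorted) vertex
order. Undefined quantities (`0/0` proportions, edgeless modularity, zero
null sd, zero-abundance optima) are `NA` with the reason documented at the
computing function, and are excluded from means rather than imputed.

## Problem sizes used in the shipped checks

Unit and acceptance tests run the generator at its default sizes (150-180
ASVs, 66-69 samples). The null-model and dispersion checks use 999-1000
iterations where the check is about calibration, and 99-199 where only a
trend sign is needed; the 20-seed end-to-end recovery checks use 99
dispersion shuffles per seed. `scripts/acceptance.R` runs both scenarios
once at the given seed with 200 SBM iterations and 199 dispersion shuffles.

## Known limitations

* The hypergeometric model treats samples as exchangeable; strong temporal
  autocorrelation inflates co-occurrence among taxa with smooth trends. That
  is a property of the method being reimplemented, not a bug, but worth
  remembering when reading edge counts.
* The SBM null is not degree-corrected; hubs inside modules will appear as
  deviations from it.
* Mantel correlograms inherit the usual caveats of distance-based tests
  (low power, class-boundary sensitivity).
* `NA` metrics in sparse samples propagate into trend estimates as missing
  values; with very shallow depth entire samples can drop out.
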