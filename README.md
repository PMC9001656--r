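# sludgenet

Community-assembly analysis for activated-sludge microbiome time series.

Wastewater treatment plants are microbially driven: the activated sludge in
their bioreactors removes organic load (BOD), nitrogen and phosphorus, and
the community doing the work turns over with season, operation and start-up
history. `sludgenet` asks *how* such communities assemble — deterministic
habitat filtering vs. stochastic drift — from three inputs a 16S amplicon
workflow produces: an ASV-by-sample count table, sample metadata
(temperature, influent/effluent BOD/TN/TP), and a rooted phylogeny of the
ASVs.

## What it computes

- **Metaweb**: after filtering ASVs by occurrence (present in more than one
  but not every timepoint), every ASV pair is classified by the exact
  hypergeometric co-occurrence model. With occupancies `n_a`, `n_b` in `N`
  samples, the shared-sample count is `J ~ Hypergeom`; a pair co-occurs when
  `P(J < j_obs) >= 0.95` and co-excludes when `P(J > j_obs) >= 0.95`. The
  metaweb holds both edge layers over all nodes with at least one
  significant edge.
- **Modules & dynamics**: walktrap modules of the co-occurrence layer;
  per-sample module completeness (fraction of a module's nodes present);
  per-sample induced timepoint networks with modularity (Newman-Girvan Q),
  global transitivity and co-exclusion proportion, each standardized
  against a stochastic-block-model null (`z = (obs - null mean)/null sd`,
  1000 fresh SBM draws matching the sample's per-module node counts).
- **Phylogenetic dispersion**: abundance-weighted MPD/MNTD per sample
  against a taxa-label shuffle null over the full analyzed pool;
  `NRI = -SES(MPD)`, `NTI = -SES(MNTD)` (positive = clustering/filtering,
  negative = overdispersion); ASV environmental optima
  (abundance-weighted means) and Mantel correlograms for phylogenetic
  signal.
- **Diversity**: Hill numbers `^0D`, `^1D`, `^2D`, phylogenetic `^0pD`
  (branch-segment formulation), Bray-Curtis dissimilarities.
- **Pollutant links**: removal rates `100 (in - out)/in`, Spearman
  correlations of node relative abundances with removal, Benjamini-Hochberg
  FDR at 5%, and per-sample summed abundance of correlated nodes.
- **Synthetic scenarios**: a first-class generator that emulates the two
  study designs — seasonal alternation of two modules under a temperature
  sinusoid, and start-up succession where a seeded module decays in favor of
  two rising specialist clades — with planted ground truth, so the whole
  pipeline is testable end to end.

## Worked example

```r
library(sludgenet)
library(dplyr)

sim <- simulate_scenario(scenario_spec("seasonal"), seed = 42)
filtered <- filter_by_occurrence(sim$counts)
occ      <- occurrence_matrix(filtered)
metaweb  <- build_metaweb(occ)
metaweb
#> <metaweb> 120 nodes; 3540 co-occurrence / 3574 co-exclusion edges (N = 66 samples)

modules <- detect_modules(metaweb, seed = 1)
glance(modules)
#> # A tibble: 1 × 3
#>   n_modules n_nodes modularity
#>       <int>   <int>      <dbl>
#> 1         2     120        0.5

module_completeness(modules, occ) |>
  group_by(module) |>
  summarise(rho_temperature = cor(completeness, sim$temperature[timepoint],
                                  method = "spearman"))
#> # A tibble: 2 × 2
#>   module rho_temperature
#>    <int>           <dbl>
#> 1      1           0.934
#> 2      2          -0.859

disp <- ses_dispersion(filtered, cophenetic_distances(sim$tree),
                       n_null = 199, seed = 1)
glance(disp)
#> # A tibble: 1 × 6
#>   n_samples nri_mean nri_sd nti_mean nti_sd n_null
#>       <int>    <dbl>  <dbl>    <dbl>  <dbl>  <dbl>
#> 1        66     3.68   1.02     1.49  0.844    199
```

Read: the pipeline recovers exactly the two planted communities
(modularity 0.5 — two near-disjoint blocks), their completeness tracks
temperature in antiphase (rho +0.93 / -0.86: one community dominates warm
months, the other cold), and mean NRI/NTI well above zero say the per-sample
assemblages are phylogenetically clustered — habitat filtering, as planted,
since module membership follows clades with conserved thermal niches.

`run_pipeline()` chains every stage and writes each result as a TSV plus a
`summary.json`/`manifest.txt` pair (see `?run_pipeline`, `?summarize_run`);
`autoplot()` methods and `plot_module_completeness()` /
`plot_alpha_diversity()` draw the standard time-series figures.

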