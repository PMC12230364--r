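# qdmflora

Floristic regionalization and corridor analysis for networks of nature
reserves, built around the seed-plant flora of the Qinling–Daba Mountains
(QDM), the east–west ranges that bridge the warm-temperate and subtropical
zones of central China. The package is written for biogeographers and
conservation planners who hold long-format plant occurrence records for a set
of protected areas and want to answer three questions:

1. **Which reserves form coherent floristic regions?** Reserve pairs are
   compared at three levels with the coefficients conventional for each —
   species incidence by the Sørensen coefficient `2a / (2a + b + c)`, genus
   incidence by the Szymkiewicz–Simpson overlap `a / min(|A|, |B|)`, and
   areal-type (phytogeographic element) incidence by the Jaccard coefficient
   `a / (a + b + c)`. Each similarity matrix becomes a distance matrix
   (`d = 1 − s`), is clustered by average-linkage (UPGMA) hierarchical
   clustering at a silhouette-selected number of groups, and the three hard
   clusterings are fused into a co-assignment **consensus matrix** — entry
   (i, j) is the fraction of levels on which reserves i and j co-cluster —
   which is clustered once more to give the final regions.
2. **Where did the Chinese endemic genera come from, and how do they
   disperse?** Each endemic genus carries a geographic-component label
   (Central-East China, Southwest China, North China, Northwest China,
   Qinling, South China, or Uncertain) with an origin center; species-level
   overrides are honoured when congeners have distinct origins. Per-reserve
   component counts are tested for distance decay: Spearman's ρ between
   great-circle distance from the origin center and genus count, with a
   seeded permutation p-value.
3. **Which environmental factors drive the pattern, and do elevation
   differences gate dispersal?** A random-forest classifier of region
   membership yields out-of-bag permutation importance (mean decrease in
   accuracy) per climate/elevation variable; region-wise comparisons are
   gated by a Brown–Forsythe homogeneity test (ANOVA when variances are
   homogeneous, Kruskal–Wallis otherwise) with Benjamini–Hochberg adjustment;
   and all within-/between-region pairwise elevation differences are
   summarised against corridor thresholds (900 m base / 800 m mean / 1000 m
   peak within regions, with the corridor-effect statement emitted when
   within-region differences stay below 1000 m while between-region
   differences exceed it).

A seeded synthetic-data generator (`generate_flora()`) emulates the full data
structure — latent regions with controlled species overlap, nested taxonomy,
areal-type spectra, endemic components decaying from origin centers,
region-structured climate and elevation — so the entire pipeline is testable
without the original database.

## Worked example

Everything below is computed from a synthetic 40-reserve flora; the same
calls accept real `occurrences.csv` / `components.csv` / `reserves.csv`
inputs via `read_occurrences()`, `read_components()`, `read_reserves()`.

```r
library(qdmflora)

ds  <- generate_flora(generator_config(seed = 7))
occ <- filter_cultivated(ds$occurrences)
#> filter_cultivated: removed 372 cultivated species

richness_summary(occ)
#> # A tibble: 1 × 5
#>   n_families n_genera n_species n_endemic_species n_endemic_genera
#> 1        124      490      2181               178               89

dists <- purrr::imap(
  c(species = "sorensen", genus = "szymkiewicz", areal_type = "jaccard"),
  \(coef, level) to_distance(similarity_matrix(to_presence(occ, level), coef))
)
rg <- regionalize(dists, meta = ds$meta)
rg
#> Consensus floristic regionalization
#>   reserves: 40   regions: 5
#>   per-level k: species=5, genus=5, areal_type=5
#>   region sizes: 1:8 2:8 3:8 4:8 5:8
```

All three levels independently support five groups and the consensus
partition splits the 40 reserves into five regions of eight — the planted
structure, recovered exactly (`tidy(rg)` lists the per-reserve labels,
`autoplot(rg)` draws the consensus heatmap). Region 1 is the westernmost.

```r
ann <- assign_components(occ, ds$components)
component_summary(ann)
#> # A tibble: 6 × 3
#>   component          n_genera proportion
#> 1 Central-East China       37      41.6
#> 2 Southwest China          27      30.3
#> 3 North China               9      10.1
#> 4 Northwest China           7       7.87
#> 5 Uncertain                 6       6.74
#> 6 Qinling                   3       3.37

gradient_test(component_counts(ann), ds$meta, "Central-East China",
              c(116, 32), n_perm = 999, seed = 7)
#> # A tibble: 1 × 5
#>   component             rho p_perm n_reserves direction
#> 1 Central-East China -0.921  0.001         40 decay
```

The Central-East China component holds the plurality of endemic genera and
its per-reserve counts fall off sharply with distance from the eastern origin
(ρ = −0.92, permutation p = 0.001): a south-westward distance-decay
gradient.

```r
elevation_report(ds$meta, rg)
#> Elevation-difference report
#>   within-region maxima < 900/800/1000 m (base/mean/peak): TRUE / TRUE / TRUE
#>   corridor effect (within < 1000 m, between >= 1000 m): TRUE
```

Reserves within a region differ by less than 900/800/1000 m in base/mean/peak
elevation while between-region differences exceed 1000 m — the elevation
signature of a dispersal corridor. `importance()` and `region_tests()`
complete the driver analysis, and `run_all(run_config(...))` executes every
stage, writing CSV/GeoJSON/JSON artifacts plus a reproducibility manifest.
A command-line front end with `validate / similarity / regionalize /
components / drivers / simulate / run` subcommands is installed at
`system.file("scripts", "flora_pipeline.R", package = "qdmflora")`.

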