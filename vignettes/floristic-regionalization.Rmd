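---
title: "Consensus floristic regionalization and corridor analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus floristic regionalization and corridor analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdmflora)
```

This vignette is the package's account of its methods: the models and
procedures, the parameters that matter, the choices made where the design was
genuinely open, and what the synthetic-data tests do and do not establish
about real floras.

## Data model

The canonical input is a long-format occurrence table — one row per
(reserve, species) record with genus, family, areal-type code, and
endemic/cultivated flags — plus a reserve metadata table (WGS84 coordinates;
base, mean and peak elevation in metres; climate variables) and a
genus-to-geographic-component table with origin centers. Wide incidence
matrices are always derived (`to_presence()`), never authored: with floras of
thousands of species a long table is the only practical exchange format, and
it matches how reserve inventories are compiled.

Validation enforces that taxonomy is functional (one genus per species, one
family per genus), deduplicates (reserve, species) pairs, and normalizes
whitespace; names are otherwise matched case-sensitively, because synonym
resolution belongs upstream in database curation, not in an analysis package.
Introduced cultivated species are removed before any analysis
(`filter_cultivated()`); a reserve left with no records is treated as a data
defect, not an observation of an empty flora. Reserves present in metadata
but absent from occurrences are dropped with a warning rather than an error,
since metadata tables are often compiled for a superset of the study panel.

The occurrence schema flags endemism per species, while endemic-genus status
is in reality a literature attribution. `richness_summary()` therefore counts
a genus as endemic iff all of its recorded species are endemic — a proxy that
is exact for the synthetic data and for any dataset where the species flags
are derived from genus status.

## Multi-level similarity

Reserve floras are compared as incidence sets at three levels, each with the
coefficient conventional for that grain of comparison:

* species — Sørensen, $2a/(2a+b+c)$: balanced weighting of shared and unique
  species;
* genus — Szymkiewicz–Simpson overlap, $a/\min(|A|,|B|)$: a poor flora nested
  in a rich one scores 1, so richness gradients do not masquerade as
  compositional turnover;
* areal type — Jaccard, $a/(a+b+c)$ over the closed vocabulary of
  distribution-type codes.

Whether areal-type similarity should be computed over the type codes
themselves (sets of ≤ 15 elements) or over genera tagged by type is a real
ambiguity; the package computes it over the codes, which is the direct
reading of "areal-type similarity", and the level argument of
`to_presence()` makes the alternative a one-line change.

Distances are $d = 1 - s$. The conversion is not stated more precisely in the
tradition this design follows; $1-s$ is the standard choice for bounded
similarities and preserves rank order, which is all that the downstream
clustering consumes. Note that $1-$Szymkiewicz can violate the triangle
inequality, so nothing downstream may assume metricity — this is why the
clustering uses average linkage rather than, say, Ward, which presumes
squared-Euclidean geometry.

Empty-set arguments to the coefficients are domain errors rather than being
defined as zero similarity, for the same reason empty reserves are rejected
at construction.

## Consensus regionalization

Each level's distance matrix is clustered by agglomerative average-linkage
(UPGMA) — robust to the non-metric genus-level distances and the norm in
floristic classification — at its own silhouette-selected number of groups.
The three hard labelings are fused into a co-assignment consensus matrix:
entry $(i,j)$ is the fraction of levels on which $i$ and $j$ share a cluster,
so with three views entries lie in $\{0, \tfrac13, \tfrac23, 1\}$. The
consensus distance $1 - C$ is clustered once more, again at a
silhouette-selected $k$, to give the final regions. All levels carry equal
weight; no weighting scheme is asserted because none is established for this
use.

Design notes:

* **Choice of k.** $k$ maximizes the mean silhouette width over
  $k \in [2, 10]$, ties to the smaller $k$. Silhouette on the clustered
  distance matrix is self-contained, needs no reference distribution, and
  behaves sensibly on consensus distances. A degenerate matrix (all pairwise
  distances equal) is flagged with a warning and the smallest candidate $k$
  returned.
* **Determinism.** Reserves are ordered lexicographically before clustering,
  so equal-distance merges resolve to the lexicographically first candidate
  pair. This makes the whole pipeline a pure function of the record set —
  invariant to input order, reproducible across platforms.
* **Region numbering.** Final labels are renumbered 1..k by the westernmost
  member longitude when metadata is supplied, giving stable west-to-east
  names; numbering is cosmetic and never affects any statistic.
* **Consensus construction.** Co-assignment fusion of hard labelings is the
  simplest member of the consensus-clustering family; bootstrapped or fuzzy
  consensus are deliberately out of scope. The construction is documented
  here as this package's procedure, not as a claim about any other
  implementation.

## Endemic components and dispersal gradients

Component assignment joins the genus-level table onto endemic records, then
applies species-level overrides — congeners can carry distinct origins (the
motivating case is a genus with one species originating from the Qinling and
others from Sichuan), so overrides always win for their species. Endemic
genera absent from the table are labelled Uncertain; listed genera that occur
in the data without endemic records trigger a warning.

The dataset-wide summary counts distinct (component, genus) pairs with the
total of those pairs as denominator, so proportions always sum to 100% even
when an override splits a genus across components. Per-reserve proportions
use the reserve's own distinct endemic-genus count as denominator; per-region
aggregation can be done either over reserves or over the region's pooled
genera, and the count matrix is returned long precisely so either denominator
can be formed — the package does not assert one as canonical.

"Spread with declining proportion" is operationalized as distance decay: for
a component with origin center $O$, Spearman's $\rho$ between each reserve's
great-circle distance from $O$ (haversine, Earth radius 6371.0088 km) and its
genus count, with a two-sided permutation p-value
$p = (1 + \#\{|\rho^*| \ge |\rho|\})/(B+1)$ from $B$ seeded shuffles of the
counts (default $B = 999$, minimum 199). Direction is `decay`/`increase` only
at $p < 0.05$, otherwise `flat`; constant counts return `flat` with $p = 1$.
Origin centers are always inputs, never estimated — origin attribution is a
literature question. Map export is plain RFC 7946 GeoJSON (points sized by
count plus origin features); no route inference is attempted because
dispersal routes are drawn interpretively, not algorithmically.

## Environmental drivers

**Importance.** A random forest classifies region membership from the
environmental variables; the importance of variable $v$ is the mean, over
`n_repeats` seeded permutations of $v$'s column, of the drop in out-of-bag
accuracy relative to the unpermuted baseline (mean decrease in accuracy,
computed from per-tree OOB votes). Defaults `n_trees = 500`,
`n_repeats = 100`, fixed seed. Negative raw importances are clipped to zero
before normalizing to percentages summing to 100, matching the non-negative
percentage scale on which such results are conventionally reported. Region
membership is the default response because the regions are what the analysis
explains; a richness-regression mode can be had by passing any other label
vector, but is not asserted as canonical. Correlated informative features
share their importance (the familiar masking property — tested explicitly),
so percentages rank drivers rather than partition causal credit.

**Gated group tests.** Per variable, a Brown–Forsythe test (one-way F on
median-centred absolute deviations) at $\alpha = 0.05$ decides between
classical one-way ANOVA (homogeneous variances) and Kruskal–Wallis
(tie-corrected $H$, $\chi^2_{g-1}$ reference). The gate level is a
convention, not a fitted quantity. Raw p-values are Benjamini–Hochberg
adjusted across variables because many variables are tested simultaneously;
constant variables and variables with fewer than two multi-reserve regions
are flagged and excluded from adjustment.

**Elevation report.** All pairwise absolute differences in base, mean and
peak elevation are split into within- and between-region pairs
(within + between = $n(n-1)/2$ per variable). The thresholds — within-region
base < 900 m, mean < 800 m, peak < 1000 m — are report flags describing
empirical regularities, not fitted parameters; a region exceeding the mean
threshold is listed as an exception rather than failing the report, since
high-relief regions are known to exceed it. The corridor-effect statement is
emitted when every within-region maximum is below 1000 m and every
between-region pair reaches 1000 m in each variable.

## The synthetic-data generator

`generate_flora()` produces full datasets with the statistical structure
every stage assumes, from a single seed routed through fixed per-stage
substreams (geography, taxonomy, sampling, components, thinning, climate,
elevation, cultivated) so that adding a stage never perturbs earlier draws.

* **Regions and overlap.** Background species live in disjoint region core
  pools plus one shared pool; each reserve includes each species of its
  region's pool with probability `within_region_overlap` (default 0.7), and
  the shared pool is sized so the expected between-region Sørensen similarity
  equals `between_region_overlap` (default 0.2). At the extremes
  (within = 1, between = 0) within-region similarity is exactly 1 and
  between-region exactly 0.
* **Taxonomy and areal types.** Species nest in genera (5 per genus) and
  families (4 genera per family). Each region's genera draw their areal type
  from a sliding window of the 15-code vocabulary and shared-pool genera from
  the central window, mimicking the geographic turnover of floristic
  elements; without this, rich reserves would hold every code and the
  areal-type level would be uninformative. The last code is reserved for
  endemic-China genera.
* **Endemic components.** 89 endemic genera (two species each) are available
  frame-wide; a genus with origin $O$ survives in a reserve at distance $d$
  with probability $0.7\,e^{-d/L}$, $L$ = `decay_length_km` (default 500 km).
  Components are drawn with weights 41/24/8/6/3/1 over six origin centers at
  the corners and midpoints of the 102–116°E × 29–37°N frame; 6/89 of genera
  stay unlisted (Uncertain).
* **Environment and elevation.** Climate variables (annual precipitation in
  mm; annual, coldest-quarter and warmest-quarter mean temperature in °C;
  current and LGM) are region means plus Gaussian noise, all region effects
  scaled by `env_effect_size` (0 gives a null environment). Elevation bases
  sit at 400 m plus 1500 m per region step with 600 m uniform within-region
  spread; means and peaks add 350–500 m and 250–400 m respectively, so
  within-region differences stay below the 900/800/1000 m flags by
  construction while between-region differences exceed 1000 m.
* **Cultivated species.** Exactly `n_cultivated` (default 372) introduced
  species are planted, each in at least one reserve, so the exclusion step
  has a known ground truth.

What the generator does **not** emulate: spatial autocorrelation within
regions, richness gradients between regions, detection error in inventories,
synonymy noise, phylogenetic structure beyond the genus/family nesting, and
abundance. Passing tests therefore establish that the pipeline recovers the
structure it models — planted partitions, exponential decay, homogeneous
within-region climate — not that real floras satisfy those models.

## Numerical choices and degenerate inputs

* Similarity matrices are computed by logical cross-products, symmetrized by
  averaging with the transpose, diagonal pinned to exactly 1; they agree with
  elementwise pairwise set computation to machine precision.
* Permutation p-values use the $+1$-corrected estimator and are therefore
  never zero and slightly conservative; with 199 permutations the realized
  type-I error at $\alpha = 0.05$ is about 0.045.
* Spearman decay tests on heavily zero-censored counts (very short decay
  scales relative to the frame) lose magnitude because far reserves tie at
  zero; monotonicity of $\rho$ in the decay scale is therefore probed across
  500/2000/100000 km, where censoring is mild.
* All-identical groups give $F$ undefined (flagged) and $H = 0$; all-zero
  median deviations give a Brown–Forsythe statistic of 0 with $p = 1$.
* A forest in which no variable shows positive importance (possible on tiny
  panels with few repeats) warns and reports all-zero percentages instead of
  dividing by zero.

## Problem sizes used by the test suite

The suite exercises the pipeline at the study's native scale — 40 reserves in
5 planted regions, ~2500 species — for single-run checks, and reduced panels
(8–15 reserves, 100–400 species) for combinatorial and property checks.
Simulation-based checks use 100 seeds for partition recovery and gradient
power, 500 simulations for permutation-null calibration, and 20 seeds for
importance ranking; these sizes give Monte-Carlo standard errors comfortably
inside the asserted bounds.

## Known limitations

* Consensus from three views can only take four co-assignment values, so the
  final clustering has limited resolution when levels disagree; more levels
  or soft consensus would refine it.
* Silhouette-based $k$ selection favours compact, balanced groups; strongly
  nested or chained floristic structure may select a coarser $k$ than an
  expert would.
* Importance percentages depend on forest hyperparameters and on feature
  correlation; they are rank evidence, not variance decompositions.
* The corridor thresholds are descriptive flags; the package deliberately
  does not fit a change-point, because the 1000 m figure is a synthesis to be
  tested against independent data, not an estimated parameter.
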