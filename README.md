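# cavenet

Cooccurrence networks and keystone taxa for microbiome count tables.

Subsurface and cave-rock microbiomes — for example the atmospheric
methane-oxidizing bacteria (atmMOB) of karst caves — are routinely profiled
by amplicon sequencing, yielding an OTU/ASV count table, a taxonomy, and
per-sample physicochemistry (pH, ions, CH₄/CO₂). The questions that follow
are standard across the field: how diverse are the communities, which
environmental gradients structure them, which taxa co-occur, and which taxa
occupy topologically central ("keystone") positions? cavenet packages that
entire analysis as tested, seeded, tidyverse-native R functions, for
microbial ecologists who want the workflow reproducible rather than spread
over ad-hoc scripts.

## What it computes

- **Tables**: TSV readers/writers (QIIME-style classic layout), relative
  abundance, without-replacement rarefaction, and the prevalence filter
  (mean relative abundance > 0.1% and occurrence > 20%, both strict and
  configurable).
- **Diversity**: Chao1 `S_obs + F1(F1−1)/(2(F2+1))`, Shannon
  `H = −Σ p_i ln p_i`, Kruskal–Wallis group tests, Bray–Curtis
  `d(u,v) = 1 − 2Σmin(u_i,v_i)/(Σu_i+Σv_i)`, PCoA (classical scaling,
  explained variance over positive eigenvalues), UPGMA with half-distance
  merge heights and newick export.
- **Environment**: Mantel permutation tests (Spearman, one-sided,
  `p = (#{r* ≥ r}+1)/(n_perm+1)`, 9,999 permutations by default) against
  z-scored Euclidean environmental distances; correlation screens with the
  `*` / `**` / `***` star convention.
- **Network**: all-pairs Spearman ρ with t-approximate p and
  Benjamini–Hochberg q; edges where `|ρ| ≥ 0.7` and `q < 0.05` (sign kept as
  an attribute); topology (APL, clustering, diameter, modularity, density
  `2E/N(N−1)`, average degree `2E/N`, weighted degree, sign fractions);
  Louvain modules; Gephi edge-list CSV and GraphML export.
- **Roles**: within-module connectivity `Zi`, participation coefficient
  `Pi = 1 − Σ_s (k_is/k_i)²`, the four-way role scheme (peripheral ≤ 2.5 /
  ≤ 0.62; connector, module hub, network hub above), keystone summaries and
  keystone subnetworks, Zi–Pi scatter plots.
- **Synthetic truth**: a seeded generator of compositional count tables with
  planted modules, connectors, negative associations, and environmental
  gradients, plus recovery metrics (adjusted Rand index, edge
  precision/recall, connector recall), so every stage is testable without
  downloading reads.

## Worked example

```r
library(cavenet)

com <- generate_community(syn_spec(seed = 1))   # 900 features x 36 samples
cfg <- analysis_config(rarefaction_depth = 8000, seed = 1, n_perm = 999)
run <- run_all(cfg, com$counts, com$taxonomy, com$metadata)
run
#> cavenet run: 188 nodes, 1115 edges, 11 modules, Q = 0.857
#> artifacts in /tmp/.../cavenet_run_...

head(run$alpha, 3)
#>   sample_id observed chao1 shannon
#> 1 S01            808  849.    6.10
#> 2 S02            788  846.    6.06
#> 3 S03            817  877.    6.15

run$mantel[run$mantel$variable %in% c("pH", "Cl", "CH4", "CO2"), ]
#>   variable       r p_value n_perm method   stars
#> 1 pH       -0.0628   0.777    999 spearman ""
#> 2 Cl       -0.0247   0.619    999 spearman ""
#> 3 CH4       0.362    0.001    999 spearman "**"
#> 4 CO2       0.315    0.001    999 spearman "**"

truth_metrics(com$truth, partition = run$modules, edges = run$network$edges)
#>   metric           value
#> 1 ari              0.978
#> 2 n_shared       188
#> 3 edge_precision   0.987
#> 4 edge_recall      0.598
```

Reading the output: the generator planted 11 modules and gradients on CH₄
and CO₂ only; the pipeline's Mantel screen flags exactly those two
variables, Louvain recovers the planted partition almost perfectly
(ARI 0.978), and 98.7% of inferred edges are planted associations. The
alpha-diversity table is per rarefied sample; `run$output_dir` holds every
intermediate artifact (filtered table, PCoA coordinates, newick tree, Mantel
TSV, Gephi edge list, GraphML, node roles, run log).

Plots: `autoplot(run$pcoa, colour_by = com$metadata$cave)` for the
ordination and `plot_zipi(run$roles)` for the Zi–Pi role chart.

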