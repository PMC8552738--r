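---
title: "From count tables to keystone taxa: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From count tables to keystone taxa: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavenet)
```

cavenet implements the statistical core of a cave-microbiome community
analysis: it starts from an OTU/ASV count table (features × samples), its
taxonomy, and sample physicochemistry, and ends with a signed cooccurrence
network, its topology, its module structure, and a Zi–Pi classification of
node roles from which keystone taxa are read off. This vignette explains the
models and the design decisions; the README shows the happy path.

## The pipeline and its assumptions

1. **Rarefaction.** Every sample is subsampled without replacement
   (multivariate hypergeometric) to a common depth so that richness and
   dissimilarity comparisons are not confounded by sequencing effort. The
   depth is a required configuration value: it must be chosen at or below the
   smallest sample total, and no universal default exists. Rarefaction is
   random; the seed is mandatory and recorded in the run log.
2. **Prevalence filtering** keeps features whose *mean* relative abundance
   across samples exceeds 0.1% and which are detected in more than 20% of
   samples — the usual complexity-reduction step before correlation
   networks. Both thresholds are strict inequalities and both are
   configurable. The abundance criterion is evaluated on the mean across
   samples (the common convention; a per-sample-maximum reading is also
   defensible but not implemented), and it is applied *after* rarefaction.
3. **Alpha diversity.** Chao1 uses the bias-corrected estimator
   `S_obs + F1(F1−1)/(2(F2+1))`; Shannon uses natural logarithms by default
   (base configurable). Group differences are tested with the tie-corrected
   Kruskal–Wallis H; an all-ties input (every value identical) returns H = 0
   and p = 1 rather than NaN, since no evidence against exchangeability can
   exist in a constant sample.
4. **Beta diversity.** Bray–Curtis dissimilarity, principal coordinates by
   classical scaling, and UPGMA (average-linkage) clustering. Bray–Curtis is
   semimetric, so some PCoA eigenvalues can be negative: those axes are
   dropped and explained-variance percentages are computed over the positive
   eigenvalues only. UPGMA merge heights are reported as *half* the
   between-cluster average distance (molecular-clock convention), so
   leaf-to-leaf path lengths in the exported newick tree equal cophenetic
   distances.
5. **Mantel tests** correlate the community distance matrix with Euclidean
   distances on z-scored environmental variables (z-scoring because pH, ppm
   and mg·kg⁻¹ are incommensurate; the single-variable case reduces to
   absolute differences). The correlation is Spearman by default, the test
   one-sided (greater), with the add-one permutation estimate
   `p = (#{r* ≥ r} + 1)/(n_perm + 1)` and 9,999 permutations by default.
6. **Network construction.** Spearman's rho is computed for every unordered
   feature pair using mid-ranks, with a two-sided p-value from the
   t-approximation `t = ρ√((n−2)/(1−ρ²))` — adequate at n = 36 samples — and
   Benjamini–Hochberg adjustment across all pairs jointly. An edge requires
   `|ρ| ≥ 0.7` and adjusted `q < 0.05`. The strength threshold is applied to
   the absolute value so that strong negative associations are retained as
   negative edges (published cave networks contain a few percent of them);
   thresholding the raw p instead of q is available as an option because the
   published phrasing is ambiguous. Nodes are edge endpoints only; features
   that pass the filter but earn no edge are not graph nodes (consistent with
   published node counts being far below candidate counts).
7. **Topology.** Density `2E/N(N−1)` and average degree `2E/N` are arithmetic
   identities. The average clustering coefficient averages local clustering
   with degree-0/1 nodes contributing 0 (the common implementation choice).
   Average path length and diameter are computed on the unweighted graph over
   connected pairs / finite eccentricities, because threshold graphs may be
   disconnected. Average weighted degree uses |ρ| as the weight, as does
   modularity.
8. **Modules and roles.** Communities come from Louvain greedy modularity
   maximization on the |ρ|-weighted graph, with a fixed seed for
   reproducibility (signed-modularity variants are out of scope). Zi (the
   z-score of a node's within-module degree, relative to its module's mean
   and standard deviation) and Pi (the participation coefficient
   `1 − Σ_s (k_is/k_i)²`) are computed on the *unweighted* graph, following
   the original role-cartography definitions. A module whose within-degree
   variance is zero (including singletons) gives Zi = 0, keeping such nodes
   peripheral unless Pi promotes them. Roles: peripheral (Zi ≤ 2.5, Pi ≤
   0.62), connector (Pi > 0.62), module hub (Zi > 2.5), network hub (both);
   connectors and hubs are keystone taxa. Large modules are those holding
   strictly more than 5% of nodes.

## The synthetic community generator

Real deposited reads require a full upstream read-processing pipeline, so
validation rests on a generator that emulates the *downstream products*:
sparse, overdispersed, compositional count tables with planted structure.

The model: each of the (default 11) modules has a per-sample standard normal
factor. A feature in module *m* has latent log-abundance
`l = μ + σ(±a·f_m + √(1−r)·ε)` with feature-level baseline μ, dispersion σ,
and loading `a = √r` where `r = 2·sin(π·ρ_s/6)` converts the target Spearman
correlation ρ_s (default 0.85) to the Pearson correlation of the underlying
Gaussian. Connector features load with `a/√k` on k (default 3) equal-sized
modules. A configurable fraction of members load negatively (default 0.018,
which makes a few percent of planted associations negative, matching the
published sign fractions' order of magnitude). Counts are drawn per sample by
multinomial sampling of softmax-transformed latents at a uniformly drawn
depth (default 9,000–11,000 reads), which makes the data compositional as
amplicon tables are. Environmental variables are linear in chosen module
factors plus unit noise (defaults: CH4 and CO2 track the dominant module, pH
a second one), then affinely mapped to plausible units, which changes neither
correlations nor standardized distances.

Default scale mirrors the study design the package targets: 36 samples
(3 caves × 2 sites × crust/rock × triplicates), ~900 features of which 200
are correlated across 11 modules, depth ~10⁴. The first module is modestly
larger than the rest; taxonomic dominance of the USCγ label is instead
produced by letting that label span most modules. An earlier design with one
giant module was rejected because a module carrying a large share of total
reads couples all other features through compositional closure (the softmax
denominator) and can fabricate strong negative correlations that were never
planted; with the flatter module-size profile, closure-induced correlations
stay near −0.1, two standard errors of a ρ estimate away from the −0.7 edge
threshold, so an all-positive specification yields an all-positive network up
to rare (≲ 10⁻⁴ per pair) sampling accidents.

What passing tests on this generator do *not* show: robustness to real
amplicon artifacts (chimeras, contamination, batch effects), to strong
compositional coupling from truly dominant taxa, or to non-monotone
taxon–environment relationships. The generator plants monotone, factor-driven
structure by construction, which is exactly the structure Spearman screening
is designed to find.

### The connector-detectability ceiling

A connector that splits one unit of latent variance evenly over k independent
module factors can correlate with members of those modules at most `1/√k`
(a positive-semidefiniteness constraint) — about 0.577 for k = 3, i.e.
*below* the 0.7 edge threshold no matter how strong the within-module signal
is. Planted connectors are therefore structurally invisible to the published
threshold, and the package's recovery checks use two routes: exact
classification on the planted association graph (the infinite-signal limit of
the count pipeline), and count-level recovery with the screen read at a
proportionately lower strength threshold (0.4, raw p < 0.05) under a strong
within-module signal (ρ_s = 0.95). The second route is noisy by nature —
whole per-module correlation blocks fluctuate jointly with the sample
correlation of the module factor — so recovery is asserted only well below
its typical value (~0.6).

## Numerical and testing choices

- Problem sizes in the test suite are chosen for desk-scale runtimes: the
  full 900 × 36 generator where the claim concerns study scale, a 300 × 36
  variant for property sweeps, graphs of ≤ 12 nodes where brute-force oracles
  (Floyd–Warshall paths, triangle-counted clustering, per-module Zi/Pi
  tallies, step-up BH) are exhaustive.
- Mantel null-uniformity is checked with 500 replicates of 99 permutations at
  n = 12 against a Kolmogorov–Smirnov test at α = 0.01; the permutation
  p-value is discrete on a 1/100 grid, which perturbs the KS statistic far
  less than its α = 0.01 critical value at 500 draws.
- Determinism: every stochastic step (rarefaction, permutations, Louvain,
  generation) takes an explicit integer seed; reruns with equal configuration
  are byte-identical in all numeric artifacts.
- Degenerate inputs have defined behavior rather than NaN: all-tied
  Kruskal–Wallis (p = 1), zero-variance screen columns (flagged undefined),
  constant features (excluded from the screen and reported), zero-variance
  modules (Zi = 0), all-zero samples (explicit errors naming the sample).

## Known limitations

- Plain Spearman correlation on compositional data is the published method,
  not the state of the art; SparCC/SPIEC-EASI-style compositional corrections
  are deliberately out of scope.
- Published real-data topology (APL 3.32, ACC 0.62, 11 modules, and the Fig
  5-style role percentages) depends on the deposited reads plus upstream
  processing and is not reproducible from this package alone; only the
  arithmetic identities of the topology table (average degree, density) are
  checked exactly.
- Negative Mantel statistics reported in some published tables cannot arise
  as "significant" under the one-sided greater convention implemented here;
  the implementation reports signed r with a one-sided p and leaves the
  published sidedness convention as unknown.
- Zi/Pi use unweighted degrees; weighted role cartography is not implemented.
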