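---
title: "Methods: holobiont community assembly analysis with holocomm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: holobiont community assembly analysis with holocomm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holocomm)
```

# Scope and model

holocomm asks a single scientific question of a coral holobiont dataset: how
much of the variation in the symbiont (ITS2) and microbial (16S) community is
attributable to the host's genetic cluster, to the reef site, and to the
colony size class? The package implements the full chain needed to answer it —
host genetics, community matrix processing, distance-based statistics, and
forest-based variable importance — together with a synthetic-data generator
that plants known effects so every stage can be verified without external
sequencing data.

# Host genetics

**IBS distance.** Genetic distance between two individuals is the expected
mismatch probability when one allele is sampled from each: at a biallelic
site with dosages $g_i, g_j \in \{0,1,2\}$, writing $p = g_i/2$, $q = g_j/2$,
the site term is $p(1-q) + (1-p)q$, averaged over jointly typed sites.
This is the analytic expectation of the single-read-resampling IBS measure
used with low-coverage RAD genotyping; we compute the expectation rather
than resampling reads, since read-level data are upstream of this package.
A Monte-Carlo resampling oracle in the test suite confirms the closed form.

**Clone pruning and cluster assignment** both use average-linkage
hierarchical clustering of the IBS matrix — the method is not prescribed
beyond "hierarchical clustering", and average linkage matches the UPGMA
convention used elsewhere in the pipeline. Clone groups are formed by
cutting at `clone_threshold`; within a group, the sample with the highest
call rate survives (ties: smallest id). When no threshold is supplied,
`prune_clones()` uses the midpoint of the largest gap in the sorted pairwise
distances — a heuristic that assumes clones are actually present, producing
a clear bimodal gap. The `run_all()` pipeline instead defaults to 0 (exact
genotype duplicates only) because its simulated world contains no clones,
and the largest gap there separates within- from between-cluster distances,
which would collapse whole clusters.

**FST.** Pairwise differentiation between clusters uses the two-population
Weir–Cockerham (1984) variance-components estimator, combined across loci as
a ratio of sums ($\sum_\ell a_\ell / \sum_\ell (a_\ell+b_\ell+c_\ell)$, the
"weighted" multi-locus form). Monomorphic loci are skipped; a negative
multi-locus total is clamped to 0 and flagged. An SFS-based estimator on
genotype likelihoods is out of scope, so this estimator is the documented
desk-scale analog.

**UPGMA.** Implemented from scratch (size-weighted arithmetic-mean linkage,
merged cluster keeps the first member's position, deterministic tie-break by
scan order) and emitted as newick with branch lengths
$h_{\text{merge}}/2 - h_{\text{child}}$. The tree is ultrametric by
construction; tests compare merge heights and cophenetic distances against
`hclust(..., "average")` as an independent oracle.

# Community processing

The fixed order is: ASV grouping (ITS2 only) → replicate aggregation →
ASV filters → colony filters → restriction to genotyped colonies →
Hellinger → Bray–Curtis. Thresholds live in `filter_config()`:

| parameter | default | semantics |
|---|---|---|
| `min_colonies_per_asv` | 3 | inclusive (present in ≥ 3 rows) |
| `min_reads_per_asv` | 100 | strict (> 100 total reads) |
| `min_reads_per_colony` | 1000 | strict |
| `min_nonzero_asvs_per_colony` | 3 | strict |
| `correlation_threshold` | 0.8 | strict, phi of presence vectors |

The source wording for the prevalence rule differs between the two
communities ("at least three colonies" vs "> 3 colonies"); we default both
to the inclusive reading and expose the threshold, so either convention is
one argument away. Presence means count > 0; no minimum-count presence
definition is imposed.

**ASV grouping** addresses intragenomic variation in Symbiodiniaceae ITS2
copies: ASVs whose presence/absence vectors correlate above 0.8 (Pearson on
0/1 vectors, the phi coefficient) are merged transitively (graph connected
components), because a chain of pairwise-correlated variants should become a
single unit. Zero-variance presence vectors (all-present or all-absent)
have undefined correlations; they merge only with identical vectors, never
through a correlation edge. Group counts are member sums; the group id is
the lexicographically smallest member. Whether grouping precedes or follows
replicate aggregation is ambiguous in the source; we group at sample level
(more samples, better-estimated correlations) and verify on synthetic
variant sets that the planted groups are recovered either way.

**Hellinger / Bray–Curtis.** $\sqrt{x_{ij}/x_{i\cdot}}$ followed by
$d(x,y) = \sum_k |x_k - y_k| / \sum_k (x_k + y_k)$, both implemented directly
and tested against vegan and a brute-force double loop.

# Distance statistics

**PCoA** is classical metric scaling: eigendecomposition of
$B = -\tfrac12 J D^{(2)} J$. Axes with eigenvalue $> 10^{-10}$ are kept and
scaled by $\sqrt{\lambda_k}$; negative eigenvalues are reported unmodified
(no Lingoes/Cailliez correction), and only positive axes feed the forest.

**PERMANOVA with marginal terms.** With $G$ the Gower-centered matrix and
$H$ the hat matrix of the full design (treatment-coded, pseudo-inverse via
SVD for rank-deficient designs), the marginal SS of term $t$ is
$\mathrm{tr}(GH_{\text{full}}) - \mathrm{tr}(GH_{-t})$ with df equal to the
rank drop; the pseudo-F uses the full-model residual. p-values permute raw
sample labels freely (no strata), recomputing every term per permutation,
with the $(1 + \#\{F^\pi \ge F\})/(1+B)$ convention and `>=` tie handling
(conservative). For $n \le 8$ an exhaustive mode enumerates all $n!$
permutations. Tests verify exact agreement of SS/F/R² with vegan's
`adonis2(by = "margin")` and with a closed-form single-factor oracle; a
1000-replicate null simulation keeps the empirical type-I rate in [3%, 7%]
at nominal 5%. Confounded terms surface as df 0 with NA F rather than an
error, matching how practitioners encounter aliased designs.

**Dispersion test.** A betadisper-style check: distances to group centroids
in the positive-axis PCoA embedding, a one-way F across groups, and a label
permutation null. Negative-eigenvalue axes are excluded by design — the
"negative contribution" convention can produce imaginary distances, and the
positive-axis embedding is sufficient for the replicate-variance claim this
test supports.

# RDA-forest importance

The forest stage regresses each of the first `n_axes` (default 15) PCoA
axes on the full one-hot predictor matrix (no reference level dropped, one
column per level) using an in-package CART random forest (Rcpp): 1500
bootstrapped trees, `mtry = p/3`, minimum node size 5 — the conventional
regression defaults, since none are stated in the source. Axis $k$
contributes weight $w_k = R^2_{k,\text{OOB}} \times
\lambda_k / \sum_{j \le m} \lambda_j$ (negative OOB R² floored at zero);
per-column OOB permutation importances (negatives floored) are normalised
to sum 1 within an axis, combined with the $w_k$, summed across a
predictor's dummy columns, and reported as shares of the total. The
original gradient-forest weighting is not fully specified publicly, so this
contract is a documented analog: only orderings and share arithmetic are
claimed, never numerical equality with the original package.

`compute_max_level()` implements $\lfloor \log_2(0.368\,n/2) \rfloor$, and
`conditional_importance = TRUE` stratifies OOB permutations within joint
levels of up to `max_level` predictors correlated $> 0.5$ with the permuted
column — a simplified extendedForest-style conditioning, off by default and
flagged experimental.

One measured caveat: a predictor's *share* is only stable under irrelevant
augmentation when `mtry` is held fixed; the default `p/3` changes when
columns are added, which alone can move a small share by ~20% relative. The
stability property is therefore tested at fixed `mtry`, and noise predictors
themselves always earn near-zero share.

# Synthetic data: the stated world

`sim_config()` defaults describe the emulated study: 5 host clusters, 4
sites, 2 size classes; 3 replicate samples per large colony, 1 per small;
Balding–Nichols genotypes at F = 0.25 (inside the published 0.19–0.38 FST
range); per-ASV log-scale effects of cluster/site/size drawn N(0, 2),
N(0, 0.5), N(0, 0.2) — the planted ordering cluster ≫ site > size that the
real analysis recovered; Dirichlet-multinomial counts (the standard
overdispersed microbiome count model; concentration 200) with log-normal
library sizes (median 20 000 reads, log-sd 0.4, typical MiSeq depth);
and 3 intragenomic-variant ASV sets whose members share the parent's
presence exactly (counts `ceiling(parent × U(0.2, 1))`, so the coupling
survives integer rounding). `replicate_noise_sd = 0.2` is a free parameter
(no published within-colony variance); 0.2 keeps replicate noise well below
the cluster effect, which is what the replicate-dispersion claim assumes.
`n_individuals = 60` and `n_snps = 1000` keep default runs fast while
leaving cluster recovery unambiguous; tests that need asymptotics raise
them explicitly.

Base ASV counts sum exactly to the drawn library size; the appended variant
columns sit on top of that total (they model additional sequenced copies of
the same organism), so count conservation is defined — and tested — over
the base columns.

What a green test does **not** establish: the generator has no sequencing
error, chimeras, spatial autocorrelation, compositional zeros beyond the
multinomial, or phylogenetic structure among ASVs; effects are additive on
the log scale by construction. Recovery results say the pipeline detects
the structure it is pointed at, not that real reef data are this clean.

# Determinism and seeds

Every stochastic operation takes its stream from one integer seed through a
documented offset map (genotypes 0, metadata 1, community 2, BLAST 3,
PERMANOVA 4, forest 5+axis, dispersion 6); `with_seed()` restores the
caller's RNG state. The C++ forest uses its own mt19937 seeded per tree, so
results are identical across platforms and independent of R's RNG. Two
`run_all()` invocations with the same config produce byte-identical output
files.

# Known limitations

- `assign_clusters()` is a hierarchical-clustering stand-in for model-based
  admixture inference; k is user-supplied, not selected.
- The consensus-taxonomy boundary is strict (`> 0.90`), following the
  wording "over 90%"; an inclusive flag exists.
- PERMANOVA supports free permutations only; restricted/strata designs are
  out of scope.
- The forest importance is an analog of the gradient-forest weighting, not
  a reimplementation of it.
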