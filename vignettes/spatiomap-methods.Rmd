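---
title: "Mapping single-cell types onto spatial transcriptomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping single-cell types onto spatial transcriptomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Microarray-based spatial transcriptomics (ST) measures whole-transcriptome
expression at barcoded spots laid out on a tissue section, but each spot
covers several cells, so spot profiles are mixtures. Single-cell RNA-seq
(scRNA-seq) of the same tissue resolves cell types but loses their
locations. `spatiomap` integrates the two modalities for a developing-organ
setting with annotated anatomical compartments (here called cortex, medulla
and pelvis, after the developing kidney): it labels spatial clusters with
cell types, estimates per-spot cell-type proportions, and runs the
downstream module, crosstalk and enrichment analyses on the mapped data.

Because public repositories typically carry the single-cell reference but
not the matching ST sections, the package ships a synthetic paired-data
generator with known ground truth; every statistical claim the test suite
makes is a claim about recovery of that ground truth.

# The statistics

## Multimodal intersection analysis (MIA)

The core statistic is a one-sided hypergeometric test on the overlap of two
gene sets inside a shared background of `N` genes: a cell-type-specific set
(size `K`, from one-vs-rest differential expression in the scRNA-seq
reference) and a region-specific set (size `n`, from the same caller run on
ST clusters). With overlap `k`,

    P = P(X >= k),  X ~ Hypergeometric(N, K, n),

computed in log space (`phyper(..., log.p = TRUE)`) so that P-values far
below `1e-300` remain representable; tables report `-log10 P` capped at
300. The background is the set of genes detected (count > 0 in at least one
observation) in *both* modalities — the most common reading of a shared
"background genes" universe, and the rule is reported with every MIA matrix
so users can audit it. Each ST cluster is assigned the cell type with the
smallest P in its column provided P < 0.01; ties break toward the larger
overlap, then the lexicographically smaller name. Only the enrichment tail
is computed; a depletion branch would be a straightforward extension but is
not part of the analysis reproduced here.

## Marker detection

One-vs-rest marker calling mirrors the conventional single-cell workflow:
genes are pre-filtered to those detected in at least `min.pct = 0.01` of
either side with `|log2 FC| >= 0.1`, where the fold change is computed on
de-logged means with a pseudocount of 1. Two tests are available:

* **Wilcoxon rank-sum** (default for the reference side). For groups both
  smaller than 50 the `stats::wilcox.test` exact method applies; larger
  problems use a vectorized normal approximation with tie and continuity
  correction that reproduces `wilcox.test(exact = FALSE)` to machine
  precision (asserted bitwise in the tests).
* **Bimodal likelihood-ratio test** (default for the ST side). Expression
  in each group is modelled as detection with probability pi plus a
  conditional Normal(mu, sigma^2) for detected values, sigma pooled across
  groups; the null shares pi and mu. The statistic `2(LL_alt - LL_null)` is
  referred to chi-square with 2 degrees of freedom (pi and mu free between
  groups). sigma is the maximum-likelihood estimate under each model. If a
  group has no detected values the Gaussian component is dropped and a
  binomial-only LRT (df = 1) is reported, flagged in the output.

Benjamini–Hochberg adjustment is applied within each cluster's tested-gene
universe (i.e. after the pre-filter), which is the denominator convention
of the standard one-vs-rest tools; this matters for reproducing adjusted
P-values and is therefore stated here. Marker *sets* are then the strictly
up-regulated genes passing `p_adj < 0.05` and `log2 FC > 0.25`; both
inequalities are strict, so boundary genes are excluded.

## Spot deconvolution and region fractions

Cell-type signatures are the mean normalized expression of the union of all
marker sets, one column per reference type. Each spot's profile on those
genes is decomposed by non-negative least squares (`pracma::lsqnonneg`);
the coefficients are normalized to proportions. Entries below a 10%
contribution are zeroed and the survivors renormalized to sum to one —
renormalization is the default because per-spot composition displays show
full disks, but `renormalize = FALSE` keeps the truncated raw values, and
the unfiltered proportions are always retained alongside. A seeded-NMF
refinement was considered and not implemented: every downstream quantity
(the >= 10% filter, the region fractions) depends only on the proportion
vector, and NNLS on marker genes recovers noiseless mixtures exactly and
NB-noisy synthetic mixtures to MAE ~ 0.04.

Region fractions divide, for each cell type, the summed (filtered)
proportions inside each region by the sum over all spots, so each type's
row is a distribution over regions. Spots with an "unassigned" region are
excluded with a warning; types with zero total proportion give NA rows.

## Co-expression modules

The network stage follows the weighted co-expression recipe: unsigned
adjacency `|cor|^beta`; soft power chosen as the smallest beta whose
scale-free fit reaches R^2 = 0.8 (log10 p(k) regressed on log10 k over ten
equal-width connectivity bins, R^2 signed negative for a positive slope,
the standard sign convention); topological-overlap dissimilarity;
average-linkage hierarchical clustering with a static cut (default height
0.99) and iterative merging of modules whose eigengenes correlate above
0.85; clusters below the minimum size go to module 0. The static cut plus
eigengene merge replaces dynamic tree cutting: it is fully specified by two
numbers and recovers planted modules with ARI ~ 1 in the validation
designs. Module eigengenes are the first principal component of the
gene-standardized module submatrix (unit norm, sign-oriented to correlate
positively with the module mean; equal to the first right-singular vector,
which the tests verify against an independent SVD to 1e-8). Module–region
association is the point-biserial correlation (Pearson against a 0/1
region indicator) with the t-transform P-value on n − 2 df; pairs with
r > 0.4 and P < 0.01 are flagged "strong" (a stricter P < 1e-3 variant is
one argument away). Hub genes are ranked by intramodular connectivity, the
sum of a gene's adjacency weights to the other module members.

## Ligand–receptor crosstalk

For ordered cluster pairs (a, b) and a ligand–receptor pair (L, R), the
matching score is the arithmetic mean of L's mean normalized expression in
the sender a and R's in the receiver b — the convention of the
CellPhoneDB family — gated to zero unless each gene is detected in at
least 10% of its cluster, so single outlier cells cannot drive a score.
Significance comes from global permutation of the cluster labels (sizes
preserved) with the add-one estimator `p = (1 + #{perm >= obs})/(1 +
n_perm)`, whose floor `1/(1 + n_perm)` is asserted in the tests. Direction
matters: (a, b) and (b, a) are distinct rows. Thresholds for the
"significant" flag default to score > 1 and P < 0.01; both the score and
alpha cutoffs are arguments because different displays of this analysis
conventionally use score > 0.5, 1 or 2.

## Gene-set enrichment

`gsea_es` is the weighted Kolmogorov–Smirnov running sum: walking down the
ranked list, hits advance by `|metric|^p / sum_hits |metric|^p`, misses
retreat by `1/(N - |S|)`; ES is the signed maximum deviation, in [−1, 1].
When the positive and negative extrema tie, the positive one is reported;
the tie comparison carries a 1e-9 tolerance because exact rational ties do
occur (e.g. a singleton set) and must not be resolved by floating-point
accumulation order. `gsea` ranks genes by the same log2 fold change used by
the marker caller, so a medulla-versus-rest enrichment is two calls.
Significance uses *gene-set* permutation (random same-size sets), not
phenotype permutation: the spot groups here can be small and unbalanced,
and set permutation keeps the null exact for any group sizes. NES is ES
divided by the mean |permuted ES| of the same sign. Over-representation
analysis (`ora`) reuses the hypergeometric core with BH adjustment across
sets; annotation content (GO/KEGG collections) is supplied by the user as
GMT.

# The synthetic data generator

`sim_config()` defines the study conditions the package is validated
under; `generate_reference()` and `generate_spatial()` realize them. The
defaults describe the regime of the motivating study at desk scale: 15
cell types with 20 disjoint marker genes each at 8-fold elevation, 40
cells per type, 800 genes of which 20 carry the `MT-` prefix, and a
16 x 16 spot lattice split by normalized Chebyshev radius into concentric
pelvis (centre), medulla and cortex rings at radii 0.35 and 0.7 of the
half-width — concentric square rings, a trivially computable stand-in for
an annular anatomical annotation.

Counts are negative binomial in the mean/size parameterization
(`variance = mean + mean^2/size`, size = `nb_dispersion`, default 2,
baseline mean 0.5 per gene per cell). Each cell type is native to one
region (round-robin). A spot's intended composition is drawn from a
region-specific Dirichlet in which native types carry the full
concentration parameter and non-native types 2% of it; that ratio makes
each type's summed proportion concentrate in its home region (fraction
> 0.5) even though the pelvis ring holds only ~36 of 256 spots.
`cells_per_spot` (default 10) cells are then drawn multinomially and their
NB expression summed (using the NB additivity in the size parameter). The
ground truth records the *realized* sampled cell fractions per spot — the
actual composition of the spot — with the Dirichlet weights kept
alongside. Every 20th spot has its mitochondrial means multiplied by 25 so
the 10% QC threshold is genuinely exercised; both knobs are config fields.

Each generator call seeds R's RNG once from `config$seed`
(`generate_spatial` uses `seed + 1`), so repeated calls are bit-identical
regardless of ambient RNG state.

What the generator does *not* emulate: spatial autocorrelation beyond the
region blocks, doublets, batch effects, gene–gene correlation within a
cell type, or ambient RNA. Passing tests therefore demonstrate that the
statistics recover planted composition, marker, module and communication
structure under NB noise — not that they are robust to every artifact of
real Visium data.

# Numerical and design choices

* **Normalization** is log-CP10K with pseudocount 1 (natural log). The
  variance-stabilizing transform used by some upstream pipelines is
  deliberately not reproduced: every downstream statistic here is
  threshold- or rank-based and robust to the normalization family.
* **QC inequalities are strict** for discarding — more than 10%
  mitochondrial fraction, fewer than 200 detected genes — so observations
  sitting exactly on a boundary are retained. Mitochondrial genes are
  recognized by a configurable name regex (default `^MT-`).
* **Variable-gene ranking** uses the raw variance-to-mean ratio of
  de-logged values rather than a mean-binned z-score. With planted
  cell-type markers, the genes of interest occupy the top mean bins
  together, and standardizing dispersion within those bins cancels the
  very signal the screen must find (recovery fell from 1.0 to ~0.3 in
  both equal-width and equal-frequency binning). The unbinned ratio keeps
  the screen monotone in overdispersion; its known bias toward high-mean
  genes is acceptable because the pipeline's feature selection is
  optional.
* **PCA** standardizes genes, fixes each component's sign so its
  largest-magnitude loading is positive, and reports variance explained;
  clustering builds a k-nearest-neighbour graph (k = 20 by default, the
  upstream tools' convention; the source study does not state k), weights
  edges by neighbourhood Jaccard overlap (self included, pruned below
  1/15) and runs Louvain at resolution 0.9 under a fixed seed. On the
  default reference simulation this recovers exactly 15 clusters at
  ARI ~ 1.
* **Pipeline-level network defaults** differ from the operation defaults
  in two places, both because the synthetic spot data are noisier than
  the planted-module designs: candidate soft powers are capped at 6 (the
  scale-free criterion alone picks beta ~ 10 there, which collapses the
  TOM toward uniform dissimilarity), the static cut is 0.995, and the
  minimum module size is 15 because the planted cell-type programs have
  20 genes. The operation defaults (cut 0.99, min size 30) remain the
  documented general-purpose values.
* **Problem sizes.** The validation designs are sized for a laptop-class
  single core: 10-seed sweeps of the full 15-type scenario for MIA, 50
  null seeds for marker-test calibration, 20 randomized-label runs for
  crosstalk calibration, 200 random instances for the ES oracle, and a
  complete enumeration of all hypergeometric configurations with
  N <= 12. The acceptance script (`scripts/acceptance.R`) regenerates all
  of them from scratch from a single command-line seed.

# Known limitations

* Cluster-level MIA only; spot-level label transfer is out of scope.
* The bimod LRT's chi-square reference is asymptotic; at very small group
  sizes its calibration is approximate (the Wilcoxon branch is exact
  there).
* NNLS proportions are non-identifiable when two reference types have
  near-collinear signatures; the signature builder warns on
  ill-conditioning rather than regularizing.
* The static-cut module detector can fragment or under-split when
  adjacency values are uniformly tiny; inspect the scale-free fit table
  and the cut height together when applying it to new data.
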