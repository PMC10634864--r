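---
title: "Brainstem-cortex functional connectomics with stemfc: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brainstem-cortex functional connectomics with stemfc: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`stemfc` implements an analysis pipeline for simultaneous brainstem-cortex
resting-state fMRI at the parcel level: a 400-region cortical parcellation
plus 58 brainstem nuclei (458 nodes). It begins after preprocessing — the
inputs are node × time matrices, a node metadata table, and per-node
annotation maps — and covers: functional connectome construction and quality
control, weighted-degree hub mapping, residualised connectivity-profile
similarity, community detection on signed similarity matrices, diffusion-map
gradients, dominance analysis of receptor predictors, and rotation-based
spatial null models. A synthetic generator with planted structure provides a
fully known test surface for every stage.

# The functional connectome

Functional connectivity (FC) is the Pearson correlation between two nodes'
time-series (`compute_fc`); the group connectome is the element-wise mean of
subject matrices (`group_average`). We deliberately average raw r values
without a Fisher transform: the group connectome is defined as the mean of
subject connectomes, and averaging z-transformed values would change every
downstream number. All sample statistics use n−1 denominators; Spearman
correlations use average ranks for ties.

Quality control follows the field's standard checks:

* **tSNR** (`compute_tsnr`): time-series mean divided by its standard
  deviation, computed on series with the mean retained; `size_association`
  verifies (Spearman) that small brainstem nuclei are not simply noisier.
* **Distance dependence** (`fc_distance_profile`): FC against Euclidean
  centroid distance, separately for within-cortex, within-brainstem and
  cortex-brainstem pairs. Whether to use Pearson or rank correlation here is
  a free choice; both are exposed and Pearson is the default.
* **Block comparison** (`compare_fc_blocks`): Welch's unequal-variance
  two-sided t-test of cortex-brainstem versus within-brainstem FC values.
  The degenerate case of two identical constant blocks returns t = 0, p = 1
  rather than an error.
* **Split-half reliability** (`split_half_reliability`): subjects are
  repeatedly split into two disjoint halves (the design assumes an even
  sample, e.g. 20 → 10/10, 100 repetitions) and group connectomes, and both
  directed weighted-degree profiles, are correlated between halves.

p-values are floored at 1e−300; an exact zero is never reported.

# Hubs and annotation maps

Weighted degree (`weighted_degree`) is the sum of a node's signed FC over a
seed set — brainstem-to-cortex degree sums a nucleus' FC across all cortical
regions, and conversely. FC is summed as-is: no thresholding and no absolute
value, so anticorrelations reduce hub strength. Degree maps are compared
with annotation maps (MEG band power, receptor densities, meta-analytic term
maps) by `correlate_with_map`, with either parametric or spin p-values, and
Benjamini–Hochberg FDR as the default multiple-comparisons procedure across
a batch (the procedure for small map batteries is not canonical; it is
exposed as an option). `decode_terms` ranks term maps by correlation and
flags the top decile (ceiling rule; boundary ties broken by term name so the
flagged set is deterministic). `class_bin_anova` is a standard one-way
fixed-effects ANOVA of a degree map across laminar or cytoarchitectonic
classes.

# Residualised similarity

Both cortical regions and brainstem nuclei are connected with the brainstem
along one dominant pattern — the brainstem weighted-degree map
(`degree_pattern_agreement` quantifies this). To see structure beyond it,
`residualize_profiles` regresses that fixed degree vector (with intercept,
ordinary least squares) out of every node's brainstem-connectivity profile.
The intercept matters: residuals differ without it, and "regressing a map
out" conventionally includes one. The same fixed regressor, computed from
the group FC, is used for every profile. `profile_similarity` then builds
Spearman correlation matrices: brainstem × brainstem (how similarly two
nuclei connect with the cortex, using the 400-length residual columns) and
cortex × cortex (how similarly two regions connect with the brainstem, using
the 58-length residual rows). The 58 × 58 brainstem-profile residual block
is computed for completeness but no downstream analysis consumes it.

# Signed-modularity communities

The brainstem similarity matrix is signed, so community detection uses the
asymmetric signed quality function: with \(W = W^+ - W^-\),
\(s_i^\pm = \sum_j w_{ij}^\pm\), \(v^\pm = \sum_{ij} w_{ij}^\pm\) and null
\(p_{ij}^\pm = s_i^\pm s_j^\pm / v^\pm\),

\[
Q(\gamma) = \frac{1}{v^+} \sum_{ij} (w_{ij}^+ - \gamma p_{ij}^+)\,
\delta(\sigma_i, \sigma_j)
 - \frac{1}{v^+ + v^-} \sum_{ij} (w_{ij}^- - \gamma p_{ij}^-)\,
\delta(\sigma_i, \sigma_j).
\]

Positive weights are rewarded within communities at full strength while
negative weights are penalised with the smaller prefactor — the standard
asymmetric signed modularity. On an all-positive graph the expression
reduces exactly to Newman–Girvan modularity at resolution \(\gamma\) (this
is verified against an independent implementation in the tests). The weight
diagonal is zeroed; the partition-independent diagonal null terms are kept.

`louvain_signed` maximises Q by the greedy two-phase Louvain procedure on
the generalised modularity matrix. Numerical choices: node visitation order
is reshuffled from the seed every pass; a node moves only on a strict gain
(> 1e−12), otherwise it keeps its community, which prevents tie-induced
cycling; the returned quality is re-evaluated exactly from the labels.

`consensus_partition` repeats Louvain (default 250 runs), forms the
co-assignment (agreement) matrix, thresholds it at the mean agreement of a
label-permutation null (100 permutations), and re-clusters the thresholded
agreement matrix as a positive graph at \(\gamma = 1\) until all runs agree.
Stability is summarised by the mean and variance of the pairwise z-Rand
score across runs, where z-Rand standardises the count of co-assigned pairs
by its exact mean and variance under the hypergeometric (fixed group sizes)
model. `gamma_sweep` tabulates community count and stability over the
resolution grid 0.1–6.0 in steps of 0.1 (60 values); stable scales have a
high z-Rand mean and low variance. Which statistic thresholds the agreement
null, and whether re-clustering uses weighted or binary agreement, are
genuinely open choices; we use the null's mean and keep the weighted
agreement, and both are deterministic given the seed.

# Gradients

`diffusion_embedding` follows the field-standard recipe for connectivity
gradients: per-row sparsification keeping the strongest 10% of entries
(`sparsity = 0.9`), cosine-similarity affinity between sparsified rows
clamped at zero, anisotropic normalisation with \(\alpha = 0.5\), and
eigendecomposition of the resulting Markov operator via its symmetric
conjugate. Scores are the non-trivial eigenvectors (normalised so the
trivial eigenvector is constant) scaled by their eigenvalues. None of these
hyperparameters are canonical; all are exposed and recorded in the result
because gradient shape depends on them. Component sign is arbitrary: it is
canonicalised so the node with the largest absolute score is positive, and
`align_and_compare` re-flips against a caller-supplied reference before
reporting correlations. A disconnected affinity graph is an error (with the
component count), not a silent multi-component embedding. `pole_degree`
sums each nucleus' FC with the negatively- and positively-scored cortical
regions separately; exact zero scores are excluded and counted.

# Dominance analysis

`dominance_analysis` decomposes the adjusted R² of the full receptor
regression across predictors. For every one of the \(2^p - 1\) non-empty
submodels, R² is computed from precomputed cross-product (sufficient
statistic) matrices, so the p = 18 case (262,143 submodels) runs in seconds.
Total dominance of a predictor is the level-weighted (Shapley) average of
its incremental adjusted R²: increments are averaged within each submodel
size and then across sizes. With the empty model's value fixed at 0, this
average telescopes, so the dominances sum exactly to the full model's
adjusted R² — the property that makes "percent contribution" well defined.
An unweighted average over all submodels would not satisfy that identity,
which is why the level-weighted form is used. Exactly collinear predictors
are handled by a rank-revealing Cholesky (a redundant predictor adds zero
R², and duplicated predictors receive equal dominance by exchangeability);
p > 18 is refused rather than silently approximated by sampling.

# Spatial null models

Correlations between cortical maps are tested against rotation ("spin")
nulls that preserve spatial autocorrelation. `generate_rotations` draws
uniform random rotations (QR of a Gaussian matrix, sign-corrected into
SO(3)), applies each to the left hemisphere's spherical parcel coordinates
and the x-mirrored conjugate rotation to the right hemisphere, and solves
the one-to-one linear assignment (Hungarian-family solver) minimising total
Euclidean distance between original and rotated parcels. Permutations are
therefore hemisphere-closed bijections. Mirroring the rotation (rather than
drawing an independent one per hemisphere) keeps the two hemispheres' spins
congruent and is the deterministic reading of "each hemisphere separately".
`spin_pvalue` permutes the first map, recomputes the statistic per spin and
reports the add-one estimator \(p = (1 + k)/(1 + n_{\mathrm{spins}})\), which
never returns zero — at 10,000 spins its floor is ~0.0001. Brainstem and
midline nodes are never spun: no spatial null is defined for the brainstem,
so brainstem-side statistics use parametric p-values only. Note that on
small parcellations a random rotation occasionally induces the identity
permutation, in which case a self-correlation's p-value exceeds the floor
accordingly.

# The synthetic world

`synth_spec`/`sample_timeseries` generate multi-subject time-series from a
zero-mean Gaussian latent-factor model, \(\Sigma = L \Lambda L' + \psi^2 I\):

* a **global factor** with nonnegative per-node loadings (a fixed
  low-discrepancy sequence in [0.6, 1.4)) that plants the dominant
  weighted-degree pattern;
* one **factor per community** (default 5), loading 1 on that community's
  brainstem nuclei and a Gaussian bump (peak 1.0, width 0.1 in gradient
  units) on the cortex, centred at the coupled network's position along the
  planted gradient;
* a **gradient factor** with signed cortical loadings on an even ramp over
  [−1, 1] and a low-amplitude brainstem ramp over [−0.2, 0.2].

Defaults mirror the acquisition design the pipeline targets: 20 subjects,
three concatenated 210-volume runs (630 timepoints) at TR 2.5 s, 400 + 58
nodes, unit noise. Draws are i.i.d. over time, not autoregressive: the
pipeline consumes only correlations, so temporal autocorrelation would add
realism but no testable structure; the effective temporal sample size is
exactly `n_timepoints`. Brainstem parcel sizes are log-uniform in
[10, 1500] voxels so size/tSNR checks are exercisable. The generator does
not emulate hemodynamics, physiological noise, scanner artifacts,
inter-subject variability in the planted structure, or empirical FC effect
sizes — no study reports those at parcel level — so a green recovery test
establishes that the pipeline's inference is correct under its statistical
assumptions, not that those assumptions hold in any particular dataset.

Three design points deserve emphasis because the obvious alternatives fail:

1. **The gradient factor must load on the brainstem too.** Gradient loadings
   on cortical nodes alone never enter the cortex-brainstem covariance, so
   no analysis of cortex-brainstem profiles could recover them. The small
   brainstem ramp is what makes the planted gradient visible to the
   pipeline.
2. **Community cortical couplings are smooth bumps along the gradient, not
   flat network indicators.** Flat indicators make the cortical similarity
   matrix block-diagonal: its sparsified affinity graph disconnects and the
   first gradient degenerates into block contrasts. Smooth, overlapping
   bumps — like real cortical projection maps along the unimodal-transmodal
   hierarchy — give cortical profiles a one-dimensional manifold structure
   whose first diffusion component is the planted gradient, while
   same-community nuclei still share one distinctive cortical pattern.
3. **Networks are gradient-ordered.** Cortical network labels default to
   contiguous quintiles of the gradient, mirroring how intrinsic networks
   order along the cortical hierarchy; this is what lets one synthetic world
   satisfy the community-recovery and gradient-recovery requirements
   simultaneously.

With the frozen defaults, the residualise → similarity → consensus pipeline
recovers the planted 5-community partition (ARI ≥ 0.9 somewhere on the
resolution sweep), the first cortical gradient matches the planted loading
at |Spearman ρ| ≥ 0.95, and brainstem weighted degree matches the planted
global loadings at ρ ≥ 0.9 — these are asserted, across seeds, in the
package's acceptance tests, which also verify the signed quality function
against brute-force enumeration, the dominance decomposition against an
explicit Shapley enumeration, and the spin test's false-positive rate
against its nominal level on independent smoothed surrogate maps.

`make_spatial_maps` produces the surrogate annotation maps for those
calibration checks: white noise smoothed by a Gaussian kernel of the given
scale (mm) on chordal distances over the cortical sphere (radius 100 mm),
z-scored per map.

# Worked example

```{r, eval = FALSE}
library(stemfc)

spec <- synth_spec(seed = 1)
geom <- make_geometry(spec)
ts   <- sample_timeseries(spec, geom)
fc   <- group_average(lapply(ts, compute_fc))

res  <- residualize_profiles(fc, geom$nodes)
simB <- profile_similarity(res, "brainstem")
cons <- consensus_partition(simB, gamma = 2, n_reps = 250, seed = 2)
adjusted_rand_index(cons$partition, spec$community_labels)

simC <- profile_similarity(res, "cortex")
emb  <- diffusion_embedding(simC)
align_and_compare(emb, spec$gradient_loading)$r
```

# Known limitations

* The generator's factor amplitudes were chosen for recoverability, not to
  match empirical effect sizes; recovered statistics (e.g. the median
  agreement with the dominant pattern) are weaker than study-scale values.
* Spin nulls assume parcels on a sphere per hemisphere; the synthetic
  geometry is quasi-uniform, whereas real parcellations have irregular
  parcel sizes and shapes.
* Dominance analysis is exhaustive by design and refuses p > 18.
* Louvain is a greedy heuristic; the tests bound its optimality gap on
  small graphs (best-of-seeds reaches the enumerated optimum in ≥ 95% of
  random 7-node graphs) but no guarantee exists at scale.
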