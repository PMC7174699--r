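---
title: "Methods: lesion simulation, strain ranking and concussion prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion simulation, strain ranking and concussion prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question the package addresses

Concussion risk after a head impact is conventionally estimated from the
peak mechanical response of the brain — either head kinematics (peak linear
and angular velocity and acceleration) or the whole-brain 95th-percentile
maximum principal strain (MPS95) predicted by a finite-element (FE) brain
model. Neither view accounts for *where* the deformation lands in the
brain's communication network. `netlesion` implements the complementary
network view: treat the parcellated brain as a weighted structural
connectome, measure each region's importance for network communication by
simulating its removal, and ask whether strain in *network-critical*
regions predicts concussion as well as strain in *high-deformation*
regions.

The pipeline has four stages: (1) network importance by exhaustive node
deletion, (2) strain-based region ranking and group statistics, (3)
logistic-regression concussion prediction under leave-one-out
cross-validation (LOOCV), and (4) a per-subject analysis of how individual
brain architecture moves predictive accuracy. Because the underlying
impact reconstructions and diffusion-imaging connectomes are not public,
the package ships a fully specified synthetic-data generator that emulates
their statistical structure and carries explicit ground truth for
parameter-recovery testing.

# Network model

## Global efficiency

For a weighted connectome with `n` regions, connection weights carry
volume-normalized streamline-count semantics. Weights are converted to
lengths by the connectivity-toolbox convention: after dividing all weights
by the matrix maximum, the length of a direct connection is the reciprocal
of its normalized weight, so the strongest connection has length 1 and all
lengths are at least 1. With `d(i, j)` the shortest-path length,

$$E(G) = \frac{1}{n(n-1)} \sum_{i \neq j} \frac{1}{d(i,j)}, \qquad
  GE(G) = \frac{E(G)}{E(G^{ideal})},$$

where the ideal network has every possible edge at the reference weight,
so all its lengths are 1 and `E(G_ideal) = 1` under this normalization.
Consequences we rely on:

* `GE` is confined to [0, 1] and equals 1 exactly for a uniform complete
  network.
* `GE` is invariant to rescaling all weights by a positive constant (the
  maximum-weight normalization cancels), so streamline-count units do not
  matter.
* Disconnected networks are legal inputs: unreachable pairs contribute
  `1/d = 0`. Lesioned networks are routinely disconnected and must not
  error.

Whether weighted or hop-count (binary) shortest paths are the right
substrate is genuinely open for this analysis family; weighted paths are
the default here because the connectome weights carry real information,
and a `binarize` switch provides the binary variant for sensitivity
checks.

## Lesion simulation and ΔGE

A lesion deletes a set of regions and all their connections (rows and
columns removed). Importance of the deleted set is the normalized drop

$$\Delta GE = \frac{GE_{intact} - GE_{lesioned}}{GE_{intact}},$$

with two deliberate conventions. First, the lesioned network's efficiency
uses its own node count `n - k` in the averaging prefactor: the lesioned
network is the network whose efficiency is being measured. Second, the
*intact* network's maximum weight remains the length-normalization
reference after deletion, so ΔGE measures lost communication rather than
an artifact of renormalizing to a new maximum. ΔGE keeps its sign:
removing a region that drags the average down (an isolated or very weakly
connected region) yields a negative value, which is informative rather
than an error.

Sweeps enumerate **all** k-subsets for k = 1, 2, 3 in lexicographic
region-id order — C(n, k) outcomes; at n = 129 that is 129 single, 8,256
pair and 349,504 triple deletions, and every region appears in
C(n−1, k−1) subsets (128 and 8,128 for pairs and triples). There is no
random subsampling of combinations. Triple sweeps above 60 regions are
gated behind an explicit `allow_large` opt-in because the enumeration cost
grows cubically.

## Aggregating multi-node deletions into region scores

For single deletions a region's score is simply its ΔGE. For pair/triple
sweeps the combinations are rank-ordered by ΔGE (rank 1 = largest drop;
ties broken by lexicographic subset order), each combination contributes a
weight to its member regions, and each region's summed weight is
normalized by its appearance count C(n−1, k−1). The weight function is a
genuine design choice — "weighted by the combination's rank" admits many
readings — so it is pluggable: the default is the linear reverse rank
`w(r) = C(n,k) − r + 1`, with `1/r` and a top-m indicator available. In
our synthetic cohorts the resulting region ranking is essentially
identical across k = 1, 2, 3 (rank correlations near 1), which is why the
cohort pipeline defaults to the k = 1 sweep and treats the multi-node
sweeps as a consistency check rather than the primary ranking.

Cohort-level importance averages per-subject scores region-by-region
(equivalently, for k = 1, the mean ΔGE per region across subjects). All
rank vectors break ties by ascending region id, everywhere, so outputs are
reproducible to the byte.

# Strain analytics

Regional maximum principal strain (rMPS) is the 95th percentile of the
element strains inside a region; MPS95 is the same percentile over all
elements in the brain. The percentile uses linear interpolation between
closest ranks (type 7); FE post-processing tools differ on this
convention, so it is configurable.

The strain ranking scores each region by its mean rMPS over *concussive*
impacts only (median available); non-concussive impacts cannot influence
it. Group contrasts use the two-sided Wilcoxon rank-sum test with
midranks: the exact null distribution when the smaller group has at most 8
observations and the data are tie-free, otherwise the normal approximation
with continuity correction; regional tests apply Bonferroni correction at
α = 0.05 over the number of regions. The correlation between the strain
ranking and the network-importance ranking is Pearson's, computed on
scores by default (ranks by switch) — both are reported by the pipeline
since the choice is not dictated by the method.

# Risk model

Concussion probability is modeled by binary logistic regression; with only
~20 positive events the 5-events-per-predictor rule caps models at 4
predictors, and the package enforces that cap. Validation is LOOCV:
accuracy, sensitivity and specificity are computed at a 0.5 threshold on
the out-of-fold probabilities; the testing AUC is computed once on the
pooled out-of-fold probabilities (Mann–Whitney formulation with midrank
tie handling); the training AUC is averaged over folds.

Small near-separable datasets make maximum-likelihood logistic fits
diverge. The fitting strategy is: attempt the ordinary fit; on detected
separation or non-convergence, warn and refit with a minimal ridge penalty
(1e-4 on standardized slopes, intercept unpenalized) so that every fold
returns a finite, deterministic model. A training fold containing a single
class predicts that fold's class rate rather than aborting, so a 53-fold
LOOCV always completes. Coefficients are always reported on the original
predictor scale.

One property of this design deserves emphasis: the pooled out-of-fold AUC
is a *pessimistic* estimate for weak predictors. Leaving out a positive
case lowers the training-fold prevalence and therefore systematically
lowers that case's held-out probability relative to held-out negatives;
with a pure-noise predictor the pooled LOOCV AUC sits well below 0.5
(seed-averaged values of roughly 0.2–0.4 at 53 cases, depending on the
predictor's tail weight) even though accuracy
correctly converges to the majority-class rate. This is a documented
artifact of pooling LOOCV probabilities, not a defect of the AUC
implementation — the same behavior reproduces with an independent
GLM/ROC stack.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with ground truth stored alongside every dataset.

**Atlas.** Two hemispheres plus one midline brainstem-like region; about
12% of parcels subcortical. Planted hubs are drawn from subcortical
parcels and planted high-strain regions from cortical parcels, mirroring
the empirical finding that network-critical regions concentrate in the
subcortex while impact strain concentrates in the lateral cortex; the two
planted sets are disjoint by construction.

**Connectomes.** Four spatial communities (hemisphere × anterior/
posterior) with within-community connection probability elevated
`intra_module_bias`-fold; edge weights log-normal (sdlog 0.6), emulating
volume-normalized streamline counts, whose distribution the source data
do not constrain — these are free knobs, not calibrated claims. Hubs
connect across communities with both elevated probability and
`hub_weight_boost`-fold elevated weights; with the default boost of 3 the
planted hubs are recovered by the single-deletion ΔGE ranking (a recovery
test, not a construction guarantee). Generation rejection-samples until
the network is one connected component (bounded attempts). Note the
realized density exceeds the `density` argument when hubs are boosted;
`density` sets the non-hub background. Cohorts share the base topology;
each subject's weights get independent multiplicative log-normal noise,
so between-subject variability grows monotonically with the noise knob
and the zero-noise cohort is degenerate-identical.

**Impacts.** A single latent log-severity per case drives all observables:
concussive cases receive a `concussion_strain_shift`-fold multiplicative
elevation (log-shift of the latent), and each channel — four kinematic
peaks and the strain field — adds independent multiplicative log-normal
noise. The noise variance shared by the strain channel and peak angular
acceleration is solved in closed form from the lognormal-mixture moment
formula so that the Pearson correlation between MPS95 and peak angular
acceleration matches the requested coupling (default 0.83) in
expectation; the other kinematic channels carry progressively larger
noise so angular acceleration remains the strongest single kinematic
predictor. Element strains are 200 gamma draws per region (shape 6)
around a spatial profile elevated 1.6-fold in the planted high-strain
regions with mild (sdlog 0.15) region-to-region heterogeneity; rMPS and
MPS95 are computed from those draws exactly as they would be from FE
elements. Baselines (8 m/s, 35 rad/s, 80 g, 5000 rad/s², baseline mean
element strain 0.12) sit in the range typical of reconstructed
professional-football impacts. Setting the shift to 1 yields an exact
null generator: identical distributions in both outcome groups.

What the generator does **not** emulate: real Lausanne region volumes or
geometry, spatially correlated strain fields beyond the shared latent
severity, tractography biases, or any FE mesh. Passing recovery tests on
these data therefore demonstrates that the *analysis machinery* is
correct and well calibrated, not that the scientific conclusions transfer
to any particular real dataset.

# Default study conditions and problem sizes

The pipeline defaults are the reference study conditions: 129 regions, 10
planted hubs and 10 planted high-strain regions, 30 subjects
(between-subject noise 0.3), 53 impacts with 20 concussive, strain shift
1.5, coupling 0.83, k = 1 lesion sweeps, 4-predictor cap, threshold 0.5.
The test suite exercises the oracle-equivalence properties exhaustively
at 4–8 nodes (where brute-force path enumeration is feasible), the
recovery properties at the full 129-region scale over 10 seeds, and the
end-to-end pipeline at a 20–24-region demo scale; those sizes are the
package's chosen balance between statistical resolution and a suite that
runs comfortably on a laptop.

# Known limitations

* The multi-node aggregation weight is an interpretation; rankings are
  insensitive to it in our cohorts, but the specific scores are not
  comparable across weight functions.
* ΔGE of weak regions can be slightly negative under the fixed-reference
  normalization; cohort averages of peripheral regions may therefore sit
  just below zero where a positive-only reading is expected.
* Pooled LOOCV AUC is pessimistic for weak predictors (see above); compare
  predictors by accuracy and training AUC as well.
* The generator's effect sizes are knobs. Only the seeded defaults are
  validated by the recovery tests; other settings should be re-validated
  before being used as a benchmark.
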