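---
title: "Modelling MCI-to-AD conversion with cluster-trajectory atlases"
author: "mciTrajectory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling MCI-to-AD conversion with cluster-trajectory atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mciTrajectory)
```

# The model

The pipeline asks a simple question of longitudinal structural MRI: does the
*path* a person's brain morphology takes through a low-dimensional space
predict whether their mild cognitive impairment (MCI) will progress to
Alzheimer's dementia (AD)?

Each scan is summarised as 62 regional cortical-thickness z-scores
(Desikan–Killiany–Tourville cortex, 31 parcels per hemisphere), standardised
against a cross-sectional normative cohort. Age is deliberately excluded
from the normalisation: age-related thinning is the very signal the
embedding should organise, and AD risk is strongly age-dependent.

**Embedding.** The 62-dimensional vectors are reduced to `m = 2` dimensions
with a neighbour-graph manifold reduction and rotated onto the principal
axes of the embedding (the SVD of the centred coordinates), so axis 0 is
the direction of maximal variance — the t-UMAP construction. Two reducers
implement one contract (`fit` + out-of-sample `project`):

* `"spectral"` (default): Laplacian eigenmaps of the symmetrised
  k-nearest-neighbour graph with a heat-kernel affinity. Eigenvectors are
  scaled by $1/\sqrt{\lambda}$ (the commute-time embedding), which is what
  gives the axes a meaningful variance ordering; unscaled Laplacian
  eigenvectors all have unit norm and the principal-axis rotation would be
  arbitrary. New points are placed by kernel-weighted averaging over their
  k nearest training points. The method is fully deterministic: identical
  inputs give identical coordinates, which is what makes end-to-end
  byte-reproducibility possible.
* `"pca"`: a plain principal-component reducer whose projection of the
  training data reproduces the training embedding to machine precision. It
  is the reference implementation for every exact contract test.

The `minDist` configuration field is accepted for interface parity with
UMAP-family reducers but has no effect on either reducer shipped here,
neither of which imposes a minimum spacing in the reduced space.

Axis signs are conventions, not data: axis 0 is flipped so its Pearson
correlation with age is non-negative (when ages are supplied); other axes
pin the largest-magnitude rotation loading positive. On the synthetic
normative cohort the emergent age correlation of axis 0 is a property the
test suite asserts (|r| ≥ 0.5 across the n_neighbors grid), echoing the
brain-age interpretation of the leading axis.

**Equal-size clustering.** Trajectory probabilities need comparable
statistical power per state, so the embedding is partitioned into C clusters
of (near-)identical size. From the point–centroid distance matrix **D**,
membership probabilities are

$$W_{ij} = 1 - D_{ij} / V_i, \qquad V_i = \max_j D_{ij},$$

so each row lies in [0, 1] with an exact zero at the furthest centroid.
Centroids are seeded with k-means++; points are assigned by a single global
greedy pass over all (point, cluster) pairs ordered by decreasing $W$,
respecting capacities $\lfloor N/C \rfloor$ (+1 for the first $N \bmod C$
clusters). Refinement then enumerates size-preserving label *swaps*
(pairs of points exchanging clusters — the minimal move that cannot unbalance
sizes), applies non-overlapping improving swaps greedily, and stops when the
best frozen-centroid gain falls below `tol` ($10^{-6}$) or after `maxIter`
(100) iterations. Inertia decreases strictly at every accepted iteration,
so termination is guaranteed; on well-separated instances the fit matches
exhaustive search over all equal bipartitions (asserted up to N = 12).
Cluster ids are relabelled to ascend with the centroid's axis-0 coordinate,
so "cluster 0 … cluster C−1" reads left to right along the principal axis.
Projected test scans take their nearest centroid without any size
constraint — balance is a training-time device only.

**Trajectory atlas.** Visits are first binned to annual steps: a visit at
time $t$ (years from the subject's first retained scan) maps to bin
$k = \mathrm{round}(t)$ and is kept only if $|t - k| \le$ `tolerance`
(default 5/12 y, i.e. one year ± five months); within a contested bin the
closest visit wins, ties going to the earlier scan. Subjects with fewer
than `minVisits` (2) retained scans are dropped. A subject's trajectory of
length $l$ is the cluster sequence of their *last* $l$ visits. Over the
$T = \sum_{l=1}^{L} C^l$ possible trajectories (by default $L = 3$; with
$C = 7$ the fixed-length count $C^L$ is 343), the atlas records how many
stable and converter subjects traversed each observed path and the
empirical conversion probability. Unobserved paths score 0 — "no evidence"
— and the supporting population is always returned alongside so callers can
distinguish that case from genuine evidence of stability; no smoothing or
shrinkage is applied.

**Evaluation.** Subjects (never scans) are split 10% test / 40% space /
50% CV, stratified by outcome; the space split exists so that the
longitudinal-embedding experiment can train its reducer on data disjoint
from both CV and test, and it is carved out even in the normative
experiment so both experiments share identical memberships at equal seed.
Repeated stratified 10-fold CV refits the clustering and atlas per fold and
scores validation subjects at each $l$; a subject with fewer than $l$
visits is excluded from that length's ROC and the exclusion is counted.
The ROC sweeps the decision threshold over all distinct scores (converter
iff probability strictly exceeds the threshold); its trapezoidal AUC equals
the Mann–Whitney rank-sum estimator with half credit for ties, which the
test suite verifies on random instances. Fold AUCs are macro-averaged; the
best (C, l) by mean AUC (ties to smaller C, then smaller l) is refit on the
full CV pool and scored once on the test subjects.

# The synthetic cohorts

Real studies of this design rely on access-restricted data, so the package
generates cohorts with the statistical structure the pipeline assumes:

* **Normative, cross-sectional** (default n = 1200, ages uniform 18–100):
  $z_{ir} = s_r (a_i - a_{\mathrm{ref}})/10 + u_i + \varepsilon_{ir}$ with
  per-region thinning slopes $s_r \le 0$ (z per decade; a smooth gradient
  with stronger decline, −0.35, in the AD-signature parcels), a shared
  subject offset $u_i \sim N(0, 0.4^2)$, noise
  $\varepsilon \sim N(0, 0.2^2)$, and $a_{\mathrm{ref}}$ the age-range
  midpoint.
* **Longitudinal MCI** (default n = 400, baseline ages 55–92 so last visits
  stay below ~97): 2–6 visits with gaps $N(1.0, 0.2^2)$ years truncated
  positive — deliberately irregular so the annual binning stage has real
  work to do. 40% of subjects are converters: their twelve bilateral
  AD-signature regions (entorhinal, supramarginal, superior frontal,
  superior temporal, inferior parietal, middle temporal) accrue an extra
  `converterExtraSlope` · t of atrophy, and their diagnosis flips from MCI
  to AD at the final visit only, mirroring an outcome defined by the last
  available follow-up.

The cohort sizes are the package's own desk-scale choices (a large
normative sample and an MCI cohort of several hundred are emulated at
1200 and 400 subjects), and `repeats = 2` is the reduced-repeat condition
used in the acceptance runs; the full `repeats = 10` matches the classical
protocol.

The **strong-effect preset** fixes `converterExtraSlope = -0.7` z/year.
This value was calibrated once so that, at these cohort sizes, the injected
signal is comfortably recoverable (best CV AUC above 0.7) — an effect at
the upper end of plausible signature-region atrophy in prodromal
converters, appropriate for a positive-control condition at a cohort scale
several times smaller than the real studies it emulates. The **null
preset** sets the slope to 0: outcome labels are assigned but carry no
signal, and the pipeline's CV AUCs must hover at chance — the key guard
against leakage anywhere in the fold/atlas machinery.

What the generator does **not** emulate: scanner and field-strength
effects, sex and head-size covariates, image-quality artefacts, nonlinear
aging curves, conversion occurring mid-follow-up (atrophy accrues from
baseline but the label flips only at the last visit), and spatial
correlation between neighbouring parcels beyond the shared subject offset.
Passing tests therefore demonstrate that the machinery recovers a linear
atrophy signal under Gaussian noise — not that the method attains any
particular accuracy on real MRI data.

# Numerical and design choices

* **Binning conventions.** Bins are anchored at integer multiples of one
  year from each subject's first retained scan (subject-relative, not
  calendar-relative), and the closest-wins/earlier-on-tie conflict rule is
  a determinism convention; nothing in the method depends on the tie
  direction. A per-visit `excludeFirst` flag drops flagged baselines before
  binning (representing protocol-change exclusions) without modelling
  scanners.
* **Degenerate inputs.** An all-zero distance row (a point coincident with
  every centroid) yields uniform membership 1 by convention rather than an
  error; zero-variance columns in correlation diagnostics return `NA`
  markers; a constant region in the normative reference is a hard error
  naming the region; an empty visit list bins to an empty result.
* **Tie-breaks.** Greedy assignment orders ties by lower point index then
  lower cluster index; nearest-centroid assignment of new points resolves
  ties to the lower cluster id; n_neighbors selection (maximise
  |r(axis0, age)| − |r(axis1, age)|) resolves ties to the smallest k, the
  cheaper model.
* **Seeds.** A single master seed derives every stream (generation, split,
  folds, every per-fold clustering) through a fixed integer chain, so a
  configuration determines all outputs byte for byte; k-means++ is the only
  intrinsically random component and is seeded per fit.
* **Trajectory-count conventions.** Both $\sum_{l=1}^{L} C^l$
  (`trajectorySpaceSize`) and $C^L$ (`fixedLengthTrajectoryCount`) are
  exposed: the literature quotes both, and for $C = 7, L = 3$ they differ
  (399 vs 343); the package takes no side and reports each explicitly.

# Limitations

* The spectral reducer preserves neighbourhood structure but is not UMAP;
  embeddings are not expected to coincide with UMAP coordinates, only to
  fill the same role in the pipeline (the contract all downstream stages
  and tests are written against).
* Zero-filled unseen trajectories bias unseen-path subjects toward
  "stable"; with small cohorts and large $C^l$ this is the dominant error
  source, which is why C is capped at 6 in the default grid.
* Out-of-sample spectral projection is a Nyström-style approximation;
  training points project near, not exactly onto, their fitted coordinates
  (the PCA reducer is exact and is used where tests require exactness).
* The atlas has no uncertainty quantification; probabilities from
  populations of 1–3 subjects are as authoritative in the lookup as
  well-populated ones. The population field is exposed precisely so callers
  can post-filter.

# A minimal run

```{r example}
cfg <- defaultPipelineConfig(seed = 1)
cfg$evaluation$repeats <- 2L
res <- runExperimentLongitudinal(cfg, outputDir = "results/exp2")
res$best        # selected (C, l) with its CV AUC
res$test$auc    # held-out AUC
```
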