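---
title: "Time-resolved structure-function coupling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved structure-function coupling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynsfc)
```

## The problem

Anatomical connections constrain, but do not fully determine, the
statistical dependencies observed between the activity of brain regions.
The usual way to quantify this *structure-function coupling* is static:
one functional connectivity (FC) matrix per scan, one coupling value per
region. This package implements a time-resolved version. Functional
connectivity is "temporally unwrapped" into frame-wise co-fluctuations,
and the coupling regression is refitted at every frame, yielding a
region x time matrix of coupling values whose fluctuations can then be
analyzed in their own right.

## Edge time-series

For z-scored regional activity $z_i(t)$, the co-fluctuation of regions
$i$ and $j$ at frame $t$ is the element-wise product
$z_i(t)\,z_j(t)$. Two regions deflecting to the same side of their
baseline co-fluctuate positively, opposite deflections negatively. The
time-average of the co-fluctuation series is exactly the Pearson
correlation — provided z-scoring uses the *population* standard
deviation (divisor $T$). We adopt that convention (`zscore_activity()`)
so the averaging identity

$$\frac{1}{T}\sum_t z_i(t) z_j(t) = r_{ij}$$

holds to machine precision rather than being off by $(T-1)/T$.

## Structural predictors

Three pairwise structural relationships serve as regressors
(`build_predictors()`):

* **Euclidean distance** between node centroids — proximity as a proxy
  for ease of communication.
* **Shortest path length** — centralized routing. Weights are first
  minmax-normalized over the whole matrix (for a sparse connectome this
  is division by the maximum weight, which avoids mapping the weakest
  existing edge to zero), then transformed to lengths by $-\log w$.
  Absent edges are non-traversable (`NA`), not infinite lengths that
  would participate in arithmetic; a unit-weight edge legally has length
  zero and the path search (Dijkstra, via igraph) tolerates it.
* **Weighted communicability** — decentralized diffusion:
  $C = \exp(D^{-1/2} A D^{-1/2})$ with $D = \mathrm{diag}(\sum_k a_{ik})$,
  computed by symmetric eigendecomposition. Degree normalization keeps
  high-strength hubs from dominating the walk sum.

Path length and communicability are computed from the *same* normalized
matrix.

## The coupling model

For region $i$ and frame $t$, the co-fluctuation profile to all other
regions $j \neq i$ is regressed on the three structural profiles:

$$\mathrm{cofluc}_{t,i}(j) = \beta_0 + \beta_1\,\mathrm{dist}_i(j) +
\beta_2\,\mathrm{spl}_i(j) + \beta_3\,\mathrm{cmc}_i(j)$$

by ordinary least squares, fitted independently per region, per frame,
per subject. Coupling is the adjusted $R^2$ of this fit
(`dynamic_coupling()`); applying the same model to the static FC profile
gives one static coupling value per region (`static_coupling()`). The
classical rank-correlation alternative (Spearman correlation between
structural and functional profiles over structurally connected pairs) is
provided for comparison (`spearman_rank_coupling()`), and
`dominance_analysis()` decomposes the full-model $R^2$ into
per-predictor contributions by averaging incremental $R^2$ over all
predictor subsets (plain $R^2$ inside the increments; the totals sum
exactly to the full-model $R^2$).

**Degenerate frames.** A frame whose co-fluctuation profile is (near)
constant across $j$ has an undefined $R^2$. Such frames are recorded as
`NA` and counted, never silently set to 0 — a zero would bias every
temporal statistic downstream, most visibly cv($R^2$).

## Dynamics statistics

* `coefficient_of_variation()` — $\mathrm{sd}_t / \mathrm{mean}_t$ per
  region, sample sd (divisor $n-1$); lets series with different means be
  compared.
* `dynamic_vs_static()` — probability that a dynamic value exceeds the
  static one (strict inequality; ties count as not-larger), bias
  (median difference), and variance (84th minus 16th percentile of the
  dynamic values, $\pm 1$ sd under normality, robust to outliers).
  Percentiles use linear interpolation between order statistics
  (R quantile type 7).
* `coupling_similarity()` — Pearson correlation between regional
  coupling time-series, averaged over subjects.
* `connectivity_distance()` — mean Euclidean distance to structurally
  connected neighbors; unweighted by default with a `weighted` switch,
  since the literature uses both variants.
* `group_similarity_contrast()` — pooled-variance two-sample t-test of
  upper-triangle similarity values split by structural connectedness or
  network co-membership.

## Spatial null models

Parcellated brain maps are spatially autocorrelated, so parametric or
naive permutation p-values are anticonservative. `generate_spins()`
draws uniform (Haar) random 3-D rotations — QR decomposition of a
Gaussian matrix with sign and determinant correction — applies them to
the left-hemisphere parcel positions on the unit sphere, mirrors the
rotation to the right hemisphere, and reassigns each parcel the value of
the nearest rotated parcel within its hemisphere. Nearest-neighbor
assignment means a source parcel can be reused; rows of the permutation
index are surjections-with-repeats rather than strict permutations.
`spin_pvalue()` recomputes the statistic under every spin and reports
$p = (1 + \#\{|\mathrm{null}| \ge |\mathrm{obs}|\})/(n_{\mathrm{perm}}+1)$,
never exactly zero; two-tailed by default with a one-tailed flag.

Robust correlations contextualize coupling maps against embedding
metrics: `biweight_midcorrelation()` (tuning constant 9, unscaled MAD)
and `percentage_bend_correlation()` (bend fraction 0.2; at 0 it reduces
to Pearson). The tuning constants are the conventional defaults.

## The synthetic world

`gen_geometry()`, `gen_connectome()`, `gen_activity()` and
`gen_annotations()` build a complete test bed with known ground truth:

* bilateral geometry — points uniform on the left half of the unit
  sphere, mirrored to the right; centroids on a shell of radius 70
  (arbitrary mm-like units);
* sparse connectomes — edges sampled without replacement with
  probability $\propto e^{-d/\lambda}$, lognormal weight variability
  (sdlog 0.5) on the same distance decay, bridging edges added if the
  graph is disconnected;
* activity — at frame $t$, node $i$ emits
  $\sqrt{w_i(t)}\,s_i(t) + \sqrt{1-w_i(t)}\,\varepsilon_i(t)$ with
  $s(t) \sim N(0, R)$, $\varepsilon$ unit white noise, and fidelity
  $w_i(t) = \mathrm{baseline} + \alpha_i \sin(2\pi t/\tau + \phi)$,
  the phase drawn once per subject;
* annotations — spatially contiguous network and class labels by
  farthest-point seeding, and a smooth gradient (anterior-posterior
  coordinate plus 5% noise).

**The correlation target.** $R$ is the degree-normalized
communicability of the generated connectome rescaled to unit diagonal —
with one twist. For sparse connectomes the plain matrix exponential
produces off-diagonal correlations near zero (median ~0.006 at 100
nodes), i.e. an almost-identity target from which no structure could
ever be recovered. We therefore scale the normalized adjacency by a
*walk temperature* before exponentiation,
$R \propto \exp(\tau_w D^{-1/2} A D^{-1/2})$, and choose $\tau_w = 4$
once so that the median off-diagonal correlation is about 0.2 — the
magnitude typical of empirical BOLD FC. $\tau_w = 1$ recovers the plain
communicability target. The matrix exponential of a symmetric matrix is
positive definite by construction; a shrinkage guard toward the identity
(smallest eigenvalue $\ge 10^{-6}$) protects only against numerical
degeneracy.

**What a green test does not establish.** The generator emulates
geometry, sparseness, distance dependence and structured covariance —
not hemodynamics, physiological noise spectra, motion, or scanner
artifacts. Recovery results on this world say the pipeline's arithmetic
is right, not that empirical coupling dynamics are identifiable.

## A known identifiability limit

One property of the per-frame regression deserves emphasis. Each
co-fluctuation frame is the rank-1 outer product $z(t)z(t)^\top$, so
region $i$'s response profile at frame $t$ is $z_i(t)\,z_{-i}(t)$ — the
global activity pattern scaled by region $i$'s own amplitude. Because
$R^2$ is invariant to rescaling the response, $R^2_{i,t}$ equals the fit
of the *global* pattern $z_{-i}(t)$ to region $i$'s predictors and does
not depend on region $i$'s own signal at all. Two consequences, both
verified numerically in this package's test suite:

* a node-specific fidelity modulation $\alpha_i$ in the generator is
  *not* recoverable from the node's own cv($R^2$) — per-frame coupling
  fluctuations are driven by the global pattern and by the node's
  predictor profile, not by the node's own fidelity;
* the time-mean of per-frame $R^2$ and the static-FC $R^2$ are
  different functionals of the underlying covariance and correlate only
  moderately across nodes even with infinite data.

The corresponding end-to-end recovery assertions in
`test-acceptance.R` are left failing deliberately: they encode a
recovery expectation the method cannot meet, and the failure documents
the limit. Interpretation of regional cv($R^2$) maps should keep this
global-pattern dependence in mind.

## Conventions and defaults

| Choice | Value | Why |
|---|---|---|
| z-score divisor | $T$ (population) | exact averaging identity |
| temporal sd divisor | $n-1$ (sample) | conventional dispersion estimate |
| percentiles | linear interpolation (type 7) | R default, matches worked examples |
| "probability larger" ties | count as not-larger | strict inequality |
| gradient bins | 10 equal-count, remainder to lowest bins, stable ties | deterministic |
| spin tails | two-tailed on absolute value | conservative default |
| biweight constant | 9 | conventional |
| bend fraction | 0.2 | conventional |
| walk temperature | 4 | realistic BOLD FC magnitude |

All switches and seeds are recorded in the JSON manifest written by
`run_subject()`.

## Workflow

```{r, eval = FALSE}
cfg <- run_config(
  synthetic = list(n_nodes = 60, n_time = 300, density = 0.25,
                   length_scale = 60, alpha = 0.2, baseline = 0.6,
                   timescale = 75, n_networks = 4, seed = 1),
  n_perm = 500, out_dir = "results")
subjects <- lapply(1:3, function(s) run_subject(cfg, s))
group <- run_group(cfg, subjects)
group
```

For real data, point `run_config()` at delimited-text activity and
connectome matrices plus an annotation TSV instead of the `synthetic`
block; the pipeline validates shapes, symmetry and connectedness before
computing anything.
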