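---
title: "Network-based RBF sparse PLS: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based RBF sparse PLS: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpls)
```

## The problem

Studies that pair whole-brain structural imaging with large biomarker panels
face a double curse of dimensionality: a subject's image is millions of
voxels, and the biomarker panel may hold hundreds of correlated assays,
while the cohort has a few hundred subjects. `netpls` implements a
regression strategy with two structure-preserving dimension reductions —
one per data side — followed by a sparse partial least squares (sPLS) link
and a diagnosis-driven component selection:

1. **Images** are compressed through a radial B-spline basis on a knot
   lattice, so each retained coordinate still refers to a location in the
   brain and any fitted weight vector can be re-mapped to a voxel map.
2. **Biomarkers** are reduced by estimating a statistical dependency graph,
   clustering it into (possibly overlapping) link communities, and keeping
   one representative variable per cluster, so each retained column is an
   actual measured variable standing for an interpretable cluster.
3. **sPLS** with L1-penalized weight vectors links the two reduced
   matrices; penalties are tuned by 5-fold PRESS cross-validation.
4. **Logistic backward-stepwise selection by BIC** on the component scores
   keeps only components relevant to the binary diagnosis.

## Image-side reduction

The basis function is the compactly supported piecewise-cubic radial
B-spline

$$\varphi(d) = \frac{1}{4g^2}\begin{cases}
g^3 + 3g^2(g-d) + 3g(g-d)^2 - 3(g-d)^3 & d \le g\\
(2g-d)^3 & g < d \le 2g\\
0 & d > 2g,
\end{cases}$$

which is continuous, nonincreasing, equals $g$ at the origin and vanishes
beyond $2g$. Knots sit on a regular lattice with spacing $g_0$ (default 4
voxels) starting at the minimum corner of the mask bounding box, and the
scale is tied to the lattice by $g = \sqrt{3 g_0^2}$ (6.93 voxels at
$g_0 = 4$) so neighbouring basis functions overlap. Stacking
$\varphi(\lVert voxel_i - knot_j \rVert)$ gives the sparse $V \times q$
matrix $B$; the image panel reduces to $Y = Y_0 B$ and any basis-space
weight vector $w$ maps back to the voxel map $Bw$.

Choices the lattice construction makes (the method is silent on them, so
they are fixed deterministically): knots anchor at the bounding-box corner;
a knot is kept iff at least one mask voxel lies within $2g$; distances are
in isotropic voxel units; voxel order is the mask scan order with the first
index fastest. Dense and sparse storage of $B$ give identical results; the
sparse path is used throughout.

## Biomarker-side reduction

Missing entries are first imputed by iterative ridge-stabilized
chained regression (deterministic given a seed; observed values never
change). This is a deliberately simple, testable stand-in for
proximity-based imputation schemes: the contract downstream stages rely on
is completeness plus determinism, not a specific imputation model.

The dependency graph is estimated, by default, as the maximum-weight
spanning forest under Gaussian mutual-information weights
$w_{ab} = -\tfrac12\log(1-\rho_{ab}^2)$, with each edge kept only if its
likelihood-ratio gain beats a one-parameter BIC penalty
($2 n w_{ab} > \log n$). This realizes "statistical dependence through a
decomposition of the joint density" as a decomposable (tree-structured)
Gaussian model with a fully specified estimator; a plain
correlation-threshold mode is available as a fallback. Binary variables
(e.g. allele counts) are treated as numeric, consistent with the
correlation machinery.

Clusters are **link communities**: edges are embedded by the Jaccard
similarity of their endpoints' inclusive neighbourhoods, agglomerated by
single linkage, and cut where the partition density

$$D = \frac{2}{M}\sum_c m_c\,\frac{m_c - (n_c - 1)}{(n_c - 2)(n_c - 1)}$$

is maximal. A node whose edges land in different communities belongs to
several clusters — the overlap is a feature, since a biomarker can
participate in more than one physiological cluster. On acyclic components
(the default forest estimator always produces these) the partition density
is identically zero, so there the edges are grouped into maximal stars
around branch vertices, each edge anchored at its higher-degree endpoint
with lexicographic tie-breaks; degenerate two-node clusters are retained.
Clustering is run per connected component, which cleanly mixes the two
regimes and cannot lower the global partition density.

Each cluster contributes one representative column: for clusters of three
or more members, the member with the highest **Stephenson–Zelen
information centrality** in the cluster's induced subgraph, computed from
$C = (L + J)^{-1}$ as $IC_i = [C_{ii} + (T - 2R_i)/n]^{-1}$; two-member
clusters use the higher-variance member (centrality is uninformative
there). The size-3 boundary is deliberately resolved toward the centrality
rule. All ties break lexicographically and are logged. Duplicate
representatives across clusters collapse to a single column, so
$p \le$ the number of clusters.

## Sparse PLS

Each component solves

$$\min_{v, w}\; -v^\top X^\top Y w + \lambda_X \lVert v\rVert_1
  + \lambda_Y \lVert w\rVert_1,\qquad \lVert v\rVert_2 = \lVert w\rVert_2 = 1$$

by alternating soft-thresholded updates
$v \leftarrow \mathrm{normalize}(h_{\lambda_X}(X^\top Y w))$,
$w \leftarrow \mathrm{normalize}(h_{\lambda_Y}(Y^\top X v))$, initialized at
the first singular-vector pair of $X^\top Y$ (at zero penalty the iteration
is exactly the power method, so weights equal the singular vectors). Scores
and loadings follow ($t = Xv$, $\ell = X^\top t / t^\top t$,
$m = Y^\top t / t^\top t$) and both matrices are deflated by the X score
($X \leftarrow X - t\ell^\top$, $Y \leftarrow Y - tm^\top$) before the next
component. Numerical choices: X columns centered and unit-scaled, Y
centered only (stored, so predictions invert the transforms); convergence
at $10^{-6}$ max-norm change with a 500-iteration cap; signs fixed so the
largest-magnitude entry of $v$ is positive; a penalty that annihilates a
weight vector raises a degenerate-component condition — an error in a
direct fit, `PRESS = Inf` during tuning, and truncation of the model (with
a warning) inside a multi-component fit.

Penalties are tuned by minimizing the total prediction error sum of
squares, $PRESS_j = \sum_i (y_{ij} - \hat y_{(-\kappa(i))j})^2$, under a
seeded 5-fold partition $\kappa$ (stratified by the label when supplied),
with refitting — including re-centering — on each training fold so no
held-out information leaks into the transforms. The two-dimensional search
runs as alternating one-dimensional golden-section searches per axis over
$[0, \max|X^\top Y|]$; the full evaluation trace is retained and the
returned optimum is the best pair actually evaluated. The per-component
$Q^2(h) = 1 - PRESS(h)/RSS(h-1)$ diagnostic is available with the
conventional 0.0975 relevance cut; the pipeline default nevertheless fits
$k = 10$ components and lets the diagnosis-driven selection decide, since
$Q^2$ knows nothing about the labels.

## Component selection

The selection stage fits a logistic regression of the diagnosis on the
component scores and greedily drops the column whose removal most lowers
BIC ($-2\ell + (m+1)\log n$), stopping when no drop helps; the path may end
at the intercept-only model. X scores ($T$) are the default predictors with
a flag for Y scores ($U$) — both conventions appear in practice and the
package does not silently pick one. Perfect separation raises an error by
default; a ridge-stabilized Newton fallback (penalty $10^{-4}$) is used by
the pipeline, where truncation would otherwise lose the run. The component
report joins, per selected component, the nonzero X weights with their
clusters and co-clustered variables, the re-mapped voxel map with its
nonzero-voxel count, and the logistic coefficient and Wald p-value.

## Synthetic data: what it emulates and what it does not

The generator plants latent severity factors $z \sim N(0,1)$ that drive
(a) spherical low-intensity ("atrophy") regions in a small 3D grid,
(b) block-correlated biomarker clusters (block $b$ shares a factor
$s_b$, linked blocks have $s_b = 0.9 z_f + $ residual; columns are
$\sqrt{\rho}\,s_b + \sqrt{1-\rho}\,\varepsilon$ giving exact within-block
correlation $\rho$), and (c) labels from a logistic model on $z$. The
desk-scale default — grid $20\times24\times20$, $n = 200$, two factors, two
radius-3 regions of effect 2 against unit voxel noise, 12 blocks of 5 with
$\rho = 0.7$, label intercept $-0.5$ and slopes 2, 5% missingness
completely at random — runs the full pipeline in a few seconds on one CPU,
and the heavier multi-seed properties in minutes. What it does **not**
emulate: realistic MRI texture, spatial noise correlation, partial-volume
or site effects, informative missingness, non-Gaussian biomarker scales.
Passing tests therefore certify the algorithmic contracts and recovery
behaviour under the assumed data model, not performance on any real cohort.

## Measuring recovered brain regions

The re-mapped voxel map is the planted region seen through a kernel of
scale $g$: its raw nonzero support is a union of $2g$-balls no matter how
compact the truth is. For a point source the half-maximum set already has
radius $\approx 0.79\,g \approx 5.5$ voxels, so for a radius-3 region even
a perfect recovery caps at Jaccard $\approx 0.17$ against the true mask —
a threshold that cannot distinguish perfect from mediocre recovery is the
wrong ruler. The recovery metrics therefore delimit support at the level a
point-source profile reaches one knot spacing from its peak,
$\varphi(g_0, g)/g$ ($\approx 0.64$ at $g_0 = 4$), which corresponds to a
blob of radius $\approx g_0$ — the lattice's own resolution unit. The
threshold is exposed (`support_frac`), and `remap_weights()` keeps an
absolute `tol` (default 0: strict nonzeros) for voxel counting, since the
mapping from basis-space sparsity to voxel counts is a reporting
convention, not part of the model.

## Evaluation harness

To compare clustering strategies in isolation, the sPLS stage is
simplified to a univariate response (summed intensity in a designated
region over summed intensity in the whole mask — a volumetric-ratio
surrogate). Per bootstrap replicate, each method — the package's network
pipeline; average-linkage hierarchical clustering on correlation distance;
a Gaussian-mixture clustering of a 5-dimensional MDS embedding of the
correlation distances — reduces the resampled panel to representatives
(hierarchical and mixture are cut/fit to the network method's cluster
count, so only the grouping differs, and use the variance rule for
representatives since they have no graph), then a lasso with 5-fold CV
screens the representatives, backward stepwise BIC refines the linear
model, and the replicate records in-sample adjusted $R^2$ and out-of-bag
MSE. The comparison is discriminating only on *representative-identifiable*
panels — blocks whose members differ in quality, e.g. one low-noise hub
assay plus noisier peripheral assays of the same quantity. On fully
exchangeable blocks all methods pick equally good representatives and the
comparison is a coin flip; the test fixtures therefore use hub-structured
blocks, which is also the realistic situation (panels contain redundant
assays of unequal precision).

## Known limitations

- Isotropic voxel units only; anisotropic spacing and subject-specific
  lattices are out of scope.
- The forest estimator sees only pairwise Gaussian dependence; strongly
  nonlinear or higher-order dependencies will be missed (the threshold
  mode shares this limit).
- The imputation is a linear chained-regression scheme; heavily
  non-ignorable missingness is not modelled.
- Binary responses only in the selection stage; multinomial staging is out
  of scope.
- PRESS-optimal L1 tuning, like all prediction-optimal penalty choices,
  may retain an occasional spurious weight entry; support recovery is
  excellent but not exact.
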