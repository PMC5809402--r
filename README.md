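# netpls — network-based RBF sparse partial least squares

`netpls` links high-dimensional 3D image panels (e.g. voxel-based
morphometry maps of the brain) to large tabular biomarker panels, and
selects the image-region / biomarker-cluster pairs that predict a binary
diagnosis. It is aimed at imaging-genetics / imaging-biomarker studies
where both data sides dwarf the cohort size and interpretability of the
result matters as much as prediction.

## The method

Two structure-preserving dimension reductions feed a sparse regression:

1. **Radial basis reduction (images).** A lattice of knots with spacing
   g0 (default 4 voxels) carries compactly supported radial B-splines
   φ(d) with scale g = √(3 g0²) and support radius 2g. Stacking
   φ(‖voxel − knot‖) gives a sparse V × q matrix **B**; the n × V panel
   Y0 becomes **Y = Y0 B**, and any fitted weight vector w maps back to a
   voxel map **B w** — dimension reduction without losing location.
2. **Network clustering (biomarkers).** A dependency graph over the p0
   variables (maximum-weight spanning forest on Gaussian
   mutual-information weights, BIC-pruned) is split into overlapping link
   communities; each cluster keeps one representative — its highest
   information-centrality member (variance rule for 2-node clusters) —
   giving the n × p matrix **X** of actual measured variables.
3. **Sparse PLS.** Components maximize vᵀXᵀYw under L1 penalties on both
   weight vectors (soft-thresholded alternating updates, deflation by the
   X score); penalties λX, λY are tuned by 5-fold PRESS cross-validation
   with an alternating golden-section search.
4. **Component selection.** Backward-stepwise logistic regression by BIC
   on the component scores keeps the components relevant to diagnosis;
   each survivor is reported as a brain map plus a set of biomarker
   clusters with a coefficient and p-value.

A synthetic-data generator with full ground truth (latent severity
factors driving atrophy regions, correlated biomarker blocks, and labels)
makes every stage testable end to end, and an evaluation harness compares
the network reduction against hierarchical and Gaussian-mixture
clustering by bootstrap adjusted R² / out-of-bag MSE.

## Worked example

```r
library(netpls)

spec <- synthetic_spec()                       # 20x24x20 grid, n = 200, 12 biomarker blocks
ds   <- generate_synthetic(spec, seed = 42)
res  <- run_pipeline(ds, config = pipeline_config(seed = 42))
print(res)
#> network-based RBF-sPLS pipeline result
#>   config hash: 040ca0b724bdb40deb7606bf34dfdefa  seed: 42
#>   basis: q = 150 knots; X: p = 23 representatives from 24 clusters
#>   penalties: lambda_x = 84320  lambda_y = 0
#>   selected components: 1, 2
```

The image side was compressed from 9,600 voxels to q = 150 basis
coordinates; the 60 biomarkers collapsed to p = 23 cluster
representatives; PRESS tuning picked a strong λX (so each component uses
few biomarkers; λX is on the scale of XᵀY, hence its magnitude), and the
BIC-stepwise logistic stage kept components 1 and 2. Each selected
component pairs a biomarker set with a brain map:

```r
cc <- res$report$components[[1]]
round(cc$x_loadings, 3)
#> blk01_v4 blk01_v5 blk02_v2 blk03_v1 blk07_v1
#>    0.687    0.711   -0.121   -0.082   -0.038
signif(cc$p_value, 3)
#> [1] 3.21e-06
```

Component 1 is dominated by variables from blocks 1–2 — exactly the
blocks the generator tied to the latent factors — and its logistic
p-value is 3.2e-06. Checking against the planted truth:

```r
gt <- ground_truth_overlap(ds, res$report, res$clusters, basis = res$basis)
round(gt$region_jaccard, 2)       # per planted region, best support overlap
#> [1] 0.19 0.23
gt$block_match_fraction           # planted blocks recovered as clusters
#> [1] 1
```

Both planted atrophy regions are localized at the lattice's resolution
(Jaccard 0.19 / 0.23 against radius-3 spheres; the basis cannot localize
below its knot spacing) and all 12 correlation blocks were recovered with
in-block representatives.

A thin command-line front end over the same functions ships in
`inst/cli/netpls.R` (subcommands `simulate`, `reduce-image`,
`cluster-biomarkers`, `run`, `evaluate`).

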