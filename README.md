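# caviclass

Automatic classification of **caveolae versus non-caveolar scaffolds** from
3D single molecule localization microscopy (SMLM) data.

Caveolae are 50–100 nm plasma-membrane invaginations built from caveolin-1
(Cav1) and the adaptor protein CAVIN1/PTRF; without CAVIN1/PTRF, Cav1 forms
flat scaffold domains instead. In 3D SMLM both appear as sub-diffraction
clusters ("blobs") of per-molecule coordinates. `caviclass` is for
microscopists and image analysts who need to decide, blob by blob, *is this
a caveola?* — reproducibly and at scale.

The package implements the full workflow:

* **Pre-processing** — eventlist ingestion, iterative ≤ 20 nm localization
  merging (multi-blink correction), CSR-based density noise filtering,
  connected-component blob segmentation, CAVIN1/PTRF wide-field mask
  labeling (PTRF+/PTRF−), the ≥ 60-molecule caveola stratification, and
  class balancing.
* **Representations** — a frozen 1×28 feature vector per blob
  (size: N, xyz ranges, convex-hull volume, density; shape: covariance
  eigenvalues λ₁ ≥ λ₂ ≥ λ₃ with Westin linear/planar/spherical measures and
  fractional anisotropy; hollowness: five point-to-centroid distance
  statistics; network: ten proximity-graph measures, threshold chosen so
  every blob is one connected component); three orthogonal binary
  projections (xy, yz, xz); and the raw point cloud.
* **Models** — a 100-tree bagged random forest on the features; a compact
  multi-view CNN on the projections; a PointNet-style network (symmetric max
  aggregation, no dropout, no jitter) on point clouds. The neural layers and
  backpropagation are implemented in R with C++ kernels and verified by
  numerical gradient checks.
* **Evaluation** — confusion-count metrics (accuracy = (TP+TN)/total,
  sensitivity = TP/(TP+FN), specificity = TN/(TN+FP)), mixed and cell-wise
  train/validation/test splits, stratified k-fold cross-validation with
  pooled counts, and seeded 2D t-SNE feature embeddings.
* **Simulator** — the two-class validation dataset: 1000 isotropic blobs
  (Σ = diag(σ²,σ²,σ²), σ = 10 nm, 60–210 points) versus 1000 anisotropic
  blobs (Σ = diag(2σ²,σ²,σ²), 10–160 points), all centered at the origin,
  bitwise reproducible from one seed; plus a synthetic multi-cell experiment
  fixture (eventlists + painted masks) so the real-data path is testable
  without any download.

## Worked example: the simulated validation study

```r
library(caviclass)

res <- validate_simulated(simulation_params(seed = 1),
                          k = 10, n_trees = 100, cv_seed = 1)
res$report
#> <cav_report> n=2000  accuracy=0.9910  sensitivity=0.9890  specificity=0.9930
#>   TP=989 TN=993 FP=7 FN=11
```

2000 blobs are generated from the two-class normal model, each is reduced to
its 28-feature vector (the proximity threshold is picked so every blob's
graph is connected), and a 100-tree random forest is scored by stratified
10-fold cross-validation. The pooled counts say: of the 1000 isotropic
(caveola-like) blobs, 989 were recognized (sensitivity 98.9%); of the 1000
anisotropic blobs, 993 (specificity 99.3%); overall accuracy 99.1%. The run
takes about half a minute on one CPU.

The real-data workflow runs end-to-end on the synthetic multi-cell fixture:

```r
fx <- simulate_experiment_fixture(seed = 42)
run <- run_real_pipeline(fx$eventlists, fx$masks,
                         n_test = 16, n_val = 8, n_trees = 50, seed = 11)
run$reports$mixed
#> <cav_report> n=16  accuracy=1.0000  sensitivity=1.0000  specificity=1.0000
#>   TP=8 TN=8 FP=0 FN=0
run$reports$cell_wise
#> <cav_report> n=18  accuracy=1.0000  sensitivity=1.0000  specificity=1.0000
#>   TP=12 TN=6 FP=0 FN=0
```

A thin CLI over the same functions ships in `inst/cli/caviclass`
(subcommands `simulate`, `validate-simulated`, `featurize`, `project`,
`embed`, `run-fixture`).

See `vignettes/caviclass-methods.Rmd` for the model, the frozen feature
definitions, the simulator's assumptions, and known limitations.

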