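# cmcseg

Segmentation of mammographic images by **chaotic map clustering** (CMC):
feature-space clustering driven by the synchronization of coupled chaotic
logistic maps, aimed at flagging small mass lesions and the regions
containing denser micro-calcifications for radiologists and CAD pipelines.

## The method

The image is divided into square tiles (default 20 px, ~2 mm at a 0.1 mm
pixel pitch). Each internal tile *i* gets a feature vector *r<sub>i</sub>*
(intensity mean, variance, skewness, kurtosis, and the co-occurrence texture
triplet energy / entropy / contrast), standardized and decorrelated by a
Karhunen-Loève transform. A chaotic map *x<sub>i</sub>* ∈ [−1, 1] is
attached to each tile and the coupled system

> x<sub>i</sub>(t+1) = Σ<sub>j≠i</sub> J<sub>ij</sub> f(x<sub>j</sub>(t)) / C<sub>i</sub>,  f(x) = 1 − 2x²,
> J<sub>ij</sub> = exp(−‖r<sub>i</sub> − r<sub>j</sub>‖² / 2a²),  C<sub>i</sub> = Σ<sub>j≠i</sub> J<sub>ij</sub>

is iterated from a random (seeded) state. The local scale *a* is the mean
K-nearest-neighbor distance (K is the method's only free parameter). Maps of
similar tiles synchronize; synchronization is measured by the mutual
information I<sub>ij</sub> ∈ [0, ln 2] of the sign-bit sequences
S<sub>i</sub>(t) = 1{x<sub>i</sub>(t) > 0} after a transient. Thresholding
I<sub>ij</sub> > θ and taking connected components yields a nested hierarchy
of partitions; the operating partition is the widest θ-plateau on which the
cluster count and the two largest cluster sizes are constant. The partition
is projected back to the image (spatial contiguity enforced; reserved
clusters for background, breast border, and normal tissue), and small
isolated candidate clusters (≤ 4 tiles, surrounded by normal tissue, ≥ 6 mm
from the border) are flagged as mass-like findings. A plain
Euclidean-distance clustering baseline shares the whole back end.

A seeded phantom generator produces mammogram-like images (breast-shaped
foreground, correlated parenchyma texture, small/large masses,
micro-calcification clusters) with ground-truth masks, so the entire
pipeline is testable without clinical data.

## Worked example

```r
library(cmcseg)

suite <- fixture_suite(seed = 42)            # six canonical phantoms
fx    <- suite$small_mass_internal           # 2 mm mass, 6+ mm from border
run   <- segment_matrix(fx$image, cmc_config(seed = 7))
run
#> <cmc_run> mode: cmc, selected theta = 0.29
#> <segmentation_result> 19 x 19 tiles; 1 candidate cluster(s), 1 isolated

tidy(run$segmentation)                       # candidate table
#> # A tibble: 1 × 7
#>   label n_tiles centroid_row centroid_col border_dist_tiles border_dist_mm isolated
#>       3       1           10            5              6.32           12.6 TRUE

evaluate_segmentation(run$segmentation, fx$truth)$roi
#> # A tibble: 1 × 6
#>     roi kind        n_px best_overlap best_label best_isolated_overlap
#>       1 small_mass   317        0.685          3                 0.685
```

The single isolated candidate is the planted 2 mm mass: one tile, 12.6 mm
from the border strip, covering 68.5% of the ground-truth ROI.
`glance(run$hierarchy)` shows the stability evidence (a 2-cluster plateau of
width 0.56 in θ), and `autoplot(run$hierarchy)` draws the cluster-count and
cluster-size curves the selection is read from. `run_segment()` wraps the
same computation around image files and writes label rasters, renderings and
CSV tables; `inst/cli/cmcseg.R` exposes `segment` / `phantom` / `evaluate`
subcommands for shell use.

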