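# leafatlas

Quantitative 2D shape phenotyping of maize ear leaves from 3D-digitizer
point grids: area-preserving flattening, 29 morphometric features, a ranked
leaf-shape atlas, and inbred-line identification.

## The problem

Maize ear-leaf morphology varies enormously across inbred lines and matters
for yield, yet most of that variation lives in a curved, twisted, folded 3D
surface that is awkward to compare quantitatively. A tracked 3D digitizer
can record a leaf as a structured grid — five points per transect,
perpendicular to the midvein, base to tip, plus one tip point, so a leaf
with `n` transects has exactly `5n + 1` points — but grids from different
leaves cannot be compared directly. leafatlas is for phenotyping and
breeding researchers who want to turn those grids into comparable 2D leaf
models and a searchable shape catalogue.

## The method

1. **Screening.** Replicates within a line are compared on four raw-mesh
   features (length, width, aspect, folding angle); in a triplet, a sample
   whose scaled distances to both others exceed the remaining pair's
   distance by more than 0.1 is dropped.
2. **Mesh processing.** The grid is triangulated, normalized (principal
   axes, tip to +x, coordinates in [-1, 1]) and refined by two √3
   subdivision iterations (9× the faces).
3. **ARAP flattening.** The 3D mesh is mapped to the plane by minimizing
   the as-rigid-as-possible energy

   E(u, L) = Σₜ Aₜ ‖Jₜ(u) − Lₜ‖²_F,  Lₜ ∈ SO(2),

   by exact local/global alternation (rotation projection / one sparse
   least-squares solve), so the energy never increases. Area is preserved
   to a fraction of a percent.
4. **Features.** 29 features: chain lengths, widths at the digitizer
   transects, tip angle, offset and tortuosity angles, triangle-sum area,
   the folding degree FA = mean over faces of the mean neighbor-normal
   angle α(x, y) = arccos(|x·y|/(|x||y|)), and twelve radial contour
   features from 600-ray sampling of the boundary.
5. **Atlas.** Redundant features are merged by average-linkage clustering
   on Pearson distance (cut 0.25); per-feature weights come from a greedy
   search over {0, 0.5, …, 3}; lines are ranked by the composite index
   L2D = Σ wᵢ·vᵢ on min-max standardized semantic features.
6. **Identification.** A query leaf is matched to lines by weighted cosine
   similarity against per-line gallery means; accuracy is reported as
   rTop-X. Shape lookup from semantic features accepts a match only at
   similarity ≥ 0.9.

Because real digitizer campaigns are rarely redistributable, the package
ships a parametric leaf generator (bend, twist, margin waves, surface
folds, replicate noise) with known ground truth; all tests and the
acceptance analysis run on it.

## Worked example

```r
library(leafatlas)

## one synthetic leaf: 13 transects -> 66 points (5n + 1)
leaf <- generate_leaf(leaf_params(length_cm = 75, max_width_cm = 9,
                                  widest_frac = 0.4, seed = 3))
leaf
#> <digitized_leaf> line=L0 sample=S0: 13 transects, 66 points

## triangulate, normalize, subdivide, flatten, sample, extract
pr <- process_leaf(leaf)
round(pr$features[c("ML", "WM", "WP", "A", "FA", "LTA", "LWR")], 3)
#>      ML      WM      WP       A      FA     LTA     LWR
#>  74.854   9.011   0.385 422.265   0.059   0.111  12.991
sprintf("area ratio 2D/3D: %.4f", pr$area_ratio)
#> "area ratio 2D/3D: 0.9998"
```

The true midvein length was 75 cm, the true maximum width 9 cm at 40% of
the length: the pipeline recovers them within a fraction of a percent, and
flattening loses 0.02% of the surface area.

```r
## a small population end to end
pop <- generate_population(population_spec(n_lines = 12, replicates = 3,
                                           master_seed = 5))
res <- run_pipeline(pop$leaves)
res$model
#> <semantic_model> 11 features, threshold 0.25
#>    RL    WM    WP   LWR   LOA   ROA   MTV    TP   RUP   LUP     L
#> 0.385 0.000 0.308 0.231 0.077 0.000 0.000 0.000 0.000 0.000 0.000
head(res$atlas$entries, 3)
#>   line_id       L2D rank
#> 1    L006 0.1174095    1
#> 2    L004 0.3048754    2
#> 3    L003 0.3298522    3
res$report
#> retained 33/36 leaves; mean area ratio 0.9996; rTop-1 0.879
```

Three replicates were screened out, every flattening kept more than 99.9%
of its area, and weighted cosine identification places 88% of leaves with
their correct line at rank 1 (chance: 8%).

A command-line wrapper ships at `inst/scripts/leafatlas`
(`synth`, `flatten`, `features`, `run-all`).

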