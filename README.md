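# clonetrack

Dominant clonal lineages from DNA barcode time series.

High-resolution lineage tracking tags every founding cell of a microbial
(or mammalian) population with a unique chromosomal DNA barcode and counts
the barcodes by amplicon sequencing over time. Each barcode's frequency
trajectory traces one founding lineage through drift, selection, and
clonal interference — but sequencing reads only the barcode, so a lineage
that acquires a beneficial mutation mid-experiment reveals itself only by
the changing *shape* of its trajectory. `clonetrack` identifies the
dominant clonal lineages in such data by clustering trajectories with
similar dynamics, for experimentalists running barcoded evolution,
antibiotic-resistance, colonization, or pooled-screen experiments.

## Method

Given a long-format table of (barcode ID, time, read count):

1. **Normalise** counts to per-timepoint frequencies `f_k(t)`; zeros are
   real non-detections, and log-scale consumers replace them by a
   detection floor `1/(2·max depth)`.
2. **Filter** noise: keep barcodes with mean frequency `> 1e-4` (over all
   timepoints) detected in `≥ 12` timepoints.
3. **Summarise diversity** with Hill numbers
   `D_q(t) = (Σ_k f_k(t)^q)^{1/(1−q)}` — richness (`q=0`), exponential
   Shannon (`q=1`), inverse Simpson (`q=2`), dominance (`q=∞`).
4. **Compare trajectories** pairwise on `log10` scale by Pearson distance
   `1 − r` or dynamic time warping
   `D(i,j) = |x_i − y_j| + min(D(i−1,j), D(i,j−1), D(i−1,j−1))`.
5. **Cluster** by UPGMA (unweighted average linkage) or UPGMC (centroid
   linkage in trajectory space), sweep all cut heights
   (`quantify_thresholds()`), pick one (silhouette / knee / plateau
   heuristics, or by eye), and summarise each cluster with a LOESS
   consensus trajectory.
6. **Rank** clusters `C1, C2, …` by summed member frequency at the final
   timepoint; `C1` is the dominant clonal lineage.

A forward **Wright-Fisher simulator** (`simulate_barcoded_evolution()`)
with fitness-weighted multinomial reproduction, de novo beneficial
mutations founding sub-lineages under the parental barcode, and multinomial
read sampling provides ground truth (`evaluate_recovery()` scores cluster
assignments against true fitness classes by adjusted Rand index).

## Worked example

Simulate a desk-scale selective sweep (1e5 cells, 1000 barcodes, six
planted fitness groups over a neutral background) and call its clonal
clusters:

```r
library(clonetrack)

cfg <- make_benchmark_scenario("fixation", scale = 0.01, seed = 42)
res <- simulate_barcoded_evolution(cfg)

fm  <- to_frequencies(res$observed)
flt <- apply_filters(fm, filter_spec(1e-4, 12, 17))
#> barcodes kept: 27 of 1000

div <- diversity_timeseries(fm)
signif(div$values[, c(1, 9, 17)], 4)
#>          0     71    142
#> 0   874.00 43.000 24.000
#> 1    23.64 15.840 16.910
#> 2    17.88 12.470 13.010
#> Inf  10.73  8.012  6.993

dm   <- build_distance_matrix(flt$fm, metric = "pearson")
tree <- linkage(dm, method = "upgma")
h    <- select_threshold(quantify_thresholds(tree, dm, grid_size = 100))
ccs  <- call_clonal_clusters(flt$fm, dm, tree, height = h)
ccs
#> <clonal_cluster_set> 6 clusters at cut height 0.1637
#>   label n_members final_frequency minor smallest_member
#> 1    C1         4         0.43097 FALSE          BC0001
#> 2    C2         4         0.24801 FALSE          BC0005
#> 3    C3         4         0.11935 FALSE          BC0009
#> 4    C4         4         0.10306 FALSE          BC0013
#> 5    C5         4         0.05953 FALSE          BC0017
#> 6    C6         7         0.03908 FALSE          BC0021
```

Reading the numbers: the 1000-barcode library collapses to 27 lineages
that ever matter (the filter removes the decaying neutral background);
richness `D_0` falls 874 → 24 while dominance diversity `D_∞` falls
10.7 → 7.0 as the sweep concentrates the population; the pipeline finds
six clonal clusters whose final population shares (43%, 25%, …, 3.9%)
descend from the still-sweeping winner C1 to the earliest outcompeted
riser C6. Against the simulator's truth the assignment scores an adjusted
Rand index of 0.85 (`evaluate_recovery()`). `plot_dynamics()`,
`plot_diversity()` and `plot_clusters()` draw the corresponding figures
and also return the exact plotted tables.

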