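---
title: "Calling dominant clonal lineages from barcode time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling dominant clonal lineages from barcode time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrack)
```

## The inference problem

Chromosomal DNA barcoding tags every founding cell of a population with a
unique, heritable sequence that amplicon sequencing can count at each
sampling time. The data are therefore a table of (barcode, time, reads),
and the frequency trajectory of each barcode traces the fortunes of one
founding lineage. Because sequencing reads only the barcode, a lineage that
acquires a beneficial mutation mid-experiment is *not* distinguishable by
genotype — only by the changed shape of its trajectory. Lineages whose
genomes confer similar fitness follow similar trajectories, so grouping
trajectories by shape recovers the clonal structure of the population: who
is sweeping, who rose and was outcompeted, who is drifting to extinction.

`clonetrack` turns that idea into a pipeline: noise filtering, effective
diversity summaries, pairwise trajectory distances, agglomerative
clustering with a threshold sweep, and LOESS consensus trajectories ranked
by final abundance. A forward Wright-Fisher simulator with known
per-lineage fitness provides ground truth for validating every stage.

## Data model and zero handling

Counts live in a dense (barcode x timepoint) matrix; (barcode, time) pairs
absent from the input table are **zero counts**, i.e. sequencing
non-detection, not missing data. Frequencies are per-timepoint fractions
`f_k(t) = counts_k(t) / total(t)`.

Zeros are handled in exactly one place: a pseudo-frequency *floor*,
`1 / (2 * max(total reads))` by default (half of one read at the deepest
timepoint), substituted for zeros **only** by log-scale consumers — the
log10 trajectory transform and log-scale plots. Diversity indices and the
filters see exact zeros; the standard Hill-number convention of dropping
zero terms from the power sum keeps `q = 0` equal to the count of barcodes
actually present.

## Noise filters

Low-frequency barcode counts are dominated by sampling noise, so barcodes
enter clustering only if

* their arithmetic mean frequency over **all** timepoints (zeros included)
  is strictly above `min_mean_frequency` (default `1e-4`), and
* they are detected (at least one read) in at least `min_persistence`
  timepoints (default 12).

Persistence counts read-count detections, not floor exceedances, because
detection is a sequencing event. Survivors are deliberately **not**
renormalised: downstream cluster abundances remain fractions of the whole
population, which is what makes the final ranking interpretable. Both
filters are idempotent and monotone in their thresholds, and the tests
assert both properties.

## Effective diversity

The Hill number of order `q`,
`D_q(t) = (sum_k f_k(t)^q)^(1/(1-q))`,
is the number of equally frequent lineages that would produce the same
diversity. `q = 0` is richness, `q = 1` the exponential of Shannon entropy
(computed as the analytic limit `exp(-sum f log f)`, not numerically near
the singularity), `q = 2` the inverse Simpson index, and `q = Inf` the
inverse of the largest frequency — dominance. The limits are implemented
analytically because both are reported routinely and evaluating
`(sum f^q)^(1/(1-q))` at `q = 1 ± 1e-8` is needlessly ill-conditioned; the
tests verify continuity of the implementation across `q = 1` to `1e-4` and
convergence to `1/max f` by `q = 100` within 5%.

## Trajectory distances

Distances are computed on `log10(max(f, floor))` by default — trajectories
span orders of magnitude, and the log view weights a tenfold change at
frequency `1e-3` equally with one at `0.1`. The linear scale is a flag
away for settings where absolute abundance changes matter.

* **Pearson distance** `1 - r(x, y)` ranges over [0, 2]; anti-correlated
  dynamics (one lineage rising as another collapses) are maximally distant.
  We use `1 - r`, not `1 - |r|` or `(1 - r)/2`, precisely to keep opposed
  dynamics apart. Constant trajectories have no defined correlation and
  are rejected with the offending barcode named; in practice the
  persistence filter removes them first.
* **Dynamic time warping** uses the canonical recurrence with local cost
  `|x_i - y_j|`, symmetric steps (insert, delete, match), no path-length
  normalisation, and an optional Sakoe-Chiba band. This exact variant is
  chosen because it is testable against brute-force enumeration of all
  warping paths, which the suite does exhaustively for series up to length
  6. DTW operates on index positions; sampling times are assumed shared
  across trajectories.

Pearson is the default metric: sampling times in serial-passage data are
aligned by design, so elastic time alignment is rarely needed and DTW costs
O(T^2) per pair.

## Clustering, the threshold sweep, and consensus

Agglomeration is implemented in the package rather than delegated to
`stats::hclust` for two reasons: merge ties are broken deterministically by
the lexicographically smallest member IDs (bit-reproducible outputs), and
centroid linkage (UPGMC) computes centroids as pointwise means in the
transformed trajectory space with the chosen metric between them — the
Lance-Williams centroid update is only valid for squared Euclidean
distances, which neither Pearson nor DTW is. UPGMA follows the unweighted
average-linkage recurrence and is verified against both a naive O(n^3)
re-implementation and `stats::hclust(method = "average")`.

Cut heights are the user's decision, supported by `quantify_thresholds()`,
which sweeps an even grid from 0 to the top merge height and records the
cluster count, the minimum distance between cluster centroid trajectories,
and the mean silhouette width. Three selection heuristics are offered:

* `"silhouette"` (default): the grid point maximising mean silhouette
  width, the standard internal criterion trading cohesion against
  separation;
* `"knee"`: the sharpest elbow (maximum second difference) of the cluster
  count curve;
* `"plateau"`: the midpoint of the longest run of constant cluster count
  (> 1 cluster).

Silhouette became the default after the other two proved structurally
fragile: the count curve's second difference is almost always maximised
where the first dense run of low-height merges ends, so the knee fires far
below any biologically meaningful level, while the widest count plateau is
almost always the final two-cluster regime, so the plateau rule fires far
above it. Both remain available for dendrograms where they are
appropriate.

Each cluster is summarised by a LOESS consensus: all member (time, value)
points are pooled unweighted and smoothed with tricube-weighted local
polynomials (span 0.75, degree 2 by default — conventional choices),
evaluated at the common timepoints, on the same scale the clustering used,
and back-transformed to frequencies (floored at the detection floor) for
reporting. Pooling is unweighted so that a cluster's consensus reflects
its typical member rather than its largest one. When a cluster has too few
points to support the local window the pointwise mean is substituted with
a warning. Note one property deliberately *not* claimed: a LOESS fit with
span 1 and degree 1 is a near-global weighted linear regression and can
leave the pointwise min/max envelope of its members whenever they are
curved; the tests pin down the properties that do hold (constants and
single linear members are reproduced exactly; a pair symmetric about a
curve yields the curve).

Clusters are ranked `C1, C2, ...` by descending summed member frequency at
the final timepoint, with ties broken by smallest member ID. Clusters
whose final summed frequency falls below `min_cluster_frequency` (default
0.01, i.e. 1% of the population) are flagged minor but never dropped.

## The Wright-Fisher simulator

`simulate_barcoded_evolution()` advances a constant-size asexual
population: each generation, lineage cell counts are redrawn
`Multinomial(N, n_i w_i / sum n_j w_j)`; beneficial mutations arrive
`Poisson(mu * n_i)` per lineage, each founding a one-cell sub-lineage with
`w + s` (fitness additive within a genome, `w = 1 + sum s`); sub-lineages
keep the parental barcode, which is the whole point — the measurement
model reads barcodes, not genotypes. Sampling draws one multinomial read
sample per timepoint at the configured depth. There is no PCR-jackpot or
extraction-bias model: read noise is pure multinomial counting noise.
Deleterious mutations are excluded by default (the supply models
beneficial contenders); the DFE can be exponential, fixed, or absent.

The truth output records every mutation (lineage, generation, s), each
barcode's cell-count and cell-weighted mean-fitness trajectories, and its
fate — `fixed` (all N cells), `extinct`, or `segregating`.

Three config extensions exist purely to construct benchmarks with known
answers: `founder_fitness` (pre-existing fitness classes),
`initial_cells` (uneven founding libraries, as real barcode libraries are),
and `fitness_events` (programmed per-barcode fitness increments at chosen
generations, recorded in the truth like any mutation).

### Benchmark scenarios and their conditions

`make_benchmark_scenario()` fixes the study conditions. At full scale the
population is `1e7` cells, `1e5` barcodes, 1125 generations, 17 evenly
spaced sampling times, `1e6` reads per sample. `scale` shrinks the
population and library proportionally; the duration contracts as
`round(1125 * scale^0.45)` and depth is floored at `1e5`. The rationale
for compressing time: per-lineage drift variance accumulates like
`integral dt / n_k(t)`, so at a hundredth of the population size a
full-length run would bury trajectory shapes in drift noise; shortening
the run while strengthening selection keeps shapes resolvable while
leaving the regime (overlapping selective sweeps at large `Ns`) intact.

The **fixation** scenario is an interference cascade: six groups of four
high-count barcodes receive programmed beneficial effects
`s = 0.16, 0.115, 0.085, 0.063, 0.046, 0.03` at staggered onsets (70%,
55%, 41%, 27%, 15%, 3.5% of the run), so each group rises once its
advantage exceeds the current population mean fitness and declines once
overtaken — six trajectory families with rises, peaks and dips at distinct
times, ending at descending population fractions (~0.37 down to ~0.04),
the strongest group still sweeping upward at the end. Founding fractions
per group were solved (by deterministic iteration of the group-level
selection recursion) so the final fractions land at those targets. The
rest of the library is ~970 neutral barcodes founded at `2e-5` of the
population each — far below the `1e-4` mean-frequency filter, so the
neutral background is excluded from clustering by the same rule a real
analysis would use. **clonal_interference** truncates the same cascade at
80% of the run, before the sweep resolves; **neutral** is pure drift on an
even library.

Within these conditions, the package's own validation (and
`scripts/acceptance.R`) asks: over 20 simulated populations, how often
does the default Pearson + UPGMA + silhouette pipeline report exactly six
clusters holding at least 1% of the population at the end? In the runs
reported by the acceptance script this holds for ~80% of seeds; the
failures cut one level too coarse (merging two adjacent families), never
spuriously inventing structure.

Note one tension the scenario resolves by construction: a lineage with
fate `fixed` holds all N cells, which would leave every other cluster at
frequency zero — incompatible with six clusters each above 1%. The
benchmark therefore ends mid-sweep with a dominant, still-rising winner;
strict fixation is exercised separately (long two-type runs in the test
suite, where the beneficial lineage does reach fate `fixed` and the rest
`extinct`).

The **fitness-class** benchmark (`make_fitness_class_config()`) founds 40
neutral, 15 `s = 0.05` and 5 `s = 0.10` barcodes in `N = 1e5` cells, 60
generations, 17 samples at depth `1e6`. The majority-neutral composition
matters: it keeps initial mean fitness low so the middle class first rises
and then falls — three distinguishable shapes (fall; rise-fall; rise)
rather than three mutually correlated monotone slopes, which Pearson
distance, being affine-invariant, cannot tell apart. Recovery is scored as
the best adjusted Rand index over all cut heights (`ari_over_cuts()`).

### What the simulator does and does not emulate

It emulates fitness-driven frequency dynamics, drift at finite N, barcode
inheritance through sub-lineages, uneven libraries, and finite sequencing
depth. It does not emulate PCR jackpotting, extraction bias, barcode
sequencing errors or chimeras, serial-passage bottlenecks, time-varying
environments, or ecological (frequency-dependent) interactions. Passing
the benchmark therefore shows that the pipeline recovers fitness structure
from clean count noise at realistic scales — not that it is robust to
artifact-laden libraries, which require upstream correction tools.

## Numerical choices and degenerate inputs

* Frequency columns must sum to 1 within `1e-9`; Hill-number inputs are
  validated to the same tolerance.
* UPGMA/UPGMC merge ties are broken by smallest member IDs; rank ties by
  smallest member ID; every output is bit-reproducible given a seed.
* `cut_linkage()` defines clusters as maximal subtrees whose internal
  merge heights do not exceed the cut, which remains well defined under
  the height inversions centroid linkage can produce.
* Degenerate LOESS windows fall back to the pointwise mean with a warning;
  zero-variance trajectories are rejected before Pearson with the barcode
  named; a timepoint with zero total reads is an error naming the
  timepoint; empty timepoints in diversity profiles yield `NA` plus a
  warning.
* Problem sizes used in the validation suite: the cascade benchmark runs
  at `scale = 0.01` (1e5 cells, 1000 barcodes, 142 generations, 20
  seeds); DTW is checked against brute force on 500 random pairs of
  length <= 6; UPGMA against the naive reference on 200 random matrices
  (n <= 8); the fixation-probability check uses 1e4 two-type replicates at
  `N = 1e4`, `s = 0.01` against the diffusion prediction
  `(1 - e^{-2s})/(1 - e^{-2Ns})`.

## Known limitations

* Pearson distance cannot separate lineage families whose log-trajectories
  differ only by slope (affine invariance); families must differ in shape
  — peak or onset timing. This is intrinsic to correlation distance, not
  to the implementation; DTW on log frequencies is the built-in
  alternative.
* The threshold heuristics are conveniences; on messy dendrograms the
  quantification table should be inspected and the cut chosen by eye.
* Frequencies are relative: a cluster can "rise" because the rest of the
  population collapses. Interpretation against absolute population size
  needs external calibration.
* The filters are deterministic thresholds, not an error model; barcodes
  hovering at the detection limit pass or fail by sampling luck.
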