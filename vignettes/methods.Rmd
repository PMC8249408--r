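---
title: "Multiscale spatial statistics of tumor-infiltrating lymphocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale spatial statistics of tumor-infiltrating lymphocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilspatial)
```

## The problem

Multiplex immunohistochemistry reduces a tumor section to a marked planar
point pattern: every cell gets Cartesian coordinates in micrometers, a
phenotype (CD20+ B cell, CD3+ T lineage, pan-cytokeratin+ cancer cell, other)
and a tissue category (inside a cancer-cell island versus stroma), inside a
pathologist-outlined region of interest (ROI). Average densities discard the
spatial arrangement of these cells, yet in triple-negative breast cancer the
*arrangement* of B cells — dispersed across the tissue versus confined in a
few spots — carries prognostic information that density alone does not.
`tilspatial` implements the statistics needed to quantify that arrangement and
compare it between outcome groups, together with a synthetic-tissue generator
so the whole chain can be validated without patient data.

## Occupancy and binary questions

The tissue is tiled with a grid of squares of side $L$. Each square is scored
1 or 0 by a *binary question* — "is there at least one stromal B cell in this
square?" — and squares containing no cells at all are omitted: they lie
outside the tissue. With $n(L)$ squares scoring 1 out of $N(L)$ squares
containing any cell, the occupancy is $n(L)/N(L)$, an estimate of the
probability that an occupied square answers yes. Varying $L$ from 10 to
600 µm profiles the spatial distribution across scales. Binary questions
compose a phenotype set with a tissue scope (island/stroma/any) and a cluster
membership scope (isolated, in any LC, in heterotypic LCs, in pure-T LCs),
which covers every combination used in the analysis.

Grid geometry is pinned down so results are deterministic: squares are
half-open, anchored at the minimum corner of the ROI bounding box, and a cell
sitting exactly on the maximal edge is clamped into the last square. For
simulated reference patterns there is no tissue to delimit, so the
denominator optionally counts every square intersecting the window
(`denominator = "window"`).

The *occupancy AUC* integrates the occupancy curve by trapezoids against
$\ln L$. The logarithmic abscissa weights the 60-fold range of $L$
scale-freely; a linear abscissa is available as an option.

## Fractal dimension and the FD difference

For a spatially uniform, area-filling arrangement the number of flagged
squares scales as $n(L) \propto 1/L^2$; for cells concentrated on isolated
points it is flat in $L$. In between, $n(L) = A/L^{\delta}$ defines a
box-counting fractal dimension $\delta \le 2$. The package estimates it as
the least-squares slope $s$ of $\ln n(L)$ versus $\ln(1/L)$ (natural
logarithms) over a window of scales, without taking the $L \to 0$ limit —
the interest is precisely how the exponent changes with scale.

Two windows are fitted: small scales 10–40 µm and large scales 200–600 µm,
bracketing the typical nearest-neighbor spacing of lymphocytes (tens of
micrometers). Their difference

$$\Delta s = s_{\mathrm{large}} - s_{\mathrm{small}}$$

measures spatial dispersion: dispersed cells look two-dimensional at large
scales and point-like at small scales (large $\Delta s$), while a
scale-free, self-similar arrangement keeps the same slope everywhere
($\Delta s \approx 0$).

The slope is fitted on the *un-normalized* $\ln n(L)$. Dividing by $N(L)$
merely shifts the curve when $N(L)$ itself follows the window geometry, and
the large-scale slope near 2 expected of a uniform random pattern only comes
out of the un-normalized definition; the normalized variant (useful for
overlaying curves from images of different sizes) is available via
`normalized = TRUE`. L values with $n(L) = 0$ are dropped from a fit and at
least three must remain, otherwise an insufficient-data error is raised
rather than returning a slope from two points.

The default ladder of 13 geometrically spaced sides,
`r paste(default_L_ladder(), collapse = ", ")` µm, spans the 10–600 µm range;
members at most 40 µm feed the small-scale fit, members at least 200 µm the
large-scale fit. The geometric spacing makes the points equidistant on the
log-log plot so no scale dominates the regression.

A closed form anchors all of this: a homogeneous Poisson process of intensity
$\lambda$ occupies a square of side $L$ with probability
$1 - e^{-\lambda L^2}$ (`expected_poisson_occupancy()`). The implied slopes
over the two default windows — 2 (all boxes occupied at 300 points/mm²) and
0.151 — are reproduced by simulation in the test suite and the acceptance
script.

## Lymphocyte clusters and TLS

Lymphocyte clusters (LCs) are found by density-based clustering (DBSCAN
semantics) over the pooled lymphocytes — B plus all T-lineage phenotypes. The
criterion "at least five lymphocytes within a circle of 40 µm diameter" is
implemented as `eps = 20` µm (the circle *radius*) and `min_pts = 5`
*counting the center cell*: with those readings, five contiguous cells of
10 µm diameter along a line make the middle cell a core point and form
exactly one cluster, reproducing the construction that motivates the rule.
Both readings of the diameter-versus-radius ambiguity are representable since
`cluster_params()` is configurable. Border cells reachable from several
clusters join the cluster of their lowest-indexed core neighbor in stable
input order — an arbitrary but deterministic tie-break, so a pattern always
partitions identically across runs and platforms.

Clusters are typed by composition: pure T (no B member), pure B (no
T-lineage member), otherwise heterotypic. Pure-B LCs are detected and
reported but excluded from size-distribution analyses, which index only
pure-T and heterotypic types; pure-B clusters are rare and tiny in both real
and synthetic tissue.

Tertiary lymphoid structures are the dense subset of LCs: a cluster is
flagged TLS when a second density pass over its own members with
`eps = 70` µm, `min_pts = 200` yields at least one core cell — that is, some
member has 200 of its fellow members within a 70 µm radius. Flagging never
alters cluster membership. The pass is scoped within detected LCs because a
TLS is by construction a subset of an LC.

For clusters of one type the size distribution counts $P(s)$ clusters of
size $s$; with $N = \sum_s P(s)\,s$ lymphocytes in such clusters the
normalized distribution is $P(s)/N$ and the cumulative fraction
$f(s) = \sum_{s' \le s} P(s')\,s'/N$ is the fraction of those lymphocytes
living in clusters of size $s$ or smaller. The identity
$\sum_s P(s)\,s/N = 1$ holds exactly by construction and is asserted to
machine precision in the tests.

## Densities and distances

Every density divides a count by the full ROI area in mm² — never by the
island or stroma area alone — so island and stroma densities of any phenotype
set add exactly to the overall density. The distance from an LC to cancer is
the exact minimum Euclidean distance between a cluster member and a
cancer-phenotype cell carrying the island tissue mark (lymphocytes sitting
inside islands are not targets: cancer cells are what define an island). The
brute-force minimum is the default and is feasible at these pattern sizes;
per-patient summaries report the mean of per-LC distances, with medians
alongside.

## Cohort statistics

Summaries follow a per-patient-first rule: each metric is computed per
patient, and cohorts are compared on those per-patient values — cells are
never pooled across patients. Group comparison reports the classical
equal-variance two-sided Student t-test (the form named by convention;
a Welch variant is included in the machine-readable output), the ROC AUC
computed as $P(\text{good} > \text{poor}) + \tfrac12 P(=)$ from ranks (ties
count one half; the direction is never auto-flipped, so AUC below 0.5 is
reported as-is), and a two-sided Mann–Whitney p-value. No multiple-testing
correction is applied; raw p-values are reported and labeled as such.

Relapse-free-survival curves use the product-limit estimator (via the
`survival` package) after stratifying patients at a threshold placed so that
two thirds fall in the upper stratum: the $\lceil n/3\rceil$-th smallest
value, interpolated midway to the next distinct value. When ties straddle
the cut, the largest midpoint keeping at least $\lfloor 2n/3\rfloor$ patients
strictly above is used; if no midpoint reaches that, the one with the largest
upper stratum. A log-rank test accompanies the curves as a standard
companion statistic (it is an addition of this package, not part of the
original analysis convention).

## The synthetic-tissue generator

`synthesize_patient()` composes, in a rectangular window: cancer cells
sampled on disc-shaped islands; a dispersed homogeneous Poisson lymphocyte
component; a clustered Thomas-type component whose parents sit at a
controlled mean offset from island boundaries; and island-infiltrating
lymphocytes. Phenotypes are i.i.d. B with probability `b_fraction`, else T;
tissue category follows disc containment; the ROI is the window.

`sample_thomas()` implements the stationary cluster process restricted to the
window: parents are drawn on a 3σ-buffered window and each parent's offspring
count is thinned by the exact analytic probability of landing inside the
window, with truncated-normal conditional placement. This removes the edge
bias a naive clip would introduce into expected counts, and makes the
large-σ limit (which must converge to a Poisson pattern of matched intensity)
cheap to simulate and test.

Default study conditions: the Poisson *reference* uses a 3 × 3 mm window at
300 points/mm². Synthetic patients use a 2 × 2 mm window — a realistic
imaged-ROI area of a few mm² — and cohorts default to 24 good and 12 poor
patients. The good profile has more dispersed lymphocytes
(120 versus 50 /mm²), more and tighter cluster parents (12 versus 5 /mm²,
σ 10 versus 15 µm), smaller clusters (mean 10 versus 30 lymphocytes), heavier
island infiltration (25 versus 5 /mm²), closer clusters (offset 40 versus
150 µm from island boundaries) and a lower B fraction (0.30 versus 0.40).
These constants were chosen once to encode the qualitative good-versus-poor
effect directions the analysis is designed to detect; they are a constructed
test bed, not a calibrated model of tumor biology. Poor patients relapse
uniformly within 6–36 months; good patients are censored event-free at
60–120 months.

What the generator does *not* emulate — and hence what passing tests do not
show about real tissue: irregular (non-disc) island shapes, spatial
correlation between phenotype and position beyond the island/cluster
structure, B/T zonation inside clusters, cell-size exclusion effects at
digitization resolution, and any within-cohort coupling between cluster size
and island distance (the size–distance correlation is therefore exercised
for correctness of the statistic, not recovered as an effect). Real TLS are
also rarer and denser than anything the default profiles produce.

## Numerical choices and degenerate inputs

* Empty patterns are rejected at the I/O layer; grid overlays on a pattern
  with zero cells are an error (the denominator would be 0).
* Duplicate coordinates are a warning, not an error — two nuclei can share a
  centroid at digitization resolution. Duplicate cell ids are an error.
* A missing ROI area falls back to the cell bounding-box area, always flagged
  in the validation report, never silent.
* An ROI polygon must agree with a declared area within 0.1%; cells outside
  the polygon are violations.
* Metrics that cannot be computed for a patient (no clusters of a type, too
  few occupied scales for an FD fit, no cancer cells for a distance) are
  `NA` in the registry — explicitly missing rather than zero — and cohort
  comparisons drop them per group.
* All randomness flows from explicit integer seeds; cohort generation spawns
  per-patient sub-seeds from the master seed so per-patient results do not
  depend on cohort ordering.

## Problem sizes used by the validation suite

The test suite and the analysis scripts run at desk scale: Poisson references
at 300 points/mm² in 3 × 3 mm (about 2 700 points, 20 replicates), oracle
equivalence on instances of up to 200 lymphocytes (50 random instances), the
normalization identity on 50 synthetic patients in 1 × 1 mm windows, and
parameter recovery on ten 24 + 12 cohorts in 2 × 2 mm windows. These sizes
were chosen as the smallest at which the asserted statistics are stable;
every documented property is independent of them.

## Known limitations

* The deposited-cohort benchmark needs the downloaded patient record; the
  package ships the converter and benchmark runner but cannot validate
  against it offline, and the corresponding acceptance check reports as
  failing until the converted record is supplied.
* DBSCAN's diameter-versus-radius reading and whether the center cell counts
  toward `min_pts` are declared conventions (documented above), not inferred
  from upstream software.
* FD fits use a fixed L ladder; the exact ladder used upstream of this
  package's conventions is not standardized, and slopes shift by a few
  hundredths under alternative ladders inside the same windows.
* Geometry helpers (polygon area, point-in-polygon) assume simple polygons
  without holes.
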