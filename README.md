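# tilspatial

Multiscale spatial statistics of tumor-infiltrating lymphocytes (TILs) from
multiplex immunohistochemistry cell coordinates.

## The problem

Imaging a tumor section with multiplex IHC yields a marked planar point
pattern: each cell has coordinates in micrometers, a phenotype (CD20+ B cell,
CD3+ T lineage, cancer, other) and a tissue category (cancer-cell island vs
stroma) inside a pathologist-outlined region of interest (ROI). In
triple-negative breast cancer, whether B cells are *spatially dispersed* or
*confined* carries prognostic information that their average density does
not. This package implements the statistics needed to quantify and compare
that arrangement, for anyone analyzing cell-coordinate tables from tumor
sections:

* **Occupancy** — tile the tissue with squares of side `L` (10–600 µm), score
  each square by a binary question ("≥ 1 stromal B cell here?"), omit squares
  with no cells at all; the occupancy is `n(L)/N(L)` and its area under the
  curve (against `ln L`) summarizes dispersion across scales.
* **Fractal dimension (FD)** — the least-squares slope `s` of `ln n(L)` vs
  `ln(1/L)` over a scale window; with `n(L) = A/L^δ` this estimates the
  box-counting exponent `δ ≤ 2` without the `L → 0` limit.
* **FD difference** — `Δs = s_large − s_small` between the 200–600 µm and
  10–40 µm windows. Dispersed cells are area-filling at large scales and
  point-like at small scales (large `Δs`); a near-fractal, confined
  arrangement has `Δs ≈ 0`. A uniform Poisson process at 300 points/mm² has
  `s_large ≈ 2.1` and `s_small ≈ 0.15`.
* **Lymphocyte clusters (LCs)** — density-based clustering (DBSCAN semantics,
  `eps` 20 µm, `min_pts` 5 counting the center) of pooled B and T cells;
  clusters are typed pure-T / heterotypic / pure-B, and tertiary lymphoid
  structures (TLS) are the dense subset holding ≥ 200 lymphocytes within a
  70 µm radius. Normalized cluster-size distributions satisfy
  `Σ P(s)·s / N = 1` exactly.
* **Region-resolved densities and distances** — counts over phenotype ×
  compartment × isolation divided by the full ROI area; exact minimum
  distance from each LC to the nearest cancer-island cell.
* **Cohort statistics** — per-patient-first averaging, two-sided Student
  t-tests, ROC AUC with ties at ½, Mann–Whitney, Kaplan–Meier relapse-free
  survival with a two-thirds stratification threshold.
* **Synthetic tissue** — Poisson and Thomas-type lymphocyte processes on
  disc-island geometries with good/poor outcome profiles, so every stage is
  testable without patient data.

## Worked example

```r
library(tilspatial)

path <- system.file("extdata", "synthetic_example.csv", package = "tilspatial")
pat <- read_pattern_table(path, roi_area_mm2 = 0.25, outcome = "good")
pat
#> <til_pattern> patient synthetic_example (good): 88 cells (59 lymphocytes), ROI 0.25 mm^2

det <- detect_clusters(pat)                      # eps 20 um, min_pts 5
cluster_table(det$clusters, pat$patient_id)[, c("cluster_id", "size", "lc_type", "n_B", "n_T")]
#>   cluster_id size     lc_type n_B n_T
#> 1          1   19 heterotypic   5  14

region_density(pat, "B", "cancer_island")$density   # B cells in islands / ROI area
#> [1] 8

cluster_island_distances(det$clusters, pat)[, c("cluster_id", "size", "distance_um")]
#>   cluster_id size distance_um
#> 1          1   19    55.63373
```

So this 0.25 mm² example holds one heterotypic LC of 19 lymphocytes (5 B,
14 T) whose nearest cancer-island cell lies 55.6 µm away, 40 isolated
lymphocytes, and 8 island-infiltrating B cells per mm² of ROI. On a full-size
synthetic patient the dispersion statistic reads:

```r
good <- synthesize_patient(default_profiles()$good, seed = 8)
fd_difference(good, binary_question("B", "stroma"))
#> <fd_difference> s_large 1.5613 - s_small 0.1877 = delta_s 1.3736
```

## Analysis workflow

Numbered drivers under `analysis/` reproduce the full study flow on synthetic
data, writing tables under `results/`:

1. `01_simulate_cohort.R` — simulate 24 good / 12 poor patients with survival
   labels and write per-patient pattern CSVs.
2. `02_poisson_reference.R` — occupancy vs the closed form
   `1 − exp(−λL²)` and the small/large-scale FD of the Poisson reference.
3. `03_cohort_pipeline.R` — run the full per-patient metric registry and the
   good-vs-poor comparison report.
4. `04_survival_and_correlation.R` — Kaplan–Meier stratification at the
   two-thirds threshold, and the LC size–distance Pearson correlation.
5. `05_benchmark_deposited.R` — optional benchmark against a downloaded
   patient point-pattern record (RDS of `ppp`-format patterns with
   `Phenotype` and `Tissue.Category` marks); converts it to pattern CSVs via
   `read_deposited_patterns()` and recomputes the headline cohort means. To
   enable the corresponding test, place the converted CSVs and a
   `cohort_manifest.csv` under `tests/testthat/deposited/`.

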