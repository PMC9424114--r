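---
title: "Methods: spatial immunophenotyping of regulatory T cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial immunophenotyping of regulatory T cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`tregspatial` analyses multiplex fluorescence immunohistochemistry (mIHC) of
tissue-microarray (TMA) cores from colorectal tumors. It starts from the
exported per-cell tables of an image-analysis system (one row per segmented
cell: coordinates in micrometres, tissue-region label, mean fluorescence
intensity per marker) and ends at survival models for 5-year relapse-free
survival (RFS). The stages are:

1. **Marker scoring.** A cell is positive for a marker when its mean
   intensity is at or above a threshold $\tau$ set per marker, stain and
   patient series. Positivity thresholds are deliberately *inputs*: in
   practice they are set by visual inspection of images and intensity
   distributions, so the package never derives them silently
   (`suggest_thresholds()` exists as an explicit helper that proposes the
   valley of a two-component mixture).
2. **Phenotypes.** Each cell gets exactly one of four categories:
   triple-positive Treg (CD4+/CD25+/FOXP3+), FOXP3+ (not triple-positive),
   CD8+, or other. For rare co-positive cells the precedence is
   tpTreg > FOXP3 > CD8 > other; conflicts are counted and logged. Treg
   identity takes precedence because the Treg subpopulations are the object
   of study.
3. **Infiltration scores.** Positive cells per mm² of tissue, analysed as
   $\log_2(\text{density} + 1)$; the $+1$ keeps cores with zero positive
   cells. Compartment scores (intraepithelial / stromal) use per-cell region
   labels for the counts and mask-derived areas for the denominators.
4. **Treg profiling.** Triple-positive Tregs are split into a 2×2 of
   CD25 {High, Low} × FOXP3 {High, Low} at the nearest-rank 75th percentile
   of the positive-cell intensities (both markers), and each sample is
   summarized by its mean CD25 and mean FOXP3 across tp-Tregs. Samples are
   classed mean-CD25 High / Low / Negative (Negative = no tp-Tregs) at a
   per-series cutoff; `cutoff = "auto"` proposes the deepest
   kernel-density valley between the two largest modes (Gaussian KDE,
   Silverman bandwidth) and refuses unimodal distributions, echoing the
   chosen value for manual confirmation.
5. **Spatial proximity.** Cell coordinates are tessellated into a Voronoi
   diagram; two cells are neighbors when their tissue-clipped Voronoi regions
   share a boundary segment longer than $\varepsilon$. The statistic is the
   number of CD8+ cells with at least one Treg neighbor
   (target = tp-Treg or any FOXP3+ cell). Its null distribution comes from
   B = 2000 Monte-Carlo label permutations that hold every cell position and
   the category counts fixed while shuffling which cell carries which
   category. A sample is classified *significant* when the observed count
   strictly exceeds the nearest-rank 95th percentile of the permuted counts
   (the 1900th of 2000 sorted values); samples without CD8+ cells are
   excluded from spatial analysis, and samples without target cells are
   non-significant by definition. No multiplicity correction is applied
   across samples.
6. **Outcome analysis.** RFS is time from surgery to recurrence or death
   from any cause, administratively censored at 60 months; the stage I–III
   analysis keeps R0-resected patients and excludes pre-operative
   radiotherapy and synchronous primaries (stage IV is analysed separately
   for overall survival). Kaplan–Meier, log-rank and Cox models are
   delegated to the `survival` package (Efron ties, cohort-stratified);
   variable selection uses bootstrap resampling with p-value-based backward
   elimination and a 30% retention cut.

# Why a permutation test rather than the neighbor fraction

The fraction of CD8+ cells with a Treg neighbor rises mechanically with Treg
abundance, so it mostly restates the density scores. The permutation test
conditions on the observed category counts and positions: it asks whether the
*arrangement* is more interdigitated than chance, given exactly those cells.
The package keeps `neighbor_fraction()` available, and its property tests
demonstrate the rationale: under label randomness the fraction correlates
strongly with target abundance while the permutation classification does not.

# Numerical choices

* **Percentiles** are nearest-rank order statistics (the ⌈qn⌉-th of the
  ascending sort) everywhere — deterministic, interpolation-free, and
  directly checkable against a sort oracle.
* **Every High/Low rule is strict `>`** against its cutoff (median
  dichotomization, 75th-percentile subgroups, mean-CD25 class, the
  permutation rule), so boundary values fall Low and ties at the critical
  value are non-significant. One uniform convention avoids per-stage
  surprises.
* **Positivity is closed (`>=`)** at $\tau$: the conventional reading of
  "thresholded at" for intensity data.
* **Duplicate coordinates** (segmentation artifacts) are jittered by a seeded
  uniform offset below 0.01 µm — two orders of magnitude below the 0.5 µm
  pixel — because Voronoi regions are undefined for coincident sites; the
  count of jittered cells is logged.
* **Shared-boundary threshold** $\varepsilon = 10^{-6}$ µm excludes
  point-contacts arising from cocircular degeneracies.
* **Clipping** is exact: each Voronoi edge segment is intersected with the
  outline rings (crossing parameters plus midpoint parity), so holes and
  excluded regions break adjacency — cells facing each other across a
  necrotic gap are not neighbors. All fragments of one cell's clipped region
  remain a single node.
* **Outline fallback.** When no segmentation mask is available the outline is
  the convex hull of the cells buffered by the median nearest-neighbor
  distance (logged); masks are traced at the half-level between foreground
  and background pixel centres, which makes polygon areas match pixel-count
  areas exactly on axis-aligned boundaries.
* **Reproducibility.** One master seed per run; per-sample sub-seeds are
  drawn once from it (`stream_seeds()`), so per-sample results do not depend
  on processing order. Permutation assignments are drawn against a canonical
  node order (by x, then y), making the permuted-count multiset invariant to
  the row order of the input table.

# The synthetic cohort: what it emulates, and what it does not

The patient-level data this pipeline was designed around are not public, so
the package ships a generator (`synthetic_config()`, `generate_sample()`,
`generate_cohort()`) that serves as the test bed for every stage. Its
defaults were calibrated once, against the published summary statistics of
the reference cohorts, and then frozen:

* **Geometry**: circular cores of 1.0 mm (0.6 mm available), uniform cell
  positions, ~1500 cells/mm² by default — a desk-scale compromise; real
  inForm-era cores contain a similar order of magnitude.
* **Abundance**: expected category proportions CD8 10%, FOXP3-only 5%,
  tp-Treg 5%, other 80%, with log-normal per-sample random effects
  (SD 0.8–0.9 on the log scale) that make the density distributions
  right-skewed; the FOXP3 and tp-Treg effects are correlated (0.45) so that
  the *scored* FOXP3+ vs tp-Treg log2 densities correlate at r ≈ 0.85 —
  part of the correlation is structural, because tp-Tregs are FOXP3+ cells.
* **Intensities**: each marker is a two-component log-normal
  (background vs positive); the default thresholds sit in the valley, so the
  calling stage recovers the generating categories almost perfectly and the
  calibration targets are measured *through the pipeline*, not from the
  latent truth. Within tp-Tregs, CD25 and FOXP3 come from a Gaussian copula
  (ρ = 0.90) and per-sample additive effects on the positive-component
  means (SD 0.273 for CD25, 0.51 for FOXP3). These four numbers reproduce,
  at 500 cores: per-sample mean-CD25 10th/90th percentiles ≈ 3.9/9.1,
  mean-FOXP3 ≈ 1.3/4.8, and a pooled CD25-High/FOXP3-High fraction ≈ 16%
  under the 75th-percentile thresholds.
* **Attraction**: the alternative hypothesis for the spatial test places
  Treg labels by weighted sampling without replacement with weight
  $\exp(\theta e^{-d/\sigma})$, where $d$ is the distance to the nearest
  CD8 cell and $\sigma$ = 20 µm (one to two cell diameters — "neighboring"
  in the Voronoi sense is short-range). θ = 0 is *exactly* the permutation
  test's null; category counts are preserved for every θ. A distance-kernel
  label assignment was chosen over a pairwise Gibbs process because it keeps
  counts exact, costs nothing, and nulls cleanly.
* **Survival**: exponential baseline hazard (0.0065/month, ≈35–38% 5-year
  event rate) under proportional hazards, with the multivariable effect
  sizes of the reference analysis as simulation truth (HR 0.62 for
  intraepithelial-CD8 High, 1.35 for mean-CD25 High, 1.36 for significant
  proximity, pT/pN/MSI/age at their reported values), uniform drop-out, and
  administrative censoring at 60 months. For survival-scale cohorts the
  immune feature indicators are drawn from their cohort prevalences (50% /
  14% / 18%) rather than recomputed from per-patient cell data — hazard-ratio
  recovery depends only on the indicators, and this keeps a 50-replicate
  recovery study of n = 1000 cohorts within desk scale. Cell-level tables
  can be attached (`generate_cells = TRUE`) for end-to-end runs at smaller n.

The generator does **not** emulate: stain spectra or spectral unmixing,
segmentation error, autofluorescence, batch effects beyond the sample-level
random effect, non-circular or fragmented cores, or spatial structure in the
epithelial/stromal partition beyond a central epithelial disc (40% of core
area). Passing tests on synthetic data therefore demonstrate the
*correctness and operating characteristics of the algorithms* under the
stated generative model — not the biological validity of any threshold or
cutoff on real images.

# Operating characteristics of the spatial test

Two designed studies characterize the test (they run in the test suite):

* **Size.** At θ = 0 with ~300 cells/core (density 382/mm², B = 500,
  300 cores), the observed significant-classification rate is ≈ 0.023.
  The test is deliberately conservative: the neighbor count is integer-valued
  with a standard deviation of only ~2.5 at these counts, so the strict `>`
  rule discards the point mass at the critical value (~0.02–0.03 of
  probability), pulling the size well below the nominal 5%. At ~1200
  cells/core the discreteness is finer and the size rises toward ~0.03.
* **Power.** The standard power grid runs at the default density
  (1500/mm², ~1180 cells/core) with fixed expected category counts
  (abundance random effects off — size and power are properties of the test
  *at given counts*, so the study controls them). The flag rate is
  monotone in θ: ≈0.03, 0.18, 0.40 and 1.00 at θ = 0, 1, 2, 5 (40 cores
  per θ, B = 500). At ~300 cells/core the same θ = 5 attraction yields only
  ~0.2–0.4 power — with ~30 CD8 and ~15 tp-Treg cells the attainable count
  barely clears the null's 95th percentile — which is why the power study is
  defined at the default density.

# Design decisions on genuinely open points

* **Scope of the 75th-percentile Treg thresholds**: pooled per patient
  series by default (one cohort-level subgroup definition, matching a single
  cohort-level High/High fraction); per-sample thresholds remain available
  via `scope = "per_sample"`.
* **Backward-elimination stay criterion**: p ≤ 0.157, the
  AIC-equivalent for one degree of freedom, configurable; the referenced
  selection procedure names neither its criterion nor its factor handling,
  so factor terms survive on their smallest coefficient p value.
  Fractional-polynomial transformation of continuous covariates is out of
  scope; continuous covariates enter linearly (documented limitation).
* **pT recoding**: pT1 and pT2 are combined as the reference level in the
  shipped model frame (`rfs_model_frame()`), as a recoding rule rather than
  hard-coded model structure.
* **Mean-CD25 "auto" cutoff**: the KDE-valley rule formalizes
  "the point between the two maxima"; it requires ≥ 30 samples with
  tp-Tregs and refuses unimodal densities rather than guessing.
* **OS5 exclusion coding**: for the stage-IV overall-survival analysis the
  non-stage-IV exclusions are recorded under the `stageIV` reason code (the
  stage criterion failed), keeping one reason enumeration for both
  endpoints.

# Problem sizes

The shipped tests and the acceptance script use: 500 cores for generator
calibration; 300 cores of ~300 cells (B = 500) for the size study; 40 cores
per θ at ~1180 cells (B = 500) for the power grid; 200 random 30-point
patterns for the tessellation oracle; and 30–50 replicate cohorts of
n = 1000 patients for hazard-ratio recovery. These sizes give Monte-Carlo
standard errors comfortably inside the assertion bands while keeping a full
run in minutes on one core.

# Known limitations

* Threshold transfer across staining batches is the user's responsibility;
  the package treats thresholds as per-series constants.
* The Treg stain carries no epithelial marker, so the spatial test is not
  stratified by compartment (whole-core only).
* Voronoi adjacency at the tissue boundary depends on the outline source;
  the buffered-hull fallback is coarser than a segmentation mask and tends
  to keep more peripheral adjacencies.
* The survival generator is exponential-baseline PH; it supports effect
  *recovery* checks, not baseline-shape inference.
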