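---
title: "Methods: modelling adolescent maturation of functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling adolescent maturation of functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`devfc` implements an end-to-end analysis of how resting-state
functional connectivity (FC) matures across adolescence in an
accelerated-longitudinal cohort: subjects enter at different ages
between 14 and 26 and contribute one to three scans, so the age range is
covered by overlapping short longitudinal windows rather than by
following one cohort for twelve years. This vignette documents the
modelling choices; the README shows a worked example.

```{r setup, eval = FALSE}
library(devfc)
```

## Head-motion quality control

Head motion is the dominant artefact in developmental FC studies
because motion is itself age-correlated. The package implements a
standard defence in depth:

- **Framewise displacement** (`framewise_displacement()`): Power-style
  FD, the sum of absolute volume-to-volume changes in the three
  translations plus the three rotations converted to arc length on a
  50 mm sphere. A 0.002-rad step on all three rotation axes therefore
  scores 3 × 0.002 × 50 = 0.3 mm.
- **Scan exclusion** (`scan_exclusion()`): a scan is dropped when mean
  FD > 0.3 mm or maximum FD > 1.3 mm.
- **Low-signal regions** (`low_signal_region_filter()`): regional mean
  intensities are z-scored *within* each scan; a region is excluded if
  its z falls below −1.96 in any scan. The within-scan convention makes
  the filter insensitive to global intensity scaling between scans.
- **Denoising** (`fd_regress()`, `global_signal_regress()`):
  `fd_regress` fits, per edge, an ordinary least-squares regression of
  FC on mean FD across scans and removes the fitted motion component
  while keeping the edge's mean level, so downstream growth models see
  level-preserved FC. The fit is pooled across all scans (one slope per
  edge), which is the regime the QC-FC diagnostic probes.
- **QC-FC** (`qcfc()`): per-edge Pearson correlation between FC and
  mean FD across scans, summarised by its median and by the Spearman
  correlation of QC-FC with inter-centroid distance (distance
  dependence). After in-sample FD regression the per-edge correlations
  are zero up to floating-point dust; ranks of such dust are noise, so
  the distance-dependence statistic is reported as exactly 0 whenever
  all |QC-FC| < 1e-8.

Regional time series can be band-limited with a maximal-overlap
discrete wavelet transform (Daubechies-4, `wavelet_bandpass()`); the
retained levels default to the scales that cover the 0.01–0.1 Hz band
at the scan's repetition time (`default_wavelet_levels()`).

## Per-edge growth model

Each edge's FC is modelled across scans as

FC ~ age + sex + site + (1 | subject)

a linear mixed model with a random intercept per subject, fitted by
REML (`fit_growth()`). Because the covariance has a single-block
structure, the REML criterion is profiled down to one scalar, the
variance ratio λ = σ²_subject / σ²_residual, and maximised by
golden-section search; the inverse covariance per subject has the
closed form V⁻¹ = I − (λ / (1 + n λ)) J. When every subject has exactly
one scan the random intercept is unidentifiable and the model reduces
*exactly* to ordinary least squares (`method = "OLS-fallback"`).
The test suite checks the fixed effects against a dense generalised
least-squares oracle at the same λ (1e-6 agreement) and against
`lme4::lmer` on balanced designs.

Two derived quantities summarise each edge: `fc14`, the model
prediction at age 14 (baseline connectivity), and `delta_14_26`,
defined as exactly 12 × the annual age slope (change across the studied
window).

## Maturational Index

The Maturational Index (MI, `maturational_index()`) of a region is the
Spearman correlation, over the edges incident to it, between baseline
FC (`fc14`) and change (`delta_14_26`). MI > 0 is *conservative*
maturation (strong edges strengthen further), MI < 0 is *disruptive*
(weak edges strengthen, strong ones weaken). Regions with fewer than
`min_edges` (default 10) estimable incident edges are marked
indeterminate rather than given a noisy value. Because MI is a rank
correlation it is invariant to monotone transforms of either axis, and
identical whether change is expressed per year or per 12 years.

## Spin permutation null

Regional maps are spatially autocorrelated, so parametric p-values for
map-to-map correlations are anti-conservative. The package uses a spin
permutation test: cortical regions carry unit-sphere coordinates, a
uniform (Haar) random rotation is applied to the left-hemisphere
sphere and its sagittal mirror image to the right-hemisphere sphere,
and values are reassigned by greedy bijective nearest-neighbour
matching in ascending-distance order (`generate_spins()`). The
two-sided empirical p is (1 + #{|null| ≥ |observed|}) / (n_spins + 1),
so the minimal attainable p is 1/(n_spins + 1).

Design notes worth knowing:

- Each hemisphere is modelled as its own full sphere (the surface
  inflation convention), so every rotation maps the support onto
  itself and rotated points always have nearby match candidates.
- Synthetic cortical centroids are a quasi-uniform Fibonacci lattice
  (`make_parcellation()`). Clustered random centroids would give the
  bijective reassignment a heavy error tail wherever density
  fluctuates, which measurably inflates the false-positive rate.
- Calibration is resolution-dependent: at 1000 regions with 45 mm
  smooth Gaussian-process null maps (`generate_null_map()`) the
  rejection rate at α = 0.05 sits inside the 95% binomial band (the
  acceptance suite verifies this). At coarse parcellations (a few tens
  of regions) nearest-neighbour reassignment degrades the rotation and
  the test becomes mildly anti-conservative — a known limitation of
  spin tests generally, not specific to this implementation.
- At coarse resolution a small-angle rotation can reproduce the
  identity permutation; self-comparisons then tie the observed
  statistic and the empirical p counts those ties.

## Colocation battery

`colocate_battery()` correlates the cortical MI map with a battery of
continuous annotation maps (Spearman over the shared coverage), spins
the MI map for the null, and controls the false discovery rate across
the battery with Benjamini–Hochberg over the spin p-values. The battery
size used for FDR is recorded as an attribute; maps with insufficient
overlap shrink it with a warning. Categorical annotations are
summarised descriptively by `class_profile()` (per-class MI
distributions), with no per-class test.

## Synthetic cohort with planted ground truth

`simulation_config()` + `sample_cohort_design()` +
`plant_edge_trajectories()` + `simulate_edge_fc()` generate an
accelerated-longitudinal cohort in which each region's true
baseline/change coupling is planted (default alternating ±0.6), motion
confounds of configurable strength and distance dependence can be
injected, and annotation maps with known coupling to the true MI map
can be produced (`make_annotation_maps()`). The generator returns the
ground truth alongside the data, which is what makes parameter-recovery
testing possible.

Generator defaults (chosen once and fixed): edge baselines
N(0.25, 0.12²) so edge correlations are generally positive, annual
slope scale 0.005 FC/yr with slope noise SD 0.0015, subject-level SD
0.06, scan noise SD 0.04, mean FD ~ Gamma(shape 2, scale 0.05) mm
(right-skewed), sex and site effects of 0.01 FC each, and no motion
confounding unless `motion_gamma0`/`motion_gamma_slope` are set.

`run_pipeline()` chains the whole analysis — simulate, QC, fit, MI,
classify, colocate — and writes plain-text tables plus a JSON
provenance record; a rerun with the same configuration reproduces every
output byte for byte. The documented reference configuration
(80 subjects, 26 cortical + 4 subcortical regions, 199 spins) completes
in well under 15 minutes on one CPU.

The package's interface is its exported functions plus `run_pipeline()`;
for shell use, `inst/scripts/run_pipeline.R` wraps the pipeline behind
`--config`/`--out` flags (no subcommand multiplexer — R users compose
the exported functions directly).
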