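---
title: "Digital subresolution-sandwich phantoms for benchmarking PET auto-segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital subresolution-sandwich phantoms for benchmarking PET auto-segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Automatic segmentation of tumours on ^18^F-FDG PET (PET-AS) is attractive
for radiotherapy target definition, but methods that look excellent on
homogeneous spherical inserts of plastic fillable phantoms often degrade on
realistic lesions: irregular outlines, heterogeneous uptake, necrotic
cores. A printed *subresolution-sandwich* (SS) phantom solves the
ground-truth problem physically: 2-mm-spaced paper sheets printed with a
mixture of ink and radiotracer are stacked between plastic sheets, so the
digital printout template *is* the ground truth for whatever uptake pattern
one chooses to print.

`ssphantom` reproduces that experimental logic entirely in software. It
generates the same family of ground-truth uptake templates (spheres,
spheroids, an irregular head-and-neck-like lesion; five uptake patterns),
simulates PET-like images from them, implements the printer-calibration
mathematics, runs ten automatic segmentation methods, and scores them with
the standard overlap metrics. Everything is seeded and deterministic, so
every number in the package's outputs can be recomputed exactly.

## Phantom model

**Grids.** Templates live on a fine grid of 1 × 1 × 2 mm voxels. The 2-mm
axial pitch mirrors the physical sheet stack, which cannot resolve axial
detail finer than one sheet; 1 mm in-plane comfortably out-resolves the
simulated PET grid (2.73 × 2.73 × 3.27 mm voxels, the clinical
whole-body protocol). All objects carry an explicit `grid_spec` (shape,
spacing, origin; voxel-centre convention).

**Lesion geometry.** Three shape families:

* spheres of diameters 10, 13, 17, 22, 28, 38 mm (S1–S6);
* an ~11 mL spheroid (ellipsoid, axis ratios 1.25 : 1 : 0.8 — mildly
  anisotropic, as lymph-node-like lesions are; the ratios are a package
  choice, any would do);
* an irregular lesion built by spherical-harmonic radial perturbation of a
  sphere (degrees 1–4, coefficient scale 0.3/degree, seeded), rescaled to a
  target volume. The original study delineated a clinical tumour outline,
  which is not reproducible; the harmonic generator produces comparable
  star-convex, non-spherical shapes (sphericity ≈ 0.93–0.94) with exact
  provenance. The study volume is 11 mL; a 5.9 mL variant of the same shape
  is available because the comparison against a NEMA sphere used that size.

**Rasterisation.** Shapes are rasterised by supersampled fractional
coverage (4³ subvoxels) followed by a volume-matching step: boundary voxels
near 0.5 coverage are swapped, in coverage order, until the voxel-count
volume is as close as possible to the analytic volume. On a 2-mm-slab grid
a plain centre-inside rule mis-measures a 10-mm sphere by up to ~7%
depending on alignment; volume matching keeps every battery size within a
fraction of a percent, which is what one wants from a ground-truth
generator. The adjustment only touches voxels whose coverage is ambiguous,
so the shape itself is unchanged.

**Uptake patterns.** Background B = 1 (relative units; the calibration
module owns absolute scaling). With tumour-to-background ratio `tbr`
(default 4, the study's value):

* *homogeneous* — lesion level `L = tbr · B`;
* *two-level* — rim at L, concentric centre at `H = 2L − B`, so the
  contrast steps are equal: `H − L = L − B` exactly on the template. The
  high centre spans half the lesion diameter (12.5% of the volume); the
  fraction is configurable because the study never states it;
* *gaussian* — the homogeneous excess `L − B` smoothed with a Gaussian of
  FWHM equal to half the lesion's volume-equivalent diameter (kernel width
  unstated in the study; configurable), added to the background;
* *necrotic* — homogeneous rim with a central core of **zero printed
  activity** occupying 40% of the lesion volume (size unstated;
  configurable). The background-like intensity seen in images arises from
  point-spread spill-in during simulation, not from printed activity;
* *necrotic-gaussian* — the necrotic excess (including the negative core
  excess) Gaussian-smoothed.

**Ground truth.** The delivered ground-truth mask of a necrotic lesion
excludes the core — a segmentation is scored on metabolically active
tumour only. The full outer shape and the core are retained in the
template (`outer_mask`, `core_mask`) for sensitivity analyses such as the
core-inclusion fractions below.

## PET simulator

Three steps stand in for acquisition plus reconstruction:

1. **volume-conserving resampling** of the template onto the PET grid
   (per-axis interval-overlap averaging; total activity is conserved
   wherever the grids overlap, and identical grids short-circuit to the
   identity);
2. **isotropic Gaussian blur**, FWHM 6.4 mm by default — the clinical
   post-reconstruction filter cut-off, used here as a single effective
   point-spread function with scanner resolution folded in;
3. **Poisson counting noise**: each voxel is drawn from
   `Pois(noise_scale · value) / noise_scale`. The default
   `noise_scale = 500` counts per unit background intensity per voxel gives
   ~4.5% relative noise in the background, visually comparable speckle to a
   3-min-per-bed whole-body scan. The study does not characterise its image
   noise, so this is a package calibration, fixed once.

Not modelled (deliberately): sinogram-level reconstruction, attenuation
and scatter, the paper/PMMA media, randoms, axial sensitivity profiles.
Consequently, passing benchmarks here show that a method handles
*geometry, heterogeneity, partial volume and counting noise* — not that it
survives reconstruction artefacts or attenuation-correction errors.

## Printer calibration

The physical technique needs two measured relationships: grey level →
deposited ink (non-linear; a third-degree polynomial fits with R² > 0.99)
and ink × activity → counts (linear, R² > 0.98, pooled across activity
concentrations). `fit_grey_to_ink()` and `fit_ink_to_counts()` reproduce
these least-squares fits (all replicates, not averages), require
monotonicity on the sampled domain, and `grey_for_target_activity()`
inverts their composition by bisection (grey tolerance 1e-6) after
normalising so grey 1 ↦ relative activity 1. Decay correction uses the
^18^F half-life of 109.77 min. Calibration works in relative units
throughout: the phantom models uptake *ratios*, absolute Bq scaling is one
free factor.

## The ten segmentation methods

All methods receive the image cropped to the true contour's bounding box
dilated by 10 mm (`crop_roi()`), and all are deterministic. Connectivity is
26-neighbour in 3-D. Details the study delegates to its own prior work are
package design decisions, documented here.

**AT — adaptive iterative background-subtracted thresholding.** Iterates
`T ← bg + β (mean{v ≥ T} − bg)` from a half-max start, with `bg` the mean
of the one-voxel ROI shell; returns the largest connected component.
`β = 0.8` was calibrated so the implementation reproduces the published AT
operating regime — conservative masks, PPV near 1 on spheres, and a
necrotic core left out of the contour; at `β = 0.5` the blurred core rim
exceeds the converged threshold and the characteristic core exclusion is
lost. No cavity filling, which is exactly why AT excludes enclosed cores.

**RG — iterative region growing with automatic seed finder.** The seed is
the maximum after 3×3×3 mean smoothing (ties → lowest linear index). For a
decreasing schedule of acceptance fractions α (0.95 … 0.05), a region is
grown from the seed accepting 26-neighbours with intensity ≥ α × current
region mean. The α is then selected at the *maximal relative drop in
region-volume growth* — the step where expansion decelerates most, i.e.
the onset of a growth plateau after an uptake level has been absorbed.
Regions that have leaked to the ROI border, or are smaller than 8 voxels
(growth ratios are quantisation noise below that), are not candidates;
ties resolve to the largest α. The final mask is hole-filled slice by
slice, so an annular cross-section is filled even when the thin polar cap
of a shell leaves the 3-D surface open — this is what makes RG engulf
necrotic cores.

**GCM2–GCM8 — fuzzy C-means with Gaussian mixture modelling.** Voxel
intensities only (no spatial features). Memberships are fuzzified Gaussian
class responsibilities: with class means and variances re-estimated from
the fuzzy weights each sweep, membership ∝ `exp(log φ(x; c_k, σ_k) / (m−1))`
with fuzziness `m = 2`. The `−log σ` normalisation term is essential — it
lets the narrow, dominant background class keep its members, where plain
variance-scaled distances push them away. Class weights are uniform so
sparse high-uptake classes are not starved. Initialisation is
deterministic and hierarchical: the 2-class solution starts from
range-spaced centres (intensity quantiles degenerate when one level holds
most voxels), and each further class is added by splitting the most
dispersed class of the converged previous solution — successive k are
continuations of one another, which is also why the background/tumour
boundary moves monotonically with k instead of jittering between
independently-initialised fits. The fit runs on the quantised intensity
histogram (identical, faster), to `tol = 1e-8` on the centres within 1000
sweeps. The lowest-mean cluster is background; the union of all others,
largest component, slice-filled, is the tumour.

**WT — slice-by-slice marker-based watershed.** Per axial slice: gradient
magnitude by central differences (optional Gaussian pre-smoothing, default
off — the simulated images are already post-filtered); internal marker =
the regional-maximum plateau containing the slice maximum (one voxel on
smooth data, the full disc on sharp two-valued slices); background markers
= the slice border plus regional minima of the gradient whose intensity is
below `bg + 0.5 (max − bg)` — that last rule is what lets an enclosed
low-uptake core drain to background instead of being annexed by the
internal basin. Priority-flood watershed with 4-connected flooding
(diagonal steps leak across one-pixel ridges; connectivity 1 is the
standard default for seeded watersheds) and Meyer's watershed-line
convention: a pixel reached by both basins belongs to the boundary and is
assigned to background. Slices whose maximum does not reach the marker
threshold are omitted; the 3-D result is the union of the per-slice
internal basins, with no hole filling.

## Evaluation

`dice()`, `sensitivity()` and `ppv()` implement
`DSC = 2|A∩B|/(|A|+|B|)`, `S = |A∩B|/|A|`, `PPV = |A∩B|/|B|` on PET-grid
masks (no sub-voxel interpolation — the comparison grid of the study). DSC
is algebraically the harmonic mean of S and PPV, which the tests verify on
random mask pairs to 1e-12. `dsc_error_bar()` implements the ±4% · (1−DSC)
experimental error model, and `good_overlap()` the strict DSC > 0.7
indicator. `evaluate_grid()` assembles the per-method × per-lesion table;
empty segmentations become flagged zero rows rather than errors.

## Study design and reproduction

`paper_experiment_config()` encodes the benchmark: six two-level spheres
(TBR 4) segmented by all ten methods, plus the spheroid under four
patterns and the irregular lesion under all five (two-level is not defined
for the spheroid), segmented with clustering capped at six clusters —
AT, RG, GCM2–GCM6, WT. `run_experiment()` executes any such config and
writes NIfTI volumes, a byte-stable metrics CSV and a JSON manifest with
checksums.

Two study-level helpers are used by the tests, the analysis scripts and
`scripts/acceptance.R`:

* `run_sphere_trend()` — the sphere battery plus a homogeneous 38-mm
  control, across replicate noise seeds (10 by default). Expected
  structure: GCM sensitivity non-decreasing and PPV non-increasing with
  the number of clusters, and the binary methods (AT, RG, WT) losing
  sensitivity on the two-level sphere relative to the homogeneous control.
* `run_necrotic_dichotomy()` — fraction of PET-grid core voxels inside
  each method's mask on the simulated necrotic spheroid. Expected: ≫ 0.9
  for RG, ≪ 0.1 for AT and WT.

Problem sizes were chosen to keep a full trend run (7 lesions × 10 seeds ×
10 methods) in a few minutes on one core: per-lesion templates of roughly
80 × 80 × 40 fine voxels, PET ROIs of a few thousand voxels.

## What the generator does and does not emulate

The digital phantom reproduces: known ground truth at sub-PET resolution,
2-mm axial quantisation of the sheet stack, partial-volume blur, counting
noise, arbitrary uptake patterns, and the evaluation protocol. It does not
reproduce: reconstruction artefacts, attenuation/scatter of the paper and
plastic, printer ink-deposition noise (the calibration module models the
*mathematics* of calibration on synthetic samples), or a structured
anatomical background around the lesions — backgrounds default to uniform,
with ellipsoidal structures available via `make_background()`. Absolute
published accuracy values from physical scans are therefore not
reproduction targets; the qualitative structure (trends, dichotomies,
optimal cluster numbers) is.

## Numerical choices and degenerate inputs

* Gaussian kernels are truncated at 4σ and renormalised; interior sources
  conserve mass to better than 0.1%.
* Resampling between identical grids returns the input bit-identically.
* Constant images: AT returns an empty, unconverged result; seed finding
  and clustering refuse with an error; WT returns an empty mask.
* Ties: seed finder and marker localisation take the lowest linear index;
  flat marker windows are flagged low-confidence.
* The GCM variance floor is (1e-3 × intensity range)², which makes exact
  two-valued separation stable; a cluster whose fuzzy mass vanishes is kept
  in place rather than producing NaNs, and an empty hard cluster triggers
  one deterministic quantile re-initialisation before erroring.
* `decay_correct()` accepts negative elapsed times (forward decay).

## Known limitations

* The irregular generator produces star-convex shapes; real tumours can
  have lobes no radial function describes. Sphericity ≈ 0.93 is irregular
  but milder than extreme clinical cases.
* WT under noise stops at spurious gradient ridges and tends to
  under-segment small spheres; that matches the conservative behaviour
  reported for slice-wise watershed, but its absolute sensitivity values
  are not calibrated against any scanner.
* The monotone GCM trend relies on the hierarchical initialisation;
  independently initialised fits of different k can cross by a fraction of
  a percent in saturated regimes.
* The two printed quantities the study leaves ambiguous — the irregular
  lesion's volume (11 vs 5.9 mL) and the sphere experiment's TBR — are
  both configurable; defaults are 11 mL and TBR 4.
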