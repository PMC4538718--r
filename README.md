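# ssphantom

Digital subresolution-sandwich phantoms for benchmarking automatic PET
tumour segmentation.

## What this is for

Evaluating PET auto-segmentation (PET-AS) needs images whose true tumour
outline is known. Plastic fillable phantoms provide that truth only for
homogeneous spheres behind plastic walls — nothing like the irregular,
heterogeneous, sometimes necrotic lesions that make segmentation hard. The
printed *subresolution-sandwich* phantom solves this physically: 2-mm-spaced
paper sheets printed with an ink + ^18^F-FDG mixture are stacked into a 3-D
object, so the printout template itself is the ground truth for any uptake
pattern. `ssphantom` is a faithful digital analogue of that workflow, for
people developing or stress-testing segmentation methods at a desk:

* **Phantom generator** — ground-truth uptake templates on a 1 × 1 × 2 mm
  grid: spheres of 10–38 mm (S1–S6), an ~11 mL spheroid and a seeded
  irregular lesion; uptake patterns *homogeneous*, *two-level*
  (H − L = L − B), *Gaussian*, *necrotic* (zero-activity core, excluded
  from the delivered ground truth) and *necrotic-Gaussian*, at a
  tumour-to-background ratio (default 4).
* **PET simulator** — volume-conserving resampling to the clinical grid
  (2.73 × 2.73 × 3.27 mm), a 6.4 mm FWHM Gaussian point spread, Poisson
  counting noise; seeded and deterministic.
* **Printer calibration** — cubic grey-to-ink and pooled linear
  ink-to-counts least-squares fits, ^18^F decay correction, and bisection
  inversion: which grey level prints a requested relative activity.
* **Ten PET-AS methods** behind one interface: adaptive iterative
  background-subtracted thresholding (`AT`), iterative region growing with
  automatic seed finding (`RG`), fuzzy C-means with Gaussian mixture
  modelling for 2–8 clusters (`GCM2`–`GCM8`), and slice-by-slice
  marker-based watershed (`WT`).
* **Evaluation** — Dice similarity coefficient
  `DSC = 2|A∩B| / (|A| + |B|)`, sensitivity `S = |A∩B|/|A|`, positive
  predictive value `PPV = |A∩B|/|B|`, the ±4 %·(1−DSC) error-bar model,
  the strict DSC > 0.7 good-overlap indicator, and a config-driven
  experiment runner with byte-stable outputs.

The methods vignette (`vignettes/digital-sandwich-phantom.Rmd`) documents
the model, every tunable parameter and the design decisions.

## Worked example

Simulate a 17-mm two-level sphere, crop the 10-mm-margin ROI, segment it
with three methods and score against the ground truth:

```r
library(ssphantom)

entry <- list(id = "S3", battery = "sphere",
              spec = lesion_spec("sphere", 17, "two_level", tbr = 4))
cfg <- experiment_config(list(entry), noise_seeds = 1L)
case <- simulate_lesion_case(entry, cfg, noise_seed = 1)
roi <- crop_roi(case$image, case$truth, margin_mm = 10)

results <- lapply(c(AT = "AT", GCM3 = "GCM3", WT = "WT"),
                  function(m) segment_lesion(roi$image, m))
metrics <- evaluate_grid(list(S3 = results), list(S3 = roi$truth))
metrics[, c("method", "dsc", "sensitivity", "ppv", "dsc_error")]
#>   method       dsc sensitivity        ppv  dsc_error
#> 1     AT 0.4461538   0.2871287 1.00000000 0.02215385
#> 2   GCM3 0.1089536   1.0000000 0.05761552 0.03564186
#> 3     WT 0.5467626   0.3762376 1.00000000 0.01812950
```

The pattern is the interesting part: on a strongly heterogeneous small
sphere the binary methods (AT, WT) are conservative — perfect PPV, low
sensitivity, because their thresholds lock onto the bright centre — while
a three-cluster GCM sweeps up the whole lesion plus background tail
(sensitivity 1, PPV near the lesion's volume fraction of the ROI). The
error bars are the ±4 %·(1−DSC) experimental-reproducibility model.

## The analysis workflow

Numbered drivers under `analysis/` reproduce the full study, writing
tables under `results/`:

1. `01_phantom_gallery.R` — all 15 phantoms (6 spheres + 4 spheroid
   patterns + 5 irregular patterns), NIfTI volumes, printable page images,
   geometry summary.
2. `02_printer_calibration.R` — calibration fits on the bundled synthetic
   sample table (`inst/extdata/synthetic_calibration_samples.csv`) and the
   inverted grey-level look-up for TBR-4 printing.
3. `03_sphere_battery.R` — the two-level sphere battery across 10 noise
   seeds and all ten methods: sensitivity/PPV trends versus the number of
   clusters, the optimal cluster count per sphere, and the
   heterogeneity-induced sensitivity drop of the binary methods.
4. `04_lesion_battery.R` — the spheroid and irregular batteries (eight
   methods, clustering capped at six clusters) and the necrotic-core
   inclusion fractions that separate region-growing (fills the core) from
   thresholding and watershed (exclude it).

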