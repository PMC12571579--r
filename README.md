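# ihcsens

Analytic sensitivity, dynamic range and diagnostic accuracy of calibrated
immunohistochemistry (IHC) assays.

## The problem

HER2 IHC drives two different treatment decisions: classical HER2-positive
disease (3+, trastuzumab) and HER2-low disease (ultralow/1+/2+,
trastuzumab deruxtecan). Whether a laboratory's stain can *see* low HER2
levels depends on the analytic sensitivity of that laboratory's assay run —
a quantity that is almost never measured in practice. Bead calibrators make
it measurable: microbeads carrying defined HER2 peptide concentrations
(26–1400 ×10³ molecules, ERF units, per cell-equivalent) are stained,
photographed and quantified, and the run's lower limit of detection (LOD) is
the concentration whose stain intensity equals the negative-control mean
plus three standard deviations:

```
fit   intensity = a · ln(concentration) + b        (slope points only)
LOD   exp((y* − b) / a),   y* = mean(neg) + 3 · sd(neg)
```

`ihcsens` is for laboratorians and methodologists who want to run that
quantification and the statistics built on it:

* **bead quantification** — greyscale conversion, circle Hough segmentation
  within an allowable radius range, overlap removal, per-bead DAB
  dot-product intensities, duplicate averaging;
* **LOD estimation** — baseline/slope/plateau classification, log
  regression, threshold inversion, QC flags;
* **consensus HER2 scoring** — per-core averages over laboratory groups
  rounded to the nearest score, with or without the ultralow (0.5) category;
* **dynamic range** — the OLS slope of aggregate TMA score on assay LOD
  (zero slope = scores blind to expression), slope t-tests, slope
  comparisons;
* **diagnostic accuracy** — confusion counts against ISH (HER2/CEP17 ≥ 2)
  or LOD-defined consensus gold standards, exact Clopper–Pearson intervals,
  per-laboratory accuracy profiles;
* **synthetic data** — calibrator images, laboratory cohorts, score
  matrices and ISH tables with known ground truth, so the whole chain is
  testable without physical slides.

All user-facing functions take data frames first and return tibbles; results
have `tidy()`/`glance()` and `autoplot()` methods.

## Worked example

Estimate a laboratory's LOD from a (here: simulated) calibrator slide, then
measure the cohort's dynamic range:

```r
library(ihcsens)

slide <- sim_calibrator_slide(calibrator_curve(40000), seed = 1)
spots <- quantify_calibrator(slide$image, slide$spots)
estimate_lod(spots)
#> LOD estimate
#>   LOD: 40022 molecules (ERF) per cell-equivalent
#>   fit: intensity = 0.2200 * ln(conc) -2.1810 (R^2 = 1.0000, n = 5)
#>   threshold: 0.1502 (neg mean 0.1500 + 3 x SD 0.0001)
```

The slide was constructed with a true LOD of 40,000; the image pipeline
recovers 40,022 (0.06% off) from five slope points with the threshold at the
negative-control mean + 3 SD.

```r
study <- sim_study(seed = 1)   # 54 labs, 80 cores, two readouts, ISH
dynamic_range_slope(study$scores, study$labs, readout = "image_analysis",
                    centers = seq(10000, 60000, 10000))
#> Dynamic range (image_analysis readout, ultralow included)
#>   slope: -1.27e-05 score units per molecule (-0.127 per 10^4), se 1.45e-06
#>   t = -8.762 on 4 df, p = 0.0009354; 6 bins
```

The aggregate HER2 score falls by ~0.13 for every 10,000-molecule rise in
LOD (p < 0.001): with an image-analysis readout, scores track analytic
sensitivity. The same call with `readout = "manual"` gives a slope several
times shallower, and `compare_slopes()` puts p ≈ 0.007 on the difference —
the simulated manual reader cannot exploit sensitivity below its perceptual
floor.

Diagnostic accuracy against ISH, with exact 95% intervals:

```r
cons <- consensus_scores(study$scores, readout = "manual")
diagnostic_metrics(trastuzumab_confusion(cons, study$ish))
#> # A tibble: 5 × 6
#>   metric          k     n estimate ci_low ci_high
#> 1 sensitivity    21    23    0.913  0.720   0.989
#> 2 specificity    49    50    0.98   0.894   0.999
#> 3 ppv            21    22    0.955  0.772   0.999
#> 4 npv            49    51    0.961  0.865   0.995
#> 5 accuracy       70    73    0.959  0.885   0.991
```

Sensitivity is 21/23 amplified cores called positive; each row carries its
Clopper–Pearson interval. `run_pipeline(pipeline_config(...))` chains all
stages and writes a CSV/JSON report bundle; a thin command-line front end
lives in `inst/scripts/ihcsens-cli.R`.

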