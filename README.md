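# pmscore

Quantitative edge-irregularity analysis of parenchymal organ margins on 2D
grayscale CT-like images.

## The problem

The margin of a healthy pancreas is lobulated and nodular where it meets the
surrounding visceral fat; pancreatic ductal adenocarcinoma, wrapped in a
dense desmoplastic stroma, presents an unusually *smooth* edge. The same idea
underlies the liver surface nodularity (LSN) score used to stage hepatic
fibrosis: quantify how irregular an organ's border looks on a CT slice, and
use that number as an imaging biomarker.

`pmscore` turns a border fragment inside a fixed-size region of interest
(ROI) into a single number, the **pancreatic margin score (PMS)**:

1. detect border pixels with a **Canny edge detector** (Gaussian smoothing,
   Sobel gradients, non-maximum suppression, quantile-based hysteresis);
2. select *the* border as the longest geodesic path through the largest
   8-connected component of edge pixels;
3. parameterize it along its principal axis as a 1D signal `v(u)`;
4. fit the **average boundary line** — a deliberately stiff least-squares
   cubic B-spline `v̂(u)` with interior knots roughly every `knot_spacing`
   pixels;
5. score the margin as the root-mean-square deviation of the border from
   that line, in pixels:

   PMS = sqrt( mean( (v(u) − v̂(u))² ) )

Low PMS = smooth margin (tumor-like); high PMS = nodular margin (healthy
parenchyma). A threshold on PMS separates the two classes; the package ships
the published single-center operating point (0.6855 px) as a default and can
recalibrate it per cohort via the Youden index on an ROC curve.

Because clinical images cannot be redistributed, the package includes a
synthetic **phantom generator**: two-phase parenchyma/fat step images whose
border is a known base curve (line or arc) plus band-limited sinusoidal
roughness of exactly controlled RMS amplitude. Every stage of the pipeline is
validated against this ground truth.

## Worked example

Score a single synthetic ROI:

```r
library(pmscore)

spec <- phantom_spec(shape = c(104, 104), perturbation_rms = 1.5,
                     band = c(4, 12), seed = 7)
ph <- make_phantom(spec)
ph
#> <phantom 104x104 px, true_rms 1.5000 px>

res <- score_roi(ph$image, roi_box(4, 4, 96, 96, label = "healthy"),
                 canny = canny_params(sigma = 0.4), knot_spacing = 40)
res
#> <pms_result: PMS 1.0355 px, 107 border points, 2 knots [healthy]>
```

The phantom's border carries 1.5 px RMS of roughness; the measured score,
1.04 px, is lower because the imaging chain (point-spread blur, integer-pixel
edge localization) attenuates the finest wavelengths — the methods vignette
quantifies this. `tidy(res)` returns the same result as a one-row tibble,
including a `params_fingerprint` hash of every setting that influenced the
score.

A full paired study on 20 simulated patients:

```r
tumor_tpl   <- phantom_spec(shape = c(104, 104), perturbation_rms = 0.5,
                            band = c(4, 12), blur_sigma = 1, noise_sigma = 2)
healthy_tpl <- phantom_spec(shape = c(104, 104), perturbation_rms = 1.5,
                            band = c(4, 12), blur_sigma = 1, noise_sigma = 2)

coh   <- make_cohort(20, tumor_tpl, healthy_tpl, seed = 11)
pairs <- score_cohort(coh, roi_shape = c(96, 96),
                      canny = canny_params(sigma = 0.4), knot_spacing = 40)
cohort_report(pairs)
#> Paired margin-score study
#>   tumor   PMS: 0.4881 +/- 0.0067 px
#>   healthy PMS: 1.0598 +/- 0.0792 px
#>   Paired t-test: t = -31.5, df = 19, p = 7.288e-18, mean diff = -0.5717 px
#>   ROC: AUC = 1.0000 (20 cancer vs 20 healthy)
#> Youden threshold = 0.6982 px (sens 1.000, spec 1.000)
#>   classification threshold: 0.6982 px
```

The smooth (tumor-analog) arm scores ~0.49 px, the nodular (healthy-analog)
arm ~1.06 px, and the cohort's own Youden-optimal cutoff, 0.70 px, separates
them perfectly — the same qualitative picture as the clinical report this
score comes from (tumor 0.50 px vs healthy 1.27 px, threshold 0.6855 px).

`autoplot()` methods draw the image, the fitted average boundary line with
its residuals, the ROC curve, and the per-group box plot;
`tidy()`/`glance()` return tibbles for further dplyr work.

Real images are read with `load_image()` (grayscale PNG/TIFF), annotated in a
CSV manifest (`patient_id, image_path, roi_tumor, roi_healthy` with ROIs as
`"top,left,height,width"`), validated by `load_manifest()` — all boxes in a
study must share one size — and scored in batch with `score_manifest()`. A
thin command-line front end (`inst/cli/pms`) exposes `score`, `batch`,
`simulate` and `roc` subcommands over the same functions.

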