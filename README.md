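# mirsiprep

Quantitative analysis of quantum-cascade-laser mid-infrared
spectrochemical imaging (MIRSI) data, built to measure how tissue
preparation — fresh-frozen (FF) versus formalin-fixed paraffin-embedded
(FFPE) — alters the biochemical information in hyperspectral tissue
images. It is aimed at vibrational-spectroscopy and spectral-pathology
groups who need a tested, reproducible implementation of the standard
fingerprint-region workflow, and it ships a synthetic-phantom generator
so every stage can be validated against known ground truth without any
tissue data.

## What it computes

Each pixel of a hyperspectral cube carries an absorbance spectrum
*A*(ν) on a common wavenumber axis (950–1800 cm⁻¹ at 2 cm⁻¹; 426
points). The pipeline:

* **Tissue masking** — Otsu thresholding (256-bin, between-class
  variance) of the single-band image at 1608 cm⁻¹; off-tissue pixels
  define the background.
* **Background noise model** — σ = population SD of the Savitzky–Golay
  second derivative of the mean off-tissue spectrum (trimmed range).
* **Preprocessing** — rubberband (lower convex hull) baseline
  correction per sampled pixel; SG second derivative d²A/dν² (window 13,
  polynomial order 2), trimming 26 of the 426 points for edge effects;
  per-spectrum Z-score normalization for classification.
* **Sub-band statistics** — significant dips are strict local minima of
  d²A/dν² below −3σ; per-ROI band *occurrence* counts pixels with a
  significant dip within ±2 cm⁻¹ of a reference band center; band
  *integrals* are composite-Simpson integrals of −d²A/dν² over windows
  around the reference centers (DNA, glycogen, amide I/II/III, protein,
  lipid bands); preparation effects are reported as the percent
  reduction 100·(I_FF − I_FFPE)/I_FF. Gaussian sub-band mixtures can be
  fitted to mean spectra by bounded nonlinear least squares.
* **Classification** — ROI-mean Pearson correlation heatmaps;
  Z-score → PCA → UMAP embedding with silhouette separation metrics; and
  L2-regularized logistic regression on the Z-scored spectra whose
  top-40 |coefficients| rank the most discriminative wavenumbers.

The phantom generator plants known effect sizes as exact ground
truth: FFPE amide-I amplitudes are scaled so the true integral
reductions are 66.3% (kidney) and 46.2% (liver), FF libraries carry 13
bands vs 8/7 retained in FFPE, and every FFPE library adds the
fixation-associated ~1026 cm⁻¹ band absent from FF tissue.

## Worked example

Generate one FF kidney phantom ROI, segment it, build the background
model, and detect the significant bands of the ROI-mean second
derivative:

```r
library(mirsiprep)

roi  <- generateRoi(phantomConfig("kidney", "FF", roiShape = c(96, 96), seed = 7))
mask <- makeTissueMask(roi$cube)       # Otsu at 1608 cm^-1
mask
#> TissueMask: 96 x 96, 4022 tissue pixels (43.6%), Otsu threshold 0.3915 at 1608 cm^-1

bg <- computeBackground(roi$cube, mask)
bg
#> BackgroundModel: sigma = 2.678e-05 (from 5194 background pixels)

pset <- samplePixels(roi$cube, mask, n = 2000, seed = 8)
d2   <- savgolSecondDerivative(rubberbandBaseline(pset))
d2
#> SecondDerivSpectrum: 2000 spectra on trimmed axis 976..1774 cm^-1 (400 points)

calls <- detectSignificantDips(colMeans(derivValues(d2)), spectralAxis(d2),
                               sigma = backgroundSigma(bg))
subset(calls, significant)
#>  position         depth significant  edge
#>      1034 -0.0005349254        TRUE FALSE
#>      1082 -0.0005905402        TRUE FALSE
#>      1154 -0.0003247498        TRUE FALSE
#>      ...
#>      1546 -0.0012671573        TRUE FALSE
#>      1658 -0.0015372111        TRUE FALSE
#>      1744 -0.0009289038        TRUE FALSE
```

The dips sit at the planted band centers (amide I 1658, amide II 1546,
lipids 1744, …); the 966 cm⁻¹ DNA band lies outside the trimmed axis and
is reported as dropped by the integration-window builder.

A paired FF/FFPE study recovers a planted amide-I reduction through the
full masking → baseline → derivative → Simpson chain (here only 2 ROIs
per preparation for speed; the study design uses 8):

```r
res <- amideReductionStudy("liver", seed = 43, nRois = 2, roiShape = c(96, 96))
round(res$reduction, 2)   # measured percent reduction
#> 46.15
res$planted               # planted ground truth
#> 46.2
```

The full pipeline (phantom study → masks → preprocessing → occurrence +
integrals → correlation/UMAP/rankings, with CSV outputs and a JSON run
report) runs from one seeded config, or from the thin CLI wrapper:

```r
rep <- runPipeline(list(n_rois = 2L, roi_shape = c(48L, 48L),
                        n_classification = 300L, n_occurrence = 50L,
                        n_umap = 200L, seed = 11L),
                   outDir = "results/run1")
```

```sh
Rscript inst/cli/mirsiprep.R all --config run.yaml --out results/ --seed 42
```

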