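---
title: "Methods: phantom-validated preprocessing and sub-band analysis for mid-IR spectrochemical imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-validated preprocessing and sub-band analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsiprep)
```

## The measurement problem

Quantum-cascade-laser mid-infrared spectrochemical imaging (MIRSI) records
an absorbance spectrum over the fingerprint region (950–1800 cm⁻¹, 2 cm⁻¹
steps, 426 grid points) at every pixel of a tissue section. How a section
was prepared — fresh-frozen (FF) versus formalin-fixed paraffin-embedded
(FFPE) — changes the chemistry the spectra can see: fixation and paraffin
clearing attenuate or remove lipid and nucleic-acid bands, shrink the
protein amide I band, and introduce a fixation-associated feature near
1026 cm⁻¹. `mirsiprep` implements the quantitative pipeline for measuring
those effects and validates every stage on synthetic hyperspectral
phantoms whose ground truth is known exactly.

The pipeline has three arms, run after tissue/background segmentation:

1. **Sub-band quantification.** Per-pixel spectra are baseline-corrected
   with a rubberband (lower convex hull) and differentiated twice with a
   Savitzky–Golay (SG) filter. Absorbance maxima appear as negative dips
   of the second derivative; a dip is *significant* when it lies below
   −3σ, where σ is the standard deviation of the second derivative of the
   averaged off-tissue background spectrum. Band *occurrence* counts, for
   each reference band, the pixels of an ROI with a significant dip within
   ±2 cm⁻¹ of the band center. Band *integrals* apply composite Simpson
   integration to −d²A/dν² over a window around each reference center, and
   preparation effects are summarized as the percent reduction
   100·(I_FF − I_FFPE)/I_FF of per-preparation mean integrals.
2. **Sub-band decomposition.** Gaussian mixtures are fitted by bounded
   Levenberg–Marquardt least squares to baseline-corrected mean spectra,
   initialized at the detected dip positions.
3. **Classification.** ROI-mean correlation matrices; per-spectrum Z-score
   normalization followed by PCA, a 2-D UMAP embedding with silhouette
   separation metrics, and ridge-logistic feature importance that maps
   discriminative power back onto wavenumbers.

## What the phantoms emulate

`generateRoi()` builds an ROI (default 96×96 pixels, a desk-scale stand-in
for 480×480 acquisitions) as

absorbance(pixel, ν) = baseline(ν) + j·Σ_b A_b·exp(−4 ln2 (ν−c_b)²/w_b²) + ε,

with iid detector noise ε ~ N(0, `noise_sd`²) and a per-pixel log-normal
intensity factor j (mean 1, `sdlog` 0.10) applied to the band component —
spatial heterogeneity in real sections is dominated by intensity, not
shape, variation. Tissue masks are unions of random ellipses; FF sections
additionally get morphological holes (random disks carved until a target
fraction of the mask, default 15%, is removed), mimicking the fractures
and discontinuities of frozen sectioning. Off-mask pixels carry baseline
plus noise only.

Band libraries (`defaultBandLibrary()`) draw centers from the reference
band table (DNA 966/1035/1082, glycogen 1154, protein 1168/1400/1448,
amide III 1238/1308, lipids 1462/1744, amide II 1546, amide I 1658). FF
libraries carry thirteen bands; FFPE retains eight (kidney) or seven
(liver) — amide and protein bands survive, DNA and lipid bands are lost —
plus the 1026 cm⁻¹ fixation band that FF tissue never shows. The 1030 and
1516 entries of the reference table are unresolvable shoulders of their
5 cm⁻¹/30 cm⁻¹ neighbours at this grid and width, so the 13-band FF
libraries omit them.

Two choices encode effect sizes as exact ground truth:

* **Planted amide-I reductions.** The FFPE amide-I amplitude is
  (1−f)·the FF amplitude at equal width, so the true band-integral
  reduction is exactly f — 0.663 for kidney and 0.462 for liver by
  default. Every other FF/FFPE amplitude ratio is a free parameter of the
  generator; retained
  non-amide FFPE bands take 0.6× the mean FF profile of the two tissues.
* **Near-identical FFPE libraries.** FF amide-I amplitudes are 0.75
  (kidney) and 0.47 (liver) AU — organs differ in protein content — which
  makes the two planted reductions land on essentially the same FFPE
  amide amplitude (0.2528 vs 0.2529 AU). Combined with the shared FFPE
  profile, FFPE kidney and liver become nearly indistinguishable while FF
  kidney and liver stay well separated, reproducing the expected behaviour
  that fixation collapses organ-specific spectral contrast. The embedding
  tests check exactly this ordering of cross-tissue silhouettes.

The phantoms deliberately do **not** emulate Mie scattering physics,
instrument noise spectra (noise is white), water-vapour lines, anatomical
texture, or band-shape heterogeneity. Passing tests therefore demonstrate
that the *pipeline arithmetic* is correct and recovers planted truth under
realistic SNR — not that the biology of any particular tissue would be
recovered.

## Noise calibration: why σ is structure-dominated

The 3σ threshold comes from the second derivative of the *averaged*
background spectrum. Averaging n background pixels suppresses white noise
by √n, so in a phantom with a featureless background σ would collapse far
below the per-pixel derivative noise and the threshold would pass noise
dips freely. In real measurements it does not, because the background's
second derivative is dominated by structured residuals (scattering
curvature, optical étendue changes), not by averaged-out white noise.

The default baseline therefore includes a broad sigmoid scattering step
(amplitude 0.25 AU, width 15 cm⁻¹, centered at 1240 cm⁻¹) on top of a
gentle polynomial. With the default `noise_sd` = 0.0015 AU:

* per-pixel SG second-derivative noise is ≈ 0.0112·`noise_sd` ≈ 1.7·10⁻⁵
  (the 0.0112 factor is the ℓ₂ norm of the SG second-derivative kernel at
  window 13, order 2, 2 cm⁻¹ spacing);
* the background σ, dominated by the sigmoid's curvature, is ≈ 2.7·10⁻⁵,
  so 3σ sits ≈ 5× above per-pixel derivative noise.

This single calibration makes the whole detection story coherent: on
band-free phantoms false occurrence stays at a few pixels per hundred,
while planted bands with center depth ≥ 6σ are detected in ≥ 95% of
pixels. Band depths after smoothing are A·8 ln2/w² times an attenuation
factor (0.63 at w = 20 cm⁻¹, 0.81 at 30, 0.93 at 50) — the SG window
spans 24 cm⁻¹, so narrow bands are substantially flattened, and default
amplitudes are chosen to clear the threshold by a wide margin (weakest FF
band ≈ 12σ, FFPE amide I after the kidney reduction ≈ 19σ).

Note that σ responds *linearly* to `noise_sd` only on flat-baseline
phantoms (where the averaged-noise pathway is all there is); with the
default curved baseline σ is deliberately insensitive to it.

## Numerical choices

* **Axis and lookups.** The axis is strictly increasing and uniform;
  requested wavenumbers map to the nearest grid point with exact
  half-step ties broken toward the lower wavenumber (so 1607 → 1606 on
  the even grid).
* **Trimming.** The SG filter (window 13, order 2) trims one full window
  length per side — 26 of 426 points, leaving 976–1774 cm⁻¹. Two
  reference features (DNA ~966, and any carbonyl feature near 1788) fall
  outside that range: their integration windows are dropped with a
  warning, and dips within 10 cm⁻¹ of the trimmed ends carry an `edge`
  flag so boundary features can be excluded from interpretation.
* **Rubberband.** The baseline is the lower convex hull (monotone-chain,
  strictly increasing slopes), linearly interpolated between hull
  vertices; endpoints are always contacts and corrected values are ≥ 0
  with exact zeros at contacts. Output is invariant to adding any linear
  function of wavenumber. Correction is applied per pixel after sampling
  and before differentiation.
* **Derivatives** are taken with respect to wavenumber (spacing 2 cm⁻¹),
  not sample index, so integrals carry absorbance·cm⁻¹-scale units and
  band depths are comparable across resolutions.
* **Otsu** runs per ROI on a 256-bin histogram of the single 1608 cm⁻¹
  image; candidate thresholds are interior bin boundaries. When the
  between-class variance has a plateau of ties (an empty histogram gap
  between modes) the plateau midpoint is returned — the convention of the
  classic implementations; a first-maximum rule would park the threshold
  at the gap's lower edge. Tissue is the high-absorbance class
  (`invert = TRUE` for inverted contrast). σ uses the population standard
  deviation (the trimmed range has 400 points; the n/(n−1) distinction is
  noise), and is recomputed per ROI.
* **Simpson.** Composite Simpson on the uniform grid is exact for cubics
  on odd point counts; even counts use Simpson on the first n−1 points
  plus a trapezoid on the last interval. The integrand is −d²A/dν² so
  absorbance peaks integrate positive.
* **Windows.** The reference table prints centers only; integration
  windows default to center ± 8 cm⁻¹ (configurable per band), wide enough
  for condensed-phase sub-bands yet narrow enough not to overlap at the
  table's spacing. Occurrence matching uses the closed interval
  [center − 2, center + 2]; a dip matching several bands is assigned to
  the nearest center, ties toward the lower wavenumber.
* **Gaussian fitting** bounds centers to their initialization ± 5 cm⁻¹
  and amplitudes to be nonnegative; non-convergence raises a condition
  carrying the best-so-far parameters, and a deliberately misplaced
  initialization is detectable by its residual norm.
* **Ridge logistic regression** uses a unit penalty (λ = 1) on the
  mean-log-likelihood objective. The 426 channels are strongly collinear,
  and a penalty that vanishes with n (the λ = 1/n reading of "unit
  strength") lets label-shuffled fits reach ~30% of the true top
  importance; at λ = 1 shuffled importance stays below ~10% while a
  genuinely discriminative band remains rank 1. Coefficients are fitted
  on Z-scored spectra — not on embedding coordinates — precisely so they
  map one-to-one onto wavenumbers.
* **Z-scoring** is per spectrum across wavenumbers (each spectrum to mean
  0, sd 1), matching normalization of individual absorption spectra
  before PCA; per-wavenumber standardization is available via
  `perWavenumber = TRUE`.
* **UMAP** is implemented in the package (exact kNN, smooth-kNN
  calibration to log₂(k) effective neighbours, probabilistic-union
  symmetrization, and an Rcpp stochastic-gradient layout with negative
  sampling and a linearly decaying learning rate). The layout uses its
  own seeded xorshift RNG, so embeddings are bit-reproducible for a given
  seed on any platform. Defaults: 20 PCA components, 15 neighbours,
  minimum distance 0.1, 200 epochs, 5000 spectra per sample type.

## Seeds and problem sizes

Every stochastic step takes an explicit seed; the pipeline fans a master
seed out deterministically per stage and ROI, and re-running an identical
configuration reproduces every CSV byte for byte. The packaged study
sizes are chosen for desk-scale validation: 96×96-pixel ROIs, 8 ROIs per
sample type, 2000 sampled pixels per ROI for integrals and
classification, 100-pixel occurrence subsets (the alternative 120-pixel
averaging scheme is a configuration knob), and a few hundred spectra per
type for embedding tests. All statistics converge quickly at these sizes:
the planted liver reduction, for example, is recovered within ~0.1
percentage point of 46.2% across seeds.

## Known limitations

* The FF "thirteen band" count refers to the library; with the stated
  trim the 966 cm⁻¹ band cannot be observed on the trimmed axis, so
  occurrence tables report at most twelve FF bands. This is a
  consequence of taking the printed trim literally and is flagged rather
  than silently patched.
* The 1154/1168 cm⁻¹ pair sits 14 cm⁻¹ apart with comparable widths;
  after smoothing their dips partially merge and per-pixel occurrence of
  the weaker partner fluctuates.
* Rubberband correction leaves concave stretches of a curved baseline in
  place by construction; the second derivative removes most, but not
  all, of the residual, which is why detection is calibrated against the
  background model rather than against zero.
* UMAP geometry (inter-cluster distances) is not metrically meaningful;
  only the ordering of silhouette contrasts is interpreted, never
  absolute embedding distances.
* Cubes are stored as multi-page TIFF with an affine scale/offset header
  sidecar (values quantized at ~2·10⁻¹⁰ of the data range, far below
  float32 resolution) plus a CSV wavenumber sidecar.
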