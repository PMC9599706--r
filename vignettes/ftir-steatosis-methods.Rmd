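---
title: "Methods: FTIR band deconvolution and chemometrics for hepatic steatosis spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FTIR band deconvolution and chemometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirsteat)
```

## The problem

Fourier-transform infrared (FTIR) absorbance spectra of cultured hepatocytes
report, in one trace, the cell's lipid and protein composition. In an
oleic-acid steatosis model, lipid loading changes the relative intensities of
the C–H stretching bands (asymmetric/symmetric CH~2~ at ~2920/2850 cm^-1^
versus CH~3~ at ~2960/2870 cm^-1^), the olefinic =CH band near 3010 cm^-1^,
and the ester carbonyl band at 1740 cm^-1^, while protein secondary structure
shifts appear as redistributions within the amide I envelope
(1700–1600 cm^-1^). A GLP-1 receptor agonist (Exendin-4) partially reverses
these changes. `ftirsteat` implements the complete analysis that turns raw
absorbance cohorts from three conditions (untreated, steatotic, Ex-4-treated)
into diagnostic band-ratio metrics, secondary-structure fractions,
chemometric summaries, and group statistics — plus a calibrated synthetic
generator that makes every step testable end to end.

## Preprocessing model

Each spectrum lives on a common, evenly spaced wavenumber grid; the default
acquisition grid spans 4000–1000 cm^-1^ with 6224 points (spacing
3000/6223 ≈ 0.482 cm^-1^), stored high-to-low as FTIR spectra are
conventionally presented. Preprocessing is fixed in this order:

1. **Area normalization** (`area_normalize()`): divide by the trapezoidal
   area under the full trace, so the spectrum integrates to 1 over its grid.
   Every downstream ratio is thereby exactly invariant to the raw intensity
   scale. "Full spectrum" here means the full 4000–1000 cm^-1^ analysis
   grid.
2. **Rubberband baseline** (`baseline_rubberband()`): subtract the lower
   convex hull of the (wavenumber, absorbance) points. The hull of a linear
   background is the background itself, so linear ramps are nulled exactly;
   the corrected trace is zero at hull touch points and the operation is
   idempotent. A least-squares polynomial mode (`baseline_polynomial()`,
   anchor windows 3900–3700, 2700–2000, 1000–980 cm^-1^) is retained for
   sensitivity checks.
3. **Windowing** (`extract_region()`): half-closed selection `[lo, hi)` on
   wavenumber values (inclusive of `lo`, exclusive of `hi`).

Baseline correction is applied per analysis window, not globally. One detail
matters in practice: the hull must anchor on *quiet* edges. The antiparallel
beta-sheet component (1692 cm^-1^) is still near half height at
1700 cm^-1^, so a hull clamped to the bare amide window would subtract a
wedge out of that band. Each band model therefore carries a *baseline
support* region whose edges sit in gaps between band groups (lipid:
2750–3100, its own window; ester and amide I share 1600–1780; amide II
1480–1600 cm^-1^); the hull is estimated on the support and the fit window
is cut out afterwards (`prepare_window()`).

## Band deconvolution

Windows are modeled as sums of Gaussian components
$h \exp\!\left(-4\ln 2\,(x - c)^2 / w^2\right)$ parameterized by height
$h$, center $c$, and full width at half maximum $w$; the closed-form
component area is $h\,w\sqrt{\pi/(4 \ln 2)} \approx 1.06447\,h\,w$.
`fit_bands()` works in two stages:

* **Stage 1 — fixed-shape linear fit.** With centers and FWHMs pinned to the
  assignment table, the window is a non-negative linear combination of
  Gaussian basis functions; heights come from a non-negative least-squares
  solve.
* **Stage 2 — bounded refinement.** Heights, centers, and FWHMs are refined
  by Levenberg–Marquardt with an analytic Jacobian, under bounds: heights
  ≥ 0, centers within ±6 cm^-1^ of the table, FWHMs in [8, 50] cm^-1^,
  cost tolerance 1e-10, at most 500 iterations. The ±6 cm^-1^ windows of
  neighbouring bands do not overlap, so components cannot swap identity.
  A `converged` flag records optimizer status; the best parameters are
  returned either way.

On exact in-model data (noiseless sums of in-bounds Gaussians with centers
≥ 10 cm^-1^ apart) the two-stage fit recovers all parameters to floating-
point accuracy, and the suite asserts this as a property over random draws.

**Why the amide window defaults to the fixed-shape fit.** The five amide I
components (antiparallel beta-sheet 1692, beta-turn 1680, alpha-helix 1655,
random coil 1640, beta-sheet 1625 cm^-1^) overlap so strongly that the
refinement problem is ill-conditioned: with widths free, minute structured
residuals — the flank of amide II entering at 1600 cm^-1^, the tiny mismatch
left by any baseline rule, ordinary noise — move area between neighbouring
components by far more than the perturbation itself. In simulation at the
package's default noise level, refined random-coil fractions were biased by
up to −0.11 while the fixed-shape fit stayed within ~0.012 of truth.
`amide_deconvolution()` therefore defaults to `refine = FALSE` (heights
only, shapes from the assignment table), which is also the plain reading of
a linear model in Gaussian basis functions; `refine = TRUE` remains
available. The lipid window (five bands, better separated relative to their
widths) keeps the full two-stage fit; its cohort-mean ratio bias is below
~2% under default noise.

## Metrics

* `lipid_metrics()` — ratios of **fitted component heights**:
  V~as~(CH~2~)/V~as~(CH~3~) (2920/2960), V~s~(CH~2~)/V~s~(CH~3~)
  (2850/2870), V~as~(CH~2~)/olefinic (2920/3010, the unsaturation metric,
  reported exactly as defined with the olefinic band in the denominator),
  and the integrated 1740 cm^-1^ ester carbonyl area. Height ratios are the
  convention for the stretching bands; `use = "area"` switches to
  closed-form area ratios.
* `amide_deconvolution()` — secondary-structure **area fractions**:
  component area over the summed area of the five fitted amide I
  components. The raw 1700–1600 cm^-1^ integral is *not* used as the
  denominator; summed component areas keep the fractions self-consistent
  (they add to 1 by construction). Derived ratios
  (alpha/amide I, coil/amide I, sheet/amide I, sheet/alpha) are populated.
  The sheet/alpha and sheet/amide I ratios are computed but not calibrated
  against any external reference, because published per-ratio values of
  this kind are generally not mutually consistent as pure area fractions.
  Amide II is fit as a single band for intensity reporting only and
  contributes no structure fractions, since its assignments are not
  structure-specific.

## Chemometrics

`run_pca()` performs covariance PCA: column-mean centering (no
unit-variance scaling, so loadings retain band-intensity structure — a
`scale` flag is provided), singular value decomposition, and a fixed sign
convention (the largest-magnitude loading coefficient of each component is
made positive) so outputs are reproducible across linear-algebra backends.
Scores, orthonormal loadings, and explained-variance fractions follow the
usual definitions. `per_wavenumber_r2()` reports, per wavenumber and
component, the share of that column's centered sum of squares explained by
the component; orthogonality makes these shares sum to 1 over all
components. `hca_ward()` clusters the q-dimensional score rows (not raw
spectra) by Ward's minimum-variance criterion on Euclidean distances; merge
heights follow the convention in which the squared height is twice the
within-cluster variance increase. `class_representatives()` averages score
rows per condition, `representatives_dendrogram()` clusters those three
centroids (the condition-level tree, with Newick export), and
`biplot_table()` assigns each wavenumber to the condition whose score
centroid makes the smallest angle with its PC1–PC2 loading vector —
loadings below 5% of the maximum norm, or exact ties, are labeled
`"none"`. The angular rule is a documented convention, configurable, not a
fitted quantity.

## Group statistics

`anova_tukey()` runs a one-way ANOVA across conditions followed by Tukey's
HSD on all pairwise contrasts in the Tukey–Kramer form, which handles the
unbalanced 70/80/80 design. Stars map adjusted p-values at 0.05, 0.01,
0.001, 0.0001. Summaries report mean ± SE with SE = SD/√n. If the response
is constant overall the F statistic is undefined; it is reported as 0 with
p = 1 and a `degenerate` flag. The pooled per-spectrum analysis treats
spectra as exchangeable across replicate cultures; spectra acquired from
the same culture are pseudo-replicates, and no random effect for culture is
modeled — a caveat users should keep in mind when interpreting p-values on
real data.

## The synthetic generator

`generate_spectrum()` draws absorbance = baseline + Σ Gaussian bands +
i.i.d. Gaussian noise on the 6224-point grid. The band table and the three
condition presets are shipped as a versioned YAML file
(`system.file("extdata", "presets.yaml", package = "ftirsteat")`):

* Shared band centers/FWHMs: olefinic 3010/14, V~as~CH~3~ 2960/24,
  V~as~CH~2~ 2920/28, V~s~CH~3~ 2870/22, V~s~CH~2~ 2850/20, ester 1740/26,
  amide II 1545/40; amide I components 1692/16, 1680/18, 1655/22, 1640/20,
  1625/18 cm^-1^ — centers chosen inside the literature assignment windows
  (beta-sheet 1635–1610, random coil 1645–1630, alpha-helix 1660–1650,
  beta-turn/antiparallel 1695–1665 cm^-1^). FWHMs are typical condensed-
  phase bandwidths; they are fixed in the preset file so results are
  reproducible.
* Condition heights are calibrated so the *true* generating ratios equal
  the reference means the pipeline should recover: V~as~ ratio 1.65 /
  1.53 / 1.63 and V~s~ ratio 1.35 / 0.97 / 1.14 for untreated / steatotic /
  Ex-4, alpha-helix fractions 0.55 / 0.68 / 0.60 and random-coil fractions
  0.28 / 0.16 / 0.22, with the minor sheet/turn/antiparallel fractions
  closing each sum to 1.
* Variability: per-band mean-preserving log-normal height factors
  (CV 0.03 — so cohort-mean heights equal the preset values and heights
  stay positive), Gaussian center jitter (SD 0.5 cm^-1^), additive noise
  (SD 0.004 a.u.), and a fixed linear baseline
  0.02 + 5·10^-6^·(wavenumber − 1000). The log-normal/jitter perturbation
  is applied to all bands, including the amide I components; a cohort with
  zero within-group amide variability would make the amide group statistics
  degenerate. Within-group dispersion is not calibrated to any published
  ±SD values, only the means are.
* Seeding: each cohort takes one seed; spectrum *i* uses the derived stream
  seed `(seed·100003 + i) mod (2^31 − 1)`, so cohorts are reproducible
  across runs and platforms.

What the generator deliberately does **not** emulate: Mie and resonance-Mie
scattering, water-vapor/CO~2~ lines, detector nonlinearity, instrument
line-shape convolution, correlated (non-diagonal) noise, and
culture-to-culture (batch) structure. Passing recovery tests on synthetic
cohorts therefore demonstrates that the *algorithms* are correct and
unbiased under in-model perturbations — not that real cellular spectra meet
these assumptions.

## Numerical choices and degenerate inputs

* Unit-area contract of normalization is 1e-9 (trapezoidal); zero or
  negative total area is an error (pathological spectrum).
* Grid validity: strictly monotone, spacing constant to 1e-9 relative;
  either orientation accepted and canonicalized to decreasing.
* The lower convex hull is computed by an Andrew monotone-chain walk;
  collinear points are dropped (cross product ≤ 0), which keeps the
  hull minimal and the correction idempotent.
* Polynomial baseline shifts the corrected trace so its minimum over the
  anchor points is zero, matching the hull contract (≥ 0 at anchors); when
  no named anchor region intersects a windowed spectrum the outer 10% of
  the window at each edge is used.
* Band identity after refinement is guaranteed by disjoint center-bound
  windows, not by post-hoc relabeling.
* PCA requires n ≥ 2 and q ≤ min(n, p); zero-variance columns yield `NA`
  in per-wavenumber R². Clustering requires ≥ 2 spectra. ANOVA requires
  ≥ 2 groups with ≥ 2 values each.

## Problem sizes

The test suite and the acceptance script run the recovery checks at the
study design sizes (70/80/80 spectra per cohort, full 6224-point grid,
lipid window ≈ 726 points, amide window ≈ 207 points). A full cohort of 80
spectra generates and deconvolves in a few seconds on one core; the
complete pipeline over 230 spectra, all four windows, PCA, clustering and
statistics runs in well under a minute.

## Known limitations

* Gaussian line shapes only; Lorentzian/Voigt profiles are out of scope.
* The amide I decomposition is reported with shapes pinned to the
  assignment table by default; on spectra whose true component widths
  deviate strongly from those values the fractions will inherit that
  mismatch (use `refine = TRUE` and inspect `residual_rms` to probe this).
* No scattering correction is provided; spectra needing Mie/EMSC correction
  should be corrected before import.
* The biplot association rule is a convention for summarizing loading
  geometry; it does not test association statistically.
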