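# ftirsteat

Analysis pipeline for FTIR absorbance spectra of cultured hepatocytes in an
oleic-acid steatosis model with GLP-1-agonist (Exendin-4) treatment. The
package is written for spectroscopists and analysts who have cohorts of
absorbance spectra on a common wavenumber grid, one condition label per
spectrum (untreated / steatotic / ex4), and want the standard downstream
quantities:

* **Preprocessing** — area normalization (unit integral over the
  4000–1000 cm⁻¹ grid) and rubberband (lower convex hull) baseline
  correction per analysis window.
* **Gaussian band deconvolution** — each window is modeled as a sum of
  Gaussian components *h* · exp(−4 ln2 (x − c)² / w²); a non-negative linear
  solve with shapes fixed at the assignment table, followed (for the lipid
  bands) by bounded Levenberg–Marquardt refinement. Component area is the
  closed form *h·w·√(π/(4 ln 2))* ≈ 1.06447 *h·w*.
* **Diagnostic metrics** — V_as(CH₂):V_as(CH₃) (2920/2960 cm⁻¹) and
  V_s(CH₂):V_s(CH₃) (2850/2870 cm⁻¹) fitted-height ratios, the
  V_as(CH₂):olefinic unsaturation metric, the integrated 1740 cm⁻¹ ester
  carbonyl intensity, and amide I secondary-structure area fractions
  (antiparallel β-sheet, β-turn, α-helix, random coil, β-sheet) from the
  1700–1600 cm⁻¹ five-component deconvolution.
* **Chemometrics** — covariance PCA (scores, orthonormal loadings,
  explained-variance fractions, per-wavenumber R², biplot association
  table) and Ward hierarchical clustering in PC score space, with
  condition-level centroid representatives.
* **Statistics** — one-way ANOVA with Tukey HSD (Tukey–Kramer for the
  unbalanced 70/80/80 design) and star annotations per pairwise contrast.
* **Synthetic cohorts** — a calibrated generator (`generate_cohort()`,
  `generate_study()`) whose condition presets have *known* generating
  ratios and fractions, so the whole pipeline is validated by parameter
  recovery.

## Worked example

```r
library(ftirsteat)

res <- run_pipeline(
  default_run_config(seed = 1, cohorts = c(untreated = 10, steatotic = 10, ex4 = 10)),
  out_dir = "run1", quiet = TRUE)

aggregate(cbind(vas_ratio, vs_ratio, frac_alpha_helix, frac_random_coil, ester_area)
          ~ condition, res$metrics, mean)
#>   condition vas_ratio vs_ratio frac_alpha_helix frac_random_coil ester_area
#> 1       ex4      1.58    1.151            0.590            0.215     0.0280
#> 2 steatotic      1.55    0.994            0.665            0.165     0.0340
#> 3 untreated      1.64    1.367            0.533            0.283     0.0232

subset(res$stats$pairwise, metric == "vs_ratio")
#>     metric            contrast    diff    p_adj stars
#> 4 vs_ratio       steatotic-ex4 -0.1567 2.12e-06  ****
#> 5 vs_ratio       untreated-ex4  0.2169 5.14e-09  ****
#> 6 vs_ratio untreated-steatotic  0.3736 2.85e-14  ****
```

Reading the output: steatotic spectra show lower CH₂:CH₃ stretching ratios
(vs_ratio 0.99 vs 1.37 untreated), a higher ester carbonyl intensity (lipid
accumulation), a higher α-helix fraction and a lower random-coil fraction;
the Ex-4 cohort sits between the two, and every pairwise vs_ratio contrast
is significant after Tukey adjustment. The pipeline writes all intermediate
artifacts (spectra, metrics, PCA scores/loadings/R², dendrogram merge list,
biplot table, stats tables, manifest) as plain CSV/JSON under `out_dir`, so
any stage can be inspected or re-run in isolation.

Per-stage functions are exported if you want the steps individually:
`read_spectra()` / `write_spectra()`, `area_normalize()`,
`baseline_rubberband()`, `extract_region()`, `fit_bands()`,
`lipid_metrics()`, `amide_deconvolution()`, `run_pca()`, `hca_ward()`,
`biplot_table()`, `anova_tukey()`.

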