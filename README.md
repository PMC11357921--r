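# ctrwdwi

Continuous-time random-walk (CTRW) diffusion modelling of multi-b-value
diffusion-weighted MRI (DWI), with the downstream statistics used to relate
diffusion parameters to tumour pathology.

## What problem this addresses

Conventional DWI summarises tissue water diffusion with a single apparent
diffusion coefficient (ADC), assuming Gaussian diffusion in a homogeneous
medium. Tumour tissue — bladder cancer in the motivating application — is
heterogeneous, and its high-b-value signal decay is visibly
non-mono-exponential. The CTRW model represents that decay as

S(b) = S₀ · E_α[−(bD)^β]

where E_α is the one-parameter Mittag-Leffler function
E_α(z) = Σₖ zᵏ / Γ(αk+1), D (mm²/s) is an anomalous diffusion coefficient
linked to cellularity, and α, β ∈ (0, 1] capture temporal and spatial
diffusion heterogeneity. α = β = 1 recovers S = S₀e^(−bD) exactly. Radiology
studies use the fitted D/α/β maps (alongside the two-point ADC from b = 0
and 800 s/mm²) to discriminate pathological grade and variant histology of
lesions noninvasively.

The package provides, as tested building blocks:

- `ml_eval()` / `ml_series()` — an accurate Mittag-Leffler evaluator
  (Taylor series + parabolic-contour Laplace inversion; absolute error
  ≤ 1e−12 on the model's argument range) and its naive-series test oracle;
- `fit_volume()` with `fit_mono_exp_D()` and `fit_alpha_beta()` — the
  segmented voxelwise fit (mono-exponential D from b ≤ 1000 s/mm², then
  bounded Levenberg–Marquardt for α, β with D fixed), producing D/α/β/ADC
  maps with per-voxel status, plus NIfTI + b-table I/O;
- `generate_phantom()`, `generate_cohort()`, `generate_enrollment()` —
  synthetic DWI phantoms with per-excitation Rician noise and NEX
  averaging, and an 81-lesion cohort generator calibrated to published
  group medians/IQRs (15 low / 66 high grade, 51 pUC / 30 variant
  histology);
- `roi_mean()`, `average_readers()`, `interobserver_icc()` — ROI
  statistics and two-reader agreement via ICC(2,1) with F-based CI;
- `compare_groups()`, `roc_analysis()`, `delong_compare()`,
  `logistic_combine()`, `run_study_analysis()` — normality-gated group
  tests, ROC with Youden operating points, paired DeLong AUC comparison,
  and the univariate/multivariate logistic combination of CTRW markers.

A thin command-line front end lives at `inst/cli/ctrwdwi`
(`fit`, `simulate`, `analyze` subcommands).

## Worked example

```r
library(ctrwdwi)

# A calibrated synthetic cohort: 81 lesions, two readers per parameter
cohort <- generate_cohort(seed = 42)

icc <- interobserver_icc(cohort$alpha_r1, cohort$alpha_r2)
# alpha ICC(2,1): 0.890 (95% CI 0.834-0.928), band: perfect

report <- run_study_analysis(cohort, contrasts = "grade")
report$grade$roc$alpha
# ROC: AUC 0.900 (95% CI 0.834-0.966), cutoff 0.8191 (lower = positive 'high')
#   sensitivity 78.79%, specificity 100.00%, accuracy 82.72%

report$grade$comparisons$alpha$p_value     # Mann-Whitney, 1.5e-06
report$grade$delong_combined_vs_adc
# combined D+alpha AUC 0.992 vs ADC 0.862 (DeLong p = 0.023)

# A 32x32 phantom at SNR 50, fitted voxel by voxel
ph   <- generate_phantom(phantom_spec(snr = 50, seed = 42))
maps <- fit_volume(ph$series)
roi_mean(maps$alpha, label_mask(ph$labels, 2L, erode = TRUE))
# mean alpha 0.724 over 196 voxels (generating value 0.783; the deficit is
# the documented bias of the segmented procedure under noise)
```

The numbers above are the actual output at these seeds. Lower ADC, D and α
in the high-grade group, α as the strongest single grading marker, an
uninformative β, and a combined D+α model beating ADC mirror the clinical
pattern the generator is calibrated to; the combined model's optimism
reflects the generator's independence assumption (see the methods
vignette, `vignettes/ctrw-dwi-methods.Rmd`).

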