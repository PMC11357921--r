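---
title: "CTRW diffusion modelling of multi-b-value DWI: models, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CTRW diffusion modelling of multi-b-value DWI: models, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The signal model

Water diffusion in tumour tissue deviates from the Gaussian behaviour that
underlies the conventional apparent diffusion coefficient (ADC). The
continuous-time random-walk (CTRW) description admits heterogeneous waiting
times and step lengths for diffusing water molecules, and leads to the
signal representation

$$S(b) = S_0 \, E_\alpha\!\left[-(bD)^\beta\right],$$

where $b$ is the diffusion weighting (s/mm^2), $D$ is an anomalous
diffusion coefficient (mm^2/s, linked to cellularity), $\alpha \in (0,1]$
and $\beta \in (0,1]$ are the temporal and spatial diffusion-heterogeneity
exponents, and $E_\alpha$ is the one-parameter Mittag-Leffler function

$$E_\alpha(z) = \sum_{k=0}^{\infty} \frac{z^k}{\Gamma(\alpha k + 1)}.$$

With $\alpha = \beta = 1$ the model collapses exactly to the
mono-exponential $S = S_0 e^{-bD}$; lower exponent values flatten the decay
at high $b$. The conventional ADC is kept as the comparison standard and is
computed from the $b=0$ and $b=800$ s/mm^2 images alone,
$ADC = \ln(S_0/S_{800})/800$ (`adc_two_point()`), not from a multi-b
regression.

The default acquisition (`default_bvalue_scheme()`) uses 11 b-values
0-3000 s/mm^2 with per-b excitation counts (NEX)
1, 1, 1, 1, 1, 2, 4, 6, 8, 14, 16: heavier averaging where the magnitude
signal is weakest.

## Evaluating the Mittag-Leffler function

`ml_eval()` must be accurate on the arguments the model produces,
$z = -(bD)^\beta \in [-50, 0]$ in practice, and fast enough for voxelwise
fitting. Evaluation is split by region:

* $|z| \le 1$: the defining Taylor series, summed to a term tolerance of
  1e-18. Inside this radius the terms decay promptly and cancellation is
  mild, so the series is both the fastest and the most accurate choice;
  the switch radius 1 was verified by overlap tests against the contour
  route.
* elsewhere: numerical inversion of the Laplace transform
  $s^{\alpha-1}/(s^\alpha - z)$ on the parabolic contour
  $s(u) = \mu(1+iu)^2$ with the trapezoidal rule (step $h = 0.05$,
  truncated where $|e^{s}|$ falls below 1e-19). Trapezoidal sums of
  analytic contour integrands converge geometrically; the step was chosen
  so the discretisation error is negligible against double precision.
  The contour scale is $\mu = 6$ for $\alpha \le 1$, keeping the round-off
  amplification $e^\mu \varepsilon$ under 1e-12. For $\alpha \in (1, 2]$
  the transform has conjugate poles at $|z|^{1/\alpha} e^{\pm i\pi/\alpha}$;
  $\mu = 9$ keeps them away from the contour, and any pole that falls
  inside the contour contributes its residue $2\,\mathrm{Re}\,
  e^{s^\ast}/\alpha$. For $z > 0$ the pole at $z^{1/\alpha}$ on the
  positive axis is handled the same way.

The accuracy contract is an absolute error below 1e-12 for
$0 < \alpha \le 1$, $z \in [-50, 0]$, and about 1e-10 for
$\alpha \in (1, 2]$ at moderate arguments. It is verified in the test suite
against closed forms ($E_1(z) = e^z$, $E_{1/2}(z) = e^{z^2}
\mathrm{erfc}(-z)$, $E_2(-x) = \cos\sqrt{x}$), against a frozen grid of
50-digit arbitrary-precision reference values, and against the asymptotic
expansion $-\sum_k z^{-k}/\Gamma(1-\alpha k)$ at large $|z|$. The truncated
series itself is exported as `ml_series()` and deliberately kept naive: it
is the independent oracle, not the production path.

A note on the reference values: for small $\alpha$ the high-precision
series itself becomes infeasible at large $|z|$ (its peak term grows like
$e^{|z|^{1/\alpha}}$), so the deep reference points were generated from the
completely monotone spectral representation of $E_\alpha(-x)$, with the
integration variable substituted as $r = v^{1/\alpha}$ to remove the
endpoint singularity; both routes agree to ~50 digits where both converge.

## Segmented voxelwise fitting

`fit_volume()` reproduces the two-step fit used in clinical CTRW work:

1. `fit_mono_exp_D()`: $D$ and $S_0$ from the images with
   $b \le 1000$ s/mm^2 by least squares in the linear signal domain
   (Levenberg-Marquardt, initialised from the log-linear regression, which
   is also kept as an internal oracle). $D$ is constrained to
   $(10^{-6}, 10^{-2})$ mm^2/s; estimates pinned at a bound are flagged
   `clipped`.
2. `fit_alpha_beta()`: $(\alpha, \beta)$ from all b-values with $D$ *and*
   $S_0$ fixed at their step-1 estimates, by bound-constrained
   Levenberg-Marquardt on $(0.01, 1]^2$, initialised at
   $\alpha_0 = \beta_0 = 0.9$ (the centre of the range observed in bladder
   tumours). Fixing $S_0$ keeps step 2 a two-parameter problem, matching
   the published description of the procedure; convergence tolerances are
   1e-10 with at most 200 iterations, and the whole fit is deterministic.

Estimates at the upper bound 1 are not flagged: the mono-exponential
special case legitimately sits on the boundary of the CTRW parameter
space.

**A property worth knowing.** For data generated by the CTRW model with
$\beta < 1$, the low-b decay is *not* mono-exponential, so step 1 is a
deliberately misspecified fit and its $\hat D$ is biased low (about 6% at
the low-grade reference medians, noiselessly), a bias this segmented
procedure inherits by construction and which propagates mildly into
$(\hat\alpha, \hat\beta)$. The test suite therefore checks exact recovery
where it is mathematically attainable - $D$ on mono-exponential data,
$(\alpha, \beta)$ given the generating $D$, and all maps on an
$\alpha=\beta=1$ phantom - and checks the noisy behaviour of the full
pipeline against a Monte-Carlo oracle rather than against the generating
truth.

Voxel masking defaults to 5% of the robust (99th percentile) maximum of the
$b=0$ volume, which removes air and background the way manual ROI protocols
exclude unusable regions.

## What the synthetic data emulate

`generate_phantom()` simulates magnitude MRI: per excitation, the observed
signal is $\sqrt{(S+g_1)^2 + g_2^2}$ with independent Gaussians of scale
$S_0(b{=}0)/\mathrm{SNR}$ (Rician noise), then the magnitudes are averaged
over the scheme's NEX for that b-value. The noise generator is validated
against the closed-form Rician mean (`rician_mean()`, evaluated through
exponentially scaled Bessel functions) and the $1/\sqrt{\mathrm{NEX}}$
noise reduction. The default phantom is a 32 x 32 x 1 grid of four tissues
spanning the extremes of the reference lesion distributions. Not emulated:
anatomy, partial-volume effects, motion, eddy currents, and the
magnitude-averaging order effects of scanner reconstruction; phantom
results therefore speak to estimator behaviour under Rician noise, not to
acquisition artifacts.

`generate_cohort()` draws an 81-lesion cohort (15 low grade / 66 high
grade; 51 pure urothelial / 30 variant histology; stages 4/39/16/11/11
across pTa-pT4). Each lesion's true parameter vector comes from log-normal
distributions calibrated so the population median and IQR of each group
match the reference table: $\mu = \ln(\mathrm{med})$ and
$\sigma = \mathrm{IQR}/(\mathrm{med}\cdot 2\Phi^{-1}(0.75))$. The
log-normal family was chosen for positivity and because the reference data
are reported as medians with IQRs (i.e. non-normal); the small-$\sigma$
approximation in the IQR formula is exact to $(q\sigma)^2/6 < 0.2\%$
relative for every calibrated cell. Design points:

* **Clipping.** $\alpha, \beta$ draws are clipped to $(0, 1]$. Under the
  default calibration about 2.5% of draws clip (dominated by low-grade
  $\beta$, whose calibrated distribution has substantial mass above 1).
  Because the clip point lies above every group's third quartile, medians
  and IQRs are unaffected; the realised rate is recorded in the
  `clip_rate` attribute.
* **Reader noise.** Two reader measurements add independent Gaussian noise
  with sd equal to 3% of the group median, a level chosen once so the
  simulated two-reader ICCs land in the published near-perfect band
  (roughly 0.88-0.95); the analyzed value is the reader average. This is a
  modelling assumption, not an estimate of the study's true reader
  variability.
* **One contrast is calibrated at a time.** `group_by = "grade"` (default)
  draws parameters conditional on grade and assigns variant histology
  preferentially to high-grade lesions, so the pUC/VH contrast emerges
  only through its association with grade; `group_by = "variant"`
  calibrates the pUC/VH cells instead. A single draw cannot satisfy both
  marginal tables exactly without the joint distribution, which is not
  reported.
* **Independence.** Parameters are drawn independently within a lesion.
  Real ADC, D and alpha are strongly correlated; this limits the fidelity
  of any quantity that depends on the joint distribution, most visibly the
  combined-model AUC and the razor-thin D-vs-ADC ordering (the calibrated
  marginals put their population grading AUCs within ~0.001 of each
  other, so that ordering is reproduced only in the median over many
  simulated cohorts, not per cohort).

`generate_enrollment()` reproduces the screening funnel (107 screened, 81
analyzable; exclusions 12/1/4/9) as a labelled table for exercising cohort
filters.

## ROI statistics and reader agreement

`roi_mean()` averages a map channel over a mask, excluding NaN voxels
(failed fits, non-positive signals) and reporting the voxel count used.
`interobserver_icc()` implements the two-way random-effects,
absolute-agreement, single-measure ICC - ICC(2,1) - from the ANOVA mean
squares, with the F-based confidence interval using Satterthwaite degrees
of freedom; no installed package provides this form, so it is implemented
directly and validated in the tests against an independent reference
implementation and against mean squares obtained from `aov()`. Point
estimates are banded at 0.2-wide cut points (poor/fair/moderate/good/
perfect). The agreement model treats lesions and readers as random; with
only two readers the rater variance component is weakly identified, which
the absolute-agreement form accounts for.

## Group-level analysis

`compare_groups()` gates on Shapiro-Wilk normality (each group at 0.05;
both must pass) between Student's t-test and the Mann-Whitney U test, and
formats summaries accordingly (mean +/- sd vs median (IQR)).

`roc_analysis()` computes the empirical ROC with AUC and a 95% DeLong
confidence interval; the operating point maximises the Youden index over
cutoffs placed midway between adjacent distinct marker values, breaking
ties toward higher sensitivity (the tie-break is unspecified in common
clinical software; maximising sensitivity favours detection). The AUC is
verified in the tests to coincide with the tie-corrected Mann-Whitney
statistic $U/(n_1 n_2)$ (`auc_mann_whitney()`), and the Youden point is
verified exhaustively. `delong_compare()` performs the paired DeLong test,
with rank-identical markers reported as the degenerate case (difference 0,
p = 1). ROC and DeLong machinery are delegated to the pROC package behind
this interface.

`logistic_combine()` reports per-marker univariate Wald p-values, admits
markers significant at 0.05 into one multivariate logistic model, and
returns its linear predictor as the combined score. Two edge policies:
a marker whose univariate fit shows (quasi-)separation is admitted even
though its Wald p collapses toward 1 (separation is maximal association,
and the Wald statistic is the wrong lens there); rank-deficient feature
sets are flagged and the aliased columns dropped. `run_study_analysis()`
orchestrates all of this per contrast and `write_study_report()` emits
JSON and CSV outputs, including ROC coordinates for plotting.

## Problem sizes and reproducibility

The test suite and the acceptance script size their simulations as: a
32 x 32 phantom at SNR 50 with a 256-fit Monte-Carlo oracle per checked
tissue; 2000 replicates for every stochastic calibration (the mean
grading AUC of alpha, DeLong and logistic type-I error, and the
median-AUC parameter ordering); 100 cohorts for the combined-model
comparison. All generators are deterministic under their seed arguments,
which never touch the caller's RNG state.

## Known limitations

* The segmented fit inherits the step-1 bias described above; it is the
  published procedure, not a maximum-likelihood CTRW estimator.
* The cohort emulation reproduces marginal group distributions, not the
  joint correlation structure of real lesions, and calibrates one
  pathology contrast at a time.
* ADC uses exactly two b-values; no noise-floor correction is applied in
  either fitting step.
* ROIs are consumed as masks; delineation itself (and 3-D whole-tumour
  volumetry) is out of scope.
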