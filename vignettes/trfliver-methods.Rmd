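---
title: "Models and methods behind trfliver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trfliver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`trfliver` is a simulation-and-analysis pipeline for time-resolved
fluorescence (TRF) optical biopsy of liver tissue. This vignette explains the
models it implements, the assumptions baked into the synthetic-data
generator, the numerical choices in the fitting and classification stages,
and what the passing test suite does and does not establish about real
clinical data.

## The decay model

Time-correlated single-photon counting (TCSPC) histograms the arrival times
of single fluorescence photons after pulsed excitation. At 375 nm excitation
the emission of liver tissue is dominated by NAD(P)H, whose free form decays
with a short lifetime (`tau1`, hundreds of picoseconds) and whose
protein-bound form with a long lifetime (`tau2`, a few nanoseconds). The
package models every spectrum with the bi-exponential decay

    I(t) = I_noise + I0 * [ alpha1 * exp(-t/tau1) + alpha2 * exp(-t/tau2) ]

with relative contributions constrained to `alpha1 + alpha2 = 100%` and a
constant background `I_noise` (counts per bin). The observed histogram is
this decay convolved with the instrument response function (IRF) and
corrupted by Poisson counting noise: each bin is an independent Poisson draw
whose mean is the noiseless model value. The per-spectrum diagnostic feature
vector is `(I_f, alpha1, alpha2, tau1, tau2)`, where `I_f` is the total
fluorescence intensity.

## What the simulator emulates

The generator reproduces the statistical structure of a clinical TRF biopsy
study with four tissue classes -- liver parenchyma, benign tumor (BT),
hepatocellular carcinoma (HCC) and metastases (MTS) -- in which group
statistics are reported as mean and standard error (SE) of the mean over a
known number of spectra per group. `study_class_params()` carries those
group parameters; per-spectrum values are drawn from Gaussians with the
group mean and standard deviation `SE * sqrt(n)`, truncated to the physical
support (`I_f > 0`, `0 < alpha2 < 100`, positive lifetimes) by resampling.
Spectra are grouped ten to a measurement point and two points to a synthetic
patient, mirroring the acquisition pattern of needle-tract measurements.

Fixed generator choices, each configurable but chosen once:

* **Time base**: 12,500 ps window, 1,024 bins (about 12.2 ps/bin). No
  window or binning is reported for the instrument being emulated; this grid
  resolves lifetimes between roughly 300 and 3,000 ps with ample margin.
* **IRF**: Gaussian, FWHM 180 ps, unit area, centered at 1,000 ps -- a
  typical width for a hybrid-detector TCSPC chain. A zero-FWHM (single-bin
  impulse) option supports analytic tests.
* **Background**: 2 expected counts per bin, Poisson.
* **Short lifetime `tau1`**: group means for `tau1` are not available
  numerically, so all classes default to 450 ps with SE 10 ps -- a typical
  free-NAD(P)H value. This is an explicit assumption, never used as a
  recovery target.
* **BT-comparison intensity**: the BT/liver intensity difference is reported
  as non-significant, with no numbers; the defaults (1.00e6 vs 1.03e6
  counts, SE 0.05e6) keep that difference non-significant at the group
  sizes used.
* **Feature independence**: cross-feature covariance within a spectrum is
  unknown and defaults to independent draws.

Two features of real data the simulator deliberately does **not** reproduce:
within-patient clustering of spectra (real needle-tract points share
physiology; simulated spectra are exchangeable within a class), and
cross-feature correlation. Classifier metrics measured on simulated cohorts
therefore quantify the pipeline's mechanics, not expected clinical
performance. One printed dispersion is physically awkward: the MTS intensity
SE (0.63e6 counts at n = 310) converts to a per-spectrum SD of about 1.1e7
counts, far wider than the positive support, so the truncated sampler's
realized `I_f` mean for MTS sits well above the nominal group mean. The
lifetime and contribution features are unaffected.

## Fitting

`fit_biexponential()` minimizes the Neyman-weighted sum of squares
`sum((counts - model)^2 / max(counts, 1))` with the Levenberg-Marquardt
algorithm (`minpack.lm`), the standard weighting for photon-counting data
and the one that makes the reduced chi-square interpretable (calibrated near
1 for a correct model; verified at 500 replicates in the tests).
Numerical choices:

* **Parameterization**: the optimizer works in `(log I0, I_noise, log tau1,
  log tau2, logit(alpha2/100))` with a box constraint `I_noise >= 0`, which
  encodes positivity and the 0--100% range smoothly and leaves
  `alpha1 = 100 - alpha2` exact by construction.
* **Reconvolution vs tail fit**: with an IRF the model is the discrete
  causal convolution (FFT-based) of the bi-exponential kernel with the
  unit-area IRF, fitted from the IRF rise to the window end; without one, a
  tail fit from the peak bin with the decay clock starting at the peak.
* **Initialization**: background from the pre-rise bins (identified by a
  counting-noise threshold so the IRF ramp is excluded), lifetimes from a
  two-segment log-linear fit of the background-subtracted tail, `alpha2`
  from the late-segment intercept clamped to [5, 95]; degenerate inputs
  fall back to `tau1 = 500`, `tau2 = 2500`, `alpha2 = 35` with a warning.
* **Restart policy**: if the data-driven start converges to a collapsed
  optimum (reduced chi-square above 2 or lifetimes within 50 ps of each
  other) the fit restarts once from the generic defaults and keeps the
  better optimum. Without this, roughly one fit in sixty on realistic
  Poisson data lands in a mono-exponential local minimum.
* **Identifiability conventions**: `tau1 < tau2` is enforced by
  swap-and-relabel at convergence; fits whose lifetimes collapse within
  50 ps are flagged effectively mono-exponential and reported as
  `alpha2 = 100`.
* **Intensity definition**: `I_f` is the background-corrected total count,
  `sum(counts) - n_bins * I_noise`, floored at zero -- chosen over the
  fitted-curve integral because it is robust to small shape misfit; the two
  agree on noiseless data.

## Feature selection

The data-preparation stage applies, in order: a variance filter (sample
variance with denominator n-1, computed on raw unstandardized values,
strictly below 1 excluded), a pairwise correlation filter (|Pearson r| above
0.7; for each violating pair the member kept is the one earlier in the
priority list, by default `alpha2` over `alpha1`, otherwise the
higher-variance member), standardization to zero mean and unit variance
using training-set statistics only, and a PCA explained-variance audit. The
absolute value in the correlation rule matters: the `alpha1`/`alpha2`
complement pair has r = -1 exactly. The variance filter runs on raw values
because standardized features all have variance 1 and would never trigger a
threshold of 1. PCA is an audit only -- on four retained features that are
nearly uncorrelated each component explains about 25% of the variance, so
no dimensionality is actually removed and the classifiers consume the
original features.

## Classification protocol

Each comparison (BT/liver, HCC/liver, MTS/liver, and the three-class tumor
problem) is evaluated with repeated stratified 80/20 train/test splits
(default 10 reshuffles), at the spectrum level: spectra from one simulated
patient may appear in both sets, which matches the acquisition-driven
expansion of the emulated study design and is a known optimistic bias of
that design. Stratification preserves class ratios in the 20% test sets; no
class reweighting is applied, and the imbalance ratio is recorded in every
report. Four models are supported: an LDA baseline (conventionally
restricted to `alpha2` and `tau2`, the two strongest single features), a
100-tree random forest with bootstrap resampling and `sqrt(d)` candidate
features per split, a polynomial-kernel SVC (degree 3, cost 1), and
unpenalized maximum-likelihood logistic regression (binomial GLM for binary
problems, multinomial otherwise). Scores feeding the ROC are vote fractions
(forest), decision-function values (binary SVC) or Platt probabilities
(multiclass SVC), and fitted probabilities (LR, LDA posterior); class
predictions use the 0.5/argmax convention. Sensitivity treats the tumor
class as positive. Undefined metrics (zero denominators) propagate as `NA`,
never as 0. A test split that degenerates to a single class is redrawn from
the next derived seed.

The Mann-Whitney U comparison behind the group-statistics table uses the
exact null distribution when the pooled sample size is at most 20 and there
are no ties, and the normal approximation with tie and continuity correction
otherwise; tests are two-sided.

## Determinism and problem sizes

Every stochastic stage takes a seed; `run_pipeline()` derives all stage
seeds from one master seed, so feature tables are bit-identical and every
reported metric reproducible across runs. The test suite exercises the full
published group sizes where the science depends on them (97 + 129 spectra
for the HCC comparison, 310 MTS, 120 BT; 500 replicates for the chi-square
calibration; 200 cohort replicates for the rank-test power check) and
scaled-down cohorts (20--60 spectra per class) where only the mechanics are
under test.

## Known limitations

* Group parameters enter as independent per-feature Gaussians; real decay
  features co-vary within a spectrum and within a patient.
* The simulator does not model detector afterpulsing, dead time, pile-up or
  spectral structure; the IRF is stationary and noise-free.
* The fitted model and the generator share the same discrete convolution,
  so round-trip tests validate the estimator, not the physics of a real
  instrument chain.
* Classification metrics on synthetic cohorts depend strongly on the
  assumed feature independence and are not predictions of clinical
  performance.
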