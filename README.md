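# trfliver

Time-resolved fluorescence (TRF) optical biopsy of the liver records, through
a fine-needle probe, the decay of NAD(P)H autofluorescence after pulsed UV
excitation. Because the free and protein-bound forms of NAD(P)H have distinct
fluorescence lifetimes, the shape of the decay carries metabolic information
that differs between liver parenchyma, benign tumors (BT), hepatocellular
carcinoma (HCC) and metastases (MTS). `trfliver` implements the complete
analysis chain for such measurements as a tested R package, for researchers
in biomedical optics who want to develop or benchmark lifetime-based tissue
classifiers without access to clinical spectra:

1. **Simulation** (`generate_study`, `synthesize_decay`): photon-counting
   (TCSPC) decay histograms for the four tissue classes, with per-spectrum
   decay parameters drawn from published group statistics
   (mean, standard error, group size; per-spectrum spread `sd = SE * sqrt(n)`),
   a Gaussian instrument response function (IRF), constant background, and
   independent Poisson counting noise per time bin.
2. **Decay fitting** (`fit_biexponential`): weighted nonlinear least squares
   of the bi-exponential model

   `I(t) = I_noise + I0 * [alpha1 * exp(-t/tau1) + alpha2 * exp(-t/tau2)]`,
   `alpha1 + alpha2 = 100%`,

   with IRF reconvolution, Neyman (photon-counting) weights
   `max(counts, 1)`, and the reduced chi-square (close to 1 for a good fit)
   plus weighted residuals as diagnostics. Per-spectrum features are the
   total fluorescence intensity `I_f`, the contributions `alpha1`/`alpha2`
   and the lifetimes `tau1`, `tau2`.
3. **Feature selection** (`select_features`): variance filter (sample
   variance < 1 excluded), pairwise Pearson correlation filter (|r| > 0.7;
   `alpha2` preferred over its complement `alpha1`), train-statistics
   standardization, and a PCA explained-variance audit.
4. **Classification** (`evaluate_comparison`): LDA baseline, random forest
   (100 trees), polynomial-kernel SVC and logistic regression under a
   repeated stratified 80/20 split protocol (10 reshuffles), reporting
   sensitivity, specificity, accuracy, F1 and ROC-AUC as mean +/- SD, for
   the binary tumor-vs-liver comparisons and the three-class tumor problem.
5. **Group statistics** (`group_stats`, `mann_whitney_u`): mean +/- SE per
   class with Mann-Whitney U significance stars.

## Worked example

Simulate one HCC spectrum at the published group parameters, fit it, and run
a small end-to-end study:

```r
library(trfliver)

acq <- acquisition_config()            # 12.5 ns window, 1024 bins, IRF FWHM 180 ps
irf <- make_gaussian_irf(acq)
spectrum <- synthesize_decay(
  data.frame(I_f = 1.8e6, alpha2 = 34.59, tau1 = 450, tau2 = 2585, label = "HCC"),
  acq, irf, rng_seed = 1)
spectrum
#> <decay_histogram> 1024 bins, 12500 ps window, 1,801,884 counts, label=HCC

fit <- fit_biexponential(spectrum, irf = irf)
fit
#> <decay_fit> tau1=449.1 ps, tau2=2578.7 ps, alpha2=34.64%, I_noise=0.91, chi2_red=1.015, converged (15 iter)
```

The fit recovers the generating lifetimes within a few picoseconds and the
reduced chi-square sits at 1, as expected for pure counting noise. A scaled-
down cohort study (40 spectra per class instead of the full 97/129) runs the
whole pipeline:

```r
cfg <- pipeline_config(comparison = "HCC_vs_liver", seed = 7,
                       n_override = c(liver = 40, HCC = 40),
                       protocol = split_protocol(n_repeats = 10),
                       models = c("lda", "rf"))
bundle <- run_pipeline(cfg)
bundle$selection
#> <selection_report>
#>   retained: I_f, alpha2, tau1, tau2
#>   dropped by variance: chi2_reduced
#>   dropped by correlation: alpha1 (kept alpha2, |r|=1.00)
#>   PCA explained fractions: 35.8%, 25.6%, 24.4%, 14.2%
bundle$evaluations$rf
#> <evaluation_report> HCC/liver, model=rf, 10 repeats
#>   HCC: Se 0.86 +/- 0.14, Sp 0.75 +/- 0.16, Acc 0.81 +/- 0.10, F1 0.82 +/- 0.09, AUC 0.87 +/- 0.10
#>   mean train accuracy 1.000; imbalance ratio 1.00
```

The selection stage keeps exactly the four diagnostic features (`I_f`,
`alpha2`, `tau1`, `tau2`), dropping `alpha1` as the redundant complement of
`alpha2`; metric rows read as mean +/- SD over the 10 reshuffles, with the
tumor class as the positive class.

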