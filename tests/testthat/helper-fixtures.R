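# Shared fixtures, built in code. Expensive cohorts are memoised so several
# test files can reuse one simulation without re-fitting.

.fixtures <- new.env(parent = emptyenv())

default_acq <- function() acquisition_config()

# Full-scale HCC-comparison cohort (97 liver + 129 HCC spectra) simulated at
# the published group parameters and fitted with IRF reconvolution.
fitted_hcc_cohort <- function() {
  if (is.null(.fixtures$hcc)) {
    study <- generate_study(study_cohort_spec("HCC_vs_liver", seed = 77001))
    fitted <- fit_decay_set(study$histograms, irf = study$irf)
    .fixtures$hcc <- list(study = study, features = fitted$features)
  }
  .fixtures$hcc
}

# Two-class Gaussian feature table with a controllable mean gap (in sd units)
# on every feature; labels drawn from the tissue classes.
make_gap_table <- function(n_per_class = 60, gap = 1, seed = 1,
                           labels = c("liver", "HCC")) {
  set.seed(seed)
  one <- function(lab, shift) {
    data.frame(label = lab,
               I_f = rnorm(n_per_class, 10 + shift, 1),
               alpha2 = rnorm(n_per_class, shift, 1),
               tau1 = rnorm(n_per_class, -shift, 1),
               tau2 = rnorm(n_per_class, 5 + shift, 1),
               stringsAsFactors = FALSE)
  }
  rbind(one(labels[1], 0), one(labels[2], gap))
}

# Noiseless synthetic decay for a given parameter set (shared acquisition).
noiseless_decay <- function(I_f = 1e6, alpha2 = 35, tau1 = 450, tau2 = 2600,
                            acq = default_acq(), irf = make_gaussian_irf(acq)) {
  synthesize_decay(data.frame(I_f = I_f, alpha2 = alpha2, tau1 = tau1,
                              tau2 = tau2, label = "liver"),
                   acq, irf, poisson = FALSE)
}
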