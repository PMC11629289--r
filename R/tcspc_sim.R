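# Synthetic TCSPC cohort generator: Gaussian IRF, truncated-Gaussian feature
# sampling parameterized by group mean / SE / n, bi-exponential decay synthesis
# with Poisson counting noise.

#' Acquisition configuration for simulated TCSPC histograms
#'
#' Defines the time base and instrument response of a simulated
#' time-correlated single-photon counting (TCSPC) measurement.
#'
#' @param window_length Histogram time span in picoseconds. Default 12500 ps
#'   comfortably resolves NAD(P)H lifetimes in the 400--2700 ps range.
#' @param n_bins Number of uniform time bins (>= 64). Default 1024
#'   (about 12.2 ps/bin).
#' @param irf_fwhm Full width at half maximum of the Gaussian instrument
#'   response function, ps. `0` gives a single-bin impulse.
#' @param irf_center Position of the IRF peak within the window, ps.
#' @param background_rate Expected constant background, counts per bin.
#' @param exposure_note Free-text acquisition metadata (not used numerically).
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(window_length = 12500, n_bins = 1024,
                               irf_fwhm = 180, irf_center = 1000,
                               background_rate = 2,
                               exposure_note = "1 s per spectrum") {
  if (window_length <= 0) stop_with("window_length must be positive")
  if (n_bins < 64) stop_with("n_bins must be at least 64")
  if (irf_fwhm < 0) stop_with("irf_fwhm must be non-negative")
  if (background_rate < 0) stop_with("background_rate must be non-negative")
  structure(list(window_length = window_length, n_bins = as.integer(n_bins),
                 irf_fwhm = irf_fwhm, irf_center = irf_center,
                 background_rate = background_rate,
                 exposure_note = exposure_note),
            class = "acquisition_config")
}

# Bin centers of the acquisition grid (ps).
acq_time_grid <- function(acq) {
  dt <- acq$window_length / acq$n_bins
  (seq_len(acq$n_bins) - 0.5) * dt
}

#' Decay histogram container
#'
#' @param time_ps Strictly increasing, uniformly spaced bin centers (ps).
#' @param counts Non-negative integer photon counts per bin.
#' @param irf_counts Optional IRF histogram on the same grid.
#' @param label Tissue class label (`""` if unlabeled).
#' @param patient_id,point_id Identifiers.
#' @return An object of class `decay_histogram`.
#' @export
decay_histogram <- function(time_ps, counts, irf_counts = NULL, label = "",
                            patient_id = "", point_id = "") {
  if (length(time_ps) != length(counts)) {
    stop_with("time_ps and counts must have equal length")
  }
  if (any(counts < 0)) stop_with("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop_with("counts must be integral-valued")
  }
  dts <- diff(time_ps)
  if (length(dts) && (any(dts <= 0) ||
                      max(dts) - min(dts) > 1e-6 * mean(dts))) {
    stop_with("time_ps must be strictly increasing with uniform spacing")
  }
  structure(list(time_ps = as.numeric(time_ps), counts = round(counts),
                 irf_counts = irf_counts, label = label,
                 patient_id = patient_id, point_id = point_id),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("<decay_histogram> %d bins, %.0f ps window, %s counts%s\n",
              length(x$counts), max(x$time_ps) + x$time_ps[1],
              format(sum(x$counts), big.mark = ","),
              if (nzchar(x$label)) paste0(", label=", x$label) else ""))
  invisible(x)
}

#' Gaussian instrument response function on an acquisition grid
#'
#' Integrates a Gaussian density over each time bin, so the histogram sums to
#' `area` up to the window truncation. `irf_fwhm = 0` yields a single-bin
#' impulse (delta limit), convenient for analytic tests.
#'
#' @param acq An [acquisition_config()].
#' @param center IRF peak position, ps; must lie inside the window.
#' @param area Total IRF counts (or 1 for a unit-area response).
#' @return A `decay_histogram` whose counts slot holds the (possibly
#'   non-integer) IRF intensities.
#' @export
make_gaussian_irf <- function(acq, center = acq$irf_center, area = 1) {
  if (center <= 0 || center >= acq$window_length) {
    stop_with("IRF center must lie strictly inside the window")
  }
  if (area <= 0) stop_with("IRF area must be positive")
  if (acq$irf_fwhm > acq$window_length) {
    stop_with("IRF FWHM exceeds the acquisition window")
  }
  dt <- acq$window_length / acq$n_bins
  edges <- seq(0, acq$window_length, by = dt)
  if (acq$irf_fwhm == 0) {
    y <- numeric(acq$n_bins)
    y[min(acq$n_bins, max(1L, findInterval(center, edges,
                                           rightmost.closed = TRUE)))] <- area
  } else {
    sigma <- acq$irf_fwhm / (2 * sqrt(2 * log(2)))
    y <- area * diff(stats::pnorm(edges, mean = center, sd = sigma))
  }
  h <- list(time_ps = acq_time_grid(acq), counts = y, irf_counts = NULL,
            label = "", patient_id = "", point_id = "")
  class(h) <- "decay_histogram"
  h
}

#' Per-class generative parameters
#'
#' Encodes one study arm: for each decay feature the group mean, the standard
#' error of that mean, and the group size from which the SE was computed. The
#' per-spectrum spread used for simulation is `sd = se * sqrt(n)`.
#'
#' @param class_label One of `"liver"`, `"BT"`, `"HCC"`, `"MTS"`.
#' @param mean,se Named numeric vectors with entries `I_f` (counts),
#'   `alpha2` (%), `tau1` (ps), `tau2` (ps).
#' @param n Named integer vector of group sizes per feature (a scalar is
#'   recycled).
#' @return An object of class `class_params`.
#' @export
class_params <- function(class_label, mean, se, n) {
  feats <- c("I_f", "alpha2", "tau1", "tau2")
  if (!class_label %in% .TISSUE_CLASSES) {
    stop_with("class_label must be one of %s",
              paste(.TISSUE_CLASSES, collapse = ", "))
  }
  if (!all(feats %in% names(mean)) || !all(feats %in% names(se))) {
    stop_with("mean and se must be named with %s",
              paste(feats, collapse = ", "))
  }
  if (length(n) == 1L) n <- stats::setNames(rep(n, 4), feats)
  if (any(n[feats] < 1)) stop_with("group sizes n must be positive")
  sd <- se[feats] * sqrt(n[feats])
  if (any(!is.finite(sd)) || any(sd < 0)) stop_with("derived sd must be finite")
  if (mean[["alpha2"]] <= 0 || mean[["alpha2"]] >= 100) {
    stop_with("alpha2 mean must lie in (0, 100)")
  }
  if (mean[["tau1"]] >= mean[["tau2"]]) stop_with("tau1 mean must be < tau2 mean")
  if (mean[["I_f"]] <= 0) stop_with("I_f mean must be positive")
  structure(list(class_label = class_label, mean = mean[feats],
                 se = se[feats], n = n[feats], sd = sd),
            class = "class_params")
}

#' Printed group parameters of the clinical liver study
#'
#' Returns the per-class generative parameters (group mean, SE, n) for one of
#' the study's pairwise comparisons, or for the three-tumor-type problem.
#' Means and SEs for fluorescence intensity `I_f`, long-component contribution
#' `alpha2` and long lifetime `tau2` are the published group statistics of the
#' clinical cohorts; the short lifetime `tau1` (reported only graphically) is
#' set to 450 +/- 10 ps SE for every class, and the intensity of the
#' benign-tumor comparison (reported as non-significant) to approximately
#' equal group means -- both are simulator assumptions, not measured values.
#'
#' @param comparison One of `"HCC_vs_liver"`, `"MTS_vs_liver"`,
#'   `"BT_vs_liver"`, `"tumors"` (BT/HCC/MTS three-class).
#' @return A list of [class_params()] objects.
#' @export
study_class_params <- function(comparison = c("HCC_vs_liver", "MTS_vs_liver",
                                              "BT_vs_liver", "tumors")) {
  comparison <- match.arg(comparison)
  cp <- function(lab, n, I_f, se_I, a2, se_a2, t2, se_t2) {
    class_params(lab,
                 mean = c(I_f = I_f, alpha2 = a2, tau1 = 450, tau2 = t2),
                 se   = c(I_f = se_I, alpha2 = se_a2, tau1 = 10, tau2 = se_t2),
                 n    = n)
  }
  hcc   <- cp("HCC", 129, 1.80e6, 0.01e6, 34.59, 0.29, 2585, 6)
  l_hcc <- cp("liver", 97, 0.91e6, 0.09e6, 36.65, 0.55, 2632, 10)
  mts   <- cp("MTS", 310, 1.42e6, 0.63e6, 33.63, 0.19, 2552, 4)
  l_mts <- cp("liver", 225, 1.01e6, 0.04e6, 32.91, 0.34, 2533, 7)
  bt    <- cp("BT", 120, 1.03e6, 0.05e6, 33.64, 0.29, 2569, 10)
  l_bt  <- cp("liver", 110, 1.00e6, 0.05e6, 35.26, 0.39, 2659, 10)
  switch(comparison,
         HCC_vs_liver = list(l_hcc, hcc),
         MTS_vs_liver = list(l_mts, mts),
         BT_vs_liver  = list(l_bt, bt),
         tumors       = list(bt, hcc, mts))
}

#' Cohort specification
#'
#' @param comparison_name Identifier, e.g. `"HCC_vs_liver"`.
#' @param classes List of [class_params()]; labels must be unique.
#' @param spectra_per_point Spectra recorded per measurement point.
#' @param seed Integer seed controlling the whole cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(comparison_name, classes, spectra_per_point = 10,
                        seed = 1) {
  labs <- vapply(classes, function(p) p$class_label, character(1))
  if (anyDuplicated(labs)) stop_with("class labels must be unique")
  if (spectra_per_point < 1) stop_with("spectra_per_point must be positive")
  structure(list(comparison_name = comparison_name, classes = classes,
                 spectra_per_point = as.integer(spectra_per_point),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Convenience constructor: cohort spec for a study comparison
#'
#' @inheritParams study_class_params
#' @param seed Integer seed.
#' @param spectra_per_point Spectra per measurement point.
#' @return A [cohort_spec()] with the published group sizes and parameters.
#' @export
study_cohort_spec <- function(comparison = "HCC_vs_liver", seed = 1,
                              spectra_per_point = 10) {
  cohort_spec(comparison, study_class_params(comparison),
              spectra_per_point = spectra_per_point, seed = seed)
}

# Truncated-Gaussian draw by resampling.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(1000)) {
    bad <- which(x <= lower | x >= upper)
    if (!length(bad)) return(x)
    x[bad] <- stats::rnorm(length(bad), mean, sd)
  }
  stop_with("truncated sampling failed to converge; check mean/sd vs support")
}

#' Sample per-spectrum decay features for one tissue class
#'
#' Draws `n` independent feature rows. Each feature is Gaussian with the
#' group mean and per-spectrum standard deviation `se * sqrt(n_group)`,
#' truncated to its physical support (`I_f > 0`, `0 < alpha2 < 100`,
#' lifetimes positive) by resampling violations. `alpha1` is the complement
#' `100 - alpha2`.
#'
#' @param params A [class_params()].
#' @param n Number of spectra to draw.
#' @param rng_seed Integer seed (`NULL` to use the current RNG stream).
#' @return A data.frame with columns `label, I_f, alpha1, alpha2, tau1, tau2`.
#' @export
sample_class_features <- function(params, n, rng_seed = NULL) {
  stopifnot(inherits(params, "class_params"))
  if (n < 1) stop_with("n must be at least 1")
  if (any(!is.finite(params$sd))) stop_with("non-finite sd")
  with_local_seed(rng_seed, {
    m <- params$mean; s <- params$sd
    I_f    <- rnorm_trunc(n, m[["I_f"]],    s[["I_f"]],    lower = 0)
    alpha2 <- rnorm_trunc(n, m[["alpha2"]], s[["alpha2"]], lower = 0, upper = 100)
    tau1   <- rnorm_trunc(n, m[["tau1"]],   s[["tau1"]],   lower = 0)
    tau2   <- rnorm_trunc(n, m[["tau2"]],   s[["tau2"]],   lower = 0)
    data.frame(label = params$class_label, I_f = I_f, alpha1 = 100 - alpha2,
               alpha2 = alpha2, tau1 = tau1, tau2 = tau2,
               stringsAsFactors = FALSE)
  })
}

# Causal discrete convolution of two equal-length sequences via FFT with
# zero padding; returns the first n samples.
convolve_causal <- function(a, b) {
  n <- length(a)
  stopifnot(length(b) == n)
  np <- 2^ceiling(log2(2 * n))
  fa <- stats::fft(c(a, numeric(np - n)))
  fb <- stats::fft(c(b, numeric(np - n)))
  out <- Re(stats::fft(fa * fb, inverse = TRUE))[seq_len(n)] / np
  pmax(out, 0)
}

# Noiseless expected counts for one feature vector on the acquisition grid:
# bi-exponential kernel convolved with the unit-area IRF, scaled so the
# signal integral equals I_f, plus constant background.
decay_model_expected <- function(I_f, alpha2, tau1, tau2, acq, irf,
                                 background = acq$background_rate) {
  dt <- acq$window_length / acq$n_bins
  s <- (seq_len(acq$n_bins) - 1) * dt
  a2 <- alpha2 / 100
  kern <- (1 - a2) * exp(-s / tau1) + a2 * exp(-s / tau2)
  irf_u <- irf$counts / sum(irf$counts)
  shape <- convolve_causal(irf_u, kern)
  tot <- sum(shape)
  if (tot <= 0) stop_with("degenerate decay model (zero integral)")
  I_f * shape / tot + background
}

#' Synthesize one TCSPC decay histogram
#'
#' Builds the noiseless expected histogram -- an ideal bi-exponential decay
#' with contributions `alpha1 = 100 - alpha2`, convolved with the unit-area
#' IRF and scaled so the expected signal counts equal `I_f`, plus the
#' constant expected background -- then draws independent Poisson counts per
#' bin (unless `poisson = FALSE`, which returns the rounded noiseless model).
#'
#' @param features One-row data.frame (or list) with `I_f`, `alpha2`, `tau1`,
#'   `tau2` and optionally `label`.
#' @param acq An [acquisition_config()].
#' @param irf IRF histogram from [make_gaussian_irf()] (any positive area;
#'   normalized internally).
#' @param rng_seed Integer seed for the Poisson draw.
#' @param poisson Draw Poisson counts (`TRUE`, default) or return the rounded
#'   noiseless model.
#' @return A [decay_histogram()]. Expected total counts are
#'   `I_f + n_bins * background_rate`.
#' @export
synthesize_decay <- function(features, acq, irf, rng_seed = NULL,
                             poisson = TRUE) {
  f <- as.list(features)
  if (f$tau1 >= f$tau2) stop_with("tau1 must be smaller than tau2")
  if (f$alpha2 <= 0 || f$alpha2 >= 100) stop_with("alpha2 must lie in (0, 100)")
  if (f$I_f <= 0) stop_with("I_f must be positive")
  mu <- decay_model_expected(f$I_f, f$alpha2, f$tau1, f$tau2, acq, irf)
  if (any(!is.finite(mu)) || any(mu < 0)) {
    stop_with("expected model overflow or negative value")
  }
  counts <- if (poisson) {
    with_local_seed(rng_seed, stats::rpois(length(mu), mu))
  } else {
    round(mu)
  }
  decay_histogram(acq_time_grid(acq), counts, label = f$label %||% "",
                  patient_id = f$patient_id %||% "",
                  point_id = f$point_id %||% "")
}

#' Generate a full labeled synthetic cohort
#'
#' Draws per-spectrum features for every class of the cohort spec, groups
#' spectra into measurement points of `spectra_per_point` (two points per
#' synthetic patient), and synthesizes one Poisson decay histogram per
#' spectrum. Fully reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param acq An [acquisition_config()].
#' @param n_override Optional named integer vector overriding the per-class
#'   spectra counts (defaults to each class's printed `n` for `I_f`).
#' @return A list with elements `histograms` (list of [decay_histogram()]),
#'   `truth` (data.frame of generating features with identifiers), `irf`,
#'   `acq` and `spec`.
#' @export
generate_study <- function(spec, acq = acquisition_config(),
                           n_override = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  irf <- make_gaussian_irf(acq)
  histograms <- list()
  truth <- list()
  for (ci in seq_along(spec$classes)) {
    params <- spec$classes[[ci]]
    lab <- params$class_label
    n <- if (!is.null(n_override) && lab %in% names(n_override)) {
      n_override[[lab]]
    } else {
      params$n[["I_f"]]
    }
    feats <- sample_class_features(params, n,
                                   rng_seed = derive_seed(spec$seed, ci))
    point <- (seq_len(n) - 1) %/% spec$spectra_per_point + 1
    patient <- (point - 1) %/% 2 + 1
    feats$spectrum_id <- sprintf("%s_%04d", lab, seq_len(n))
    feats$point_id <- sprintf("%s_pt%03d", lab, point)
    feats$patient_id <- sprintf("%s_p%02d", lab, patient)
    hs <- vector("list", n)
    for (i in seq_len(n)) {
      hs[[i]] <- synthesize_decay(feats[i, ], acq, irf,
                                  rng_seed = derive_seed(spec$seed,
                                                         ci * 1000000 + i))
    }
    names(hs) <- feats$spectrum_id
    histograms <- c(histograms, hs)
    truth[[ci]] <- feats
  }
  truth <- do.call(rbind, truth)
  cols <- c("spectrum_id", "patient_id", "point_id", "label",
            "I_f", "alpha1", "alpha2", "tau1", "tau2")
  truth <- truth[, cols]
  rownames(truth) <- NULL
  list(histograms = histograms, truth = truth, irf = irf, acq = acq,
       spec = spec)
}
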