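test_that("Gaussian IRF integrates the density over bins", {
  acq <- acquisition_config(irf_fwhm = 100)
  irf <- make_gaussian_irf(acq, center = 1000, area = 1e5)
  expect_equal(sum(irf$counts), 1e5, tolerance = 1e-3)
  expect_true(all(irf$counts >= 0))
  # independent oracle: per-bin quadrature of the Gaussian density
  sigma <- 100 / (2 * sqrt(2 * log(2)))
  dt <- acq$window_length / acq$n_bins
  idx <- which(irf$counts > 1e-6 * max(irf$counts))
  for (i in idx[seq(1, length(idx), by = 5)]) {
    lo <- (i - 1) * dt
    q <- stats::integrate(function(x) stats::dnorm(x, 1000, sigma),
                          lo, lo + dt)$value
    expect_equal(irf$counts[i], 1e5 * q, tolerance = 1e-6)
  }
  # peak in the bin containing the center; one-sigma bin holds ~exp(-1/2)
  # of the peak density
  peak <- which.max(irf$counts)
  expect_equal(irf$time_ps[peak], 1000, tolerance = dt)
  bin_sigma <- which.min(abs(irf$time_ps - (1000 + sigma)))
  q_sigma <- stats::integrate(function(x) stats::dnorm(x, 1000, sigma),
                              (bin_sigma - 1) * dt, bin_sigma * dt)$value
  q_peak <- stats::integrate(function(x) stats::dnorm(x, 1000, sigma),
                             (peak - 1) * dt, peak * dt)$value
  expect_equal(irf$counts[bin_sigma] / irf$counts[peak], q_sigma / q_peak,
               tolerance = 1e-6)
  expect_equal(q_sigma / q_peak, exp(-0.5), tolerance = 0.05)
})

test_that("zero-width IRF is a single-bin impulse and wide IRFs are rejected", {
  acq <- acquisition_config(irf_fwhm = 0)
  irf <- make_gaussian_irf(acq, center = 1000, area = 500)
  expect_equal(sum(irf$counts > 0), 1)
  expect_equal(sum(irf$counts), 500)
  expect_equal(which(irf$counts > 0), 82) # bin containing 1000 ps
  expect_error(make_gaussian_irf(acquisition_config(irf_fwhm = 2e4)),
               "FWHM")
  expect_error(make_gaussian_irf(acq, center = -5), "center")
})

test_that("feature sampler honours mean, SE-derived sd and support truncation", {
  p <- class_params("liver",
                    mean = c(I_f = 0.91e6, alpha2 = 36.65, tau1 = 450,
                             tau2 = 2632),
                    se = c(I_f = 0.09e6, alpha2 = 0.55, tau1 = 10, tau2 = 10),
                    n = 97)
  expect_equal(unname(p$sd[["tau2"]]), 10 * sqrt(97), tolerance = 1e-12)
  x <- sample_class_features(p, 1e5, rng_seed = 42)
  sd_t2 <- 10 * sqrt(97)
  expect_lt(abs(mean(x$tau2) - 2632), 3 * sd_t2 / sqrt(1e5))
  expect_equal(sd(x$tau2), sd_t2, tolerance = 0.02)
  expect_true(all(x$I_f > 0))
  expect_true(all(x$alpha2 > 0 & x$alpha2 < 100))
  expect_equal(x$alpha1 + x$alpha2, rep(100, nrow(x)))

  # degenerate SE: all rows equal the mean exactly
  p0 <- class_params("BT",
                     mean = c(I_f = 1e6, alpha2 = 33, tau1 = 450, tau2 = 2569),
                     se = c(I_f = 0, alpha2 = 0, tau1 = 0, tau2 = 0), n = 120)
  x0 <- sample_class_features(p0, 8, rng_seed = 1)
  expect_true(all(x0$tau2 == 2569) && all(x0$alpha2 == 33))

  # truncation near the upper alpha2 bound keeps draws inside (0, 100)
  pt <- class_params("HCC",
                     mean = c(I_f = 1e6, alpha2 = 99.9, tau1 = 450,
                              tau2 = 2585),
                     se = c(I_f = 1, alpha2 = 5, tau1 = 1, tau2 = 1), n = 1)
  xt <- sample_class_features(pt, 2000, rng_seed = 7)
  expect_true(all(xt$alpha2 > 0 & xt$alpha2 < 100))
})

test_that("noiseless decay matches its contract and mono-exponential tail is log-linear", {
  acq <- acquisition_config(background_rate = 2)
  irf <- make_gaussian_irf(acq)
  h <- noiseless_decay(I_f = 1e6, acq = acq, irf = irf)
  expect_lt(abs(sum(h$counts) - (1e6 + acq$n_bins * 2)), 100) # rounding only
  # nearly pure long component with a delta IRF: log tail slope = -1/tau2
  acq0 <- acquisition_config(irf_fwhm = 0, background_rate = 0)
  irf0 <- make_gaussian_irf(acq0)
  h0 <- synthesize_decay(data.frame(I_f = 1e7, alpha2 = 99.99, tau1 = 450,
                                    tau2 = 2600, label = ""),
                         acq0, irf0, poisson = FALSE)
  tail_idx <- which(h0$time_ps > 3000 & h0$time_ps < 9000 & h0$counts > 0)
  slope <- coef(lm(log(h0$counts[tail_idx]) ~ h0$time_ps[tail_idx]))[[2]]
  expect_equal(-1 / slope, 2600, tolerance = 0.01)
  expect_error(synthesize_decay(data.frame(I_f = 1e6, alpha2 = 35,
                                           tau1 = 2600, tau2 = 450),
                                acq, irf), "tau1")
})

test_that("Poisson stage has the right mean and Fano factor near one", {
  acq <- acquisition_config(n_bins = 128, background_rate = 0)
  irf <- make_gaussian_irf(acq)
  f <- data.frame(I_f = 1e6, alpha2 = 35, tau1 = 450, tau2 = 2600, label = "")
  totals <- vapply(1:200, function(i) {
    sum(synthesize_decay(f, acq, irf, rng_seed = 3000 + i)$counts)
  }, numeric(1))
  expect_lt(abs(mean(totals) - 1e6), 4 * sqrt(1e6 / 200))

  # per-bin variance ~ per-bin mean across replicates (Fano factor ~ 1)
  f2 <- data.frame(I_f = 2e4, alpha2 = 35, tau1 = 450, tau2 = 2600, label = "")
  reps <- sapply(1:500, function(i) {
    synthesize_decay(f2, acq, irf, rng_seed = 9000 + i)$counts
  })
  mu <- rowMeans(reps)
  keep <- mu > 5
  fano <- apply(reps[keep, ], 1, var) / mu[keep]
  expect_lt(abs(mean(fano) - 1), 4 * sqrt(2 / 499) / sqrt(sum(keep)))
})

test_that("generate_study reproduces the published group sizes deterministically", {
  spec <- study_cohort_spec("HCC_vs_liver", seed = 11)
  acq <- acquisition_config(n_bins = 64) # coarse grid keeps this test light
  st <- generate_study(spec, acq = acq)
  expect_length(st$histograms, 226)
  expect_equal(as.vector(table(st$truth$label)[c("HCC", "liver")]),
               c(129, 97))
  st2 <- generate_study(spec, acq = acq)
  expect_identical(st$truth, st2$truth)
  expect_identical(lapply(st$histograms, `[[`, "counts"),
                   lapply(st2$histograms, `[[`, "counts"))

  # 120 spectra at 10 per point -> 12 points
  spec_bt <- study_cohort_spec("BT_vs_liver", seed = 5)
  st_bt <- generate_study(spec_bt, acq = acq, n_override = c(liver = 20))
  bt <- st_bt$truth[st_bt$truth$label == "BT", ]
  expect_equal(length(unique(bt$point_id)), 12)
  expect_equal(sum(st_bt$truth$label == "liver"), 20)
})
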