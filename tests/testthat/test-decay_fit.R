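test_that("initial guess recovers lifetimes from log-linear tails", {
  # noiseless mono-exponential tail, no background: tau2 guess within 10%
  t <- (1:1024 - 0.5) * 12500 / 1024
  counts <- round(2e4 * exp(-t / 2500))
  h <- decay_histogram(t, counts)
  g <- initial_guess(h)
  expect_equal(g$tau2, 2500, tolerance = 0.1)
  expect_identical(g$I_noise, 0) # all-zero pre-rise region

  # flat histogram (pure background): fallback defaults with a warning
  hf <- decay_histogram(t, rep(5, length(t)))
  expect_warning(gf <- initial_guess(hf), "fall")
  expect_equal(c(gf$tau1, gf$tau2, gf$alpha2), c(500, 2500, 35))
  expect_error(initial_guess(decay_histogram(t, rep(0, length(t)))), "zero")
})

test_that("noiseless bi-exponential decays are recovered across the parameter grid", {
  acq <- acquisition_config()
  irf <- make_gaussian_irf(acq)
  for (tau1 in c(300, 500, 700)) {
    for (tau2 in c(2300, 2550, 2800)) {
      for (alpha2 in c(25, 45)) {
        h <- noiseless_decay(I_f = 1e7, alpha2 = alpha2, tau1 = tau1,
                             tau2 = tau2, acq = acq, irf = irf)
        fit <- fit_biexponential(h, irf = irf)
        expect_true(fit$converged)
        expect_true(fit$params$tau1 < fit$params$tau2)
        expect_equal(fit$params$tau1, tau1, tolerance = 1e-3)
        expect_equal(fit$params$tau2, tau2, tolerance = 1e-3)
        expect_equal(fit$params$alpha2, alpha2, tolerance = 1e-3)
      }
    }
  }
  # delta-IRF variant of the round trip
  acq0 <- acquisition_config(irf_fwhm = 0)
  irf0 <- make_gaussian_irf(acq0)
  h0 <- noiseless_decay(alpha2 = 35, tau1 = 450, tau2 = 2600, acq = acq0,
                        irf = irf0)
  fit0 <- fit_biexponential(h0, irf = irf0)
  expect_equal(fit0$params$tau2, 2600, tolerance = 1e-3)
  expect_equal(fit0$params$alpha2, 35, tolerance = 1e-3)
})

test_that("tail fit without an IRF recovers the decay past the peak", {
  acq0 <- acquisition_config(irf_fwhm = 0, background_rate = 2)
  irf0 <- make_gaussian_irf(acq0)
  h <- synthesize_decay(data.frame(I_f = 1e6, alpha2 = 35, tau1 = 450,
                                   tau2 = 2600, label = ""),
                        acq0, irf0, rng_seed = 12)
  fit <- fit_biexponential(h, irf = NULL)
  expect_true(fit$converged)
  expect_equal(fit$fit_range[1], which.max(h$counts))
  expect_equal(fit$params$tau2, 2600, tolerance = 0.02)
  expect_equal(fit$params$alpha2, 35, tolerance = 0.1)
})

test_that("reduced chi-square follows its definition and calibration", {
  expect_equal(reduced_chi_square(c(5, 9, 2, 7), c(5, 9, 2, 7), n_params = 1),
               0)
  # one bin off by k on an otherwise exact fit
  counts <- c(100, 50, 25, 12, 6, 3)
  model <- counts; model[2] <- 50 + 4
  expect_equal(reduced_chi_square(counts, model, n_params = 2),
               16 / (50 * (6 - 2)))
  expect_error(reduced_chi_square(1:5, 1:4, 1), "length")
  expect_error(reduced_chi_square(1:5, 1:5, 5), "n_params")
  # Poisson-sampled counts from a smooth model: value ~ 1 +/- 2 sqrt(2/N)
  set.seed(101)
  model <- 2000 * exp(-(1:20000) / 6000) + 10
  counts <- rpois(length(model), model)
  v <- reduced_chi_square(counts, model, n_params = 5)
  expect_lt(abs(v - 1), 2 * sqrt(2 / length(model)))
})

test_that("fits of Poisson data are calibrated and scale-equivariant", {
  acq <- acquisition_config()
  irf <- make_gaussian_irf(acq)
  f <- data.frame(I_f = 1e6, alpha2 = 35, tau1 = 450, tau2 = 2600, label = "")
  out <- t(vapply(1:40, function(i) {
    h <- synthesize_decay(f, acq, irf, rng_seed = 500 + i)
    ft <- fit_biexponential(h, irf = irf)
    c(ft$chi2_reduced, ft$params$tau2, ft$params$tau1 < ft$params$tau2)
  }, numeric(3)))
  expect_gt(mean(out[, 1]), 0.9)
  expect_lt(mean(out[, 1]), 1.1)
  expect_true(all(out[, 3] == 1))
  expect_lt(abs(mean(out[, 2]) - 2600), 3 * sd(out[, 2]) / sqrt(40) + 1)

  # multiplying the counts by 10 leaves lifetimes and contributions unchanged
  h1 <- noiseless_decay(I_f = 1e5, acq = acq, irf = irf)
  h10 <- decay_histogram(h1$time_ps, h1$counts * 10)
  f1 <- fit_biexponential(h1, irf = irf)
  f10 <- fit_biexponential(h10, irf = irf)
  expect_equal(f10$params$tau2, f1$params$tau2, tolerance = 1e-3)
  expect_equal(f10$params$alpha2, f1$params$alpha2, tolerance = 1e-2)
  expect_gt(f10$params$I0 / f1$params$I0, 5)
})

test_that("feature extraction is background-corrected arithmetic", {
  t <- (1:1024 - 0.5) * 12500 / 1024
  h <- decay_histogram(t, rep(0, 1024), label = "HCC", patient_id = "p1",
                       point_id = "pt1")
  h$counts <- rep(0, 1024); h$counts[1] <- 0
  fake_fit <- structure(list(
    params = list(I0 = 1, I_noise = 2, alpha1 = 65.41, alpha2 = 34.59,
                  tau1 = 450, tau2 = 2585),
    chi2_reduced = 1, converged = TRUE), class = "decay_fit")
  h2 <- h; h2$counts <- rep(0, 1024)
  # sum(counts) = 1e6 spread over bins, I_noise * n_bins = 2048
  h2$counts <- c(rep(976, 1024))  # 976 * 1024 = 999424; adjust first bin
  h2$counts[1] <- 976 + (1e6 - 999424)
  ft <- extract_features(fake_fit, h2)
  expect_equal(ft$I_f, 1e6 - 2048)
  expect_equal(ft$alpha1, 100 - 34.59)
  expect_identical(ft$label, "HCC")
  fake_fit$converged <- FALSE
  expect_error(extract_features(fake_fit, h2), "converge")
  ft2 <- extract_features(fake_fit, h2, allow_unconverged = TRUE)
  expect_false(ft2$converged)

  # round trip: background-free noiseless decay returns the generator I_f
  acq0 <- acquisition_config(background_rate = 0)
  irf <- make_gaussian_irf(acq0)
  h3 <- noiseless_decay(I_f = 5e5, acq = acq0, irf = irf)
  fit3 <- fit_biexponential(h3, irf = irf)
  ft3 <- extract_features(fit3, h3)
  expect_equal(ft3$I_f, 5e5, tolerance = 1e-2)
})
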