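test_that("default profiles satisfy the spectral geometry the methods assume", {
  profiles <- default_profiles()
  g <- default_grid()
  # theophylline: 271 nm reading within 1% of its maximum
  thp <- profile_absorbance(profiles$thp, g)
  expect_gte(profile_absorbance(profiles$thp, 271), 0.99 * max(thp))
  # transparency constraints at the univariate measurement wavelengths
  expect_lt(profile_absorbance(profiles$hyx, 271), 1e-6)
  expect_lt(profile_absorbance(profiles$eph, 271), 1e-6)
  expect_lt(profile_absorbance(profiles$eph, 234.2), 1e-6)
  # strong three-way overlap in the multivariate window
  for (nm in c("hyx", "eph", "thp")) {
    prof <- profiles[[nm]]
    expect_gt(profile_absorbance(prof, 220),
              0.1 * max(profile_absorbance(prof, g)))
  }
})

test_that("the hydroxyzine ratio-derivative crosses zero at the ephedrine wavelength", {
  profiles <- default_profiles()
  g <- default_grid()
  p <- derivative_params()
  div <- spectrum(g, 22 * profile_absorbance(profiles$thp, g))
  d3_h <- nth_derivative(divide_spectra(
    spectrum(g, profile_absorbance(profiles$hyx, g)), div), p)
  d3_e <- nth_derivative(divide_spectra(
    spectrum(g, profile_absorbance(profiles$eph, g)), div), p)
  wl <- find_null_wavelength(d3_h, d3_e, c(219, 225))
  expect_lt(abs(wl - 222), 0.2 + 1e-9)
  # the interferent amplitude at the crossing is negligible against the
  # analyte amplitude
  expect_lt(abs(amplitude_at(d3_h, 222)), 1e-9 * abs(amplitude_at(d3_e, 222)))
})

test_that("mixture simulation is additive, nonnegative-checked and seeded", {
  profiles <- default_profiles()
  cfg0 <- sim_config(noise_sd = 0)
  zero <- simulate_mixture(c(0, 0, 0), profiles, cfg0)
  expect_true(all(zero$absorbance == 0))

  a <- simulate_mixture(c(2, 3, 4), profiles, cfg0)
  b <- simulate_mixture(c(1, 5, 2), profiles, cfg0)
  ab <- simulate_mixture(c(3, 8, 6), profiles, cfg0)
  expect_equal(a$absorbance + b$absorbance, ab$absorbance, tolerance = 1e-12)

  s1 <- simulate_mixture(c(2, 3, 4), profiles, sim_config(seed = 99))
  s2 <- simulate_mixture(c(2, 3, 4), profiles, sim_config(seed = 99))
  expect_identical(s1$absorbance, s2$absorbance)

  expect_error(simulate_mixture(c(-1, 2, 3), profiles, cfg0), ">= 0")
})

test_that("pure divisor-component spectra produce a flat plateau ratio", {
  profiles <- default_profiles()
  g <- default_grid()
  div <- spectrum(g, 22 * profile_absorbance(profiles$thp, g))
  pure <- simulate_mixture(c(hyx = 0, eph = 0, thp = 9), profiles,
                           sim_config(noise_sd = 0))
  ratio <- divide_spectra(pure, div)
  sel <- ratio$wavelength >= 265 & ratio$wavelength <= 280
  vals <- ratio$absorbance[sel]
  expect_lt(sd(vals) / mean(vals), 1e-9)
  expect_equal(mean(vals), 9 / 22, tolerance = 1e-12)
})

test_that("simulated data sets track their design and seeds", {
  d <- generate_design()
  profiles <- default_profiles()
  ds <- simulate_dataset(d, profiles, sim_config(noise_sd = 0.002, seed = 4))
  expect_equal(nrow(ds$spectra$matrix), 25L)
  expect_equal(ds$concentrations, d$runs[, c("hyx", "eph", "thp")])

  ds2 <- simulate_dataset(d, profiles, sim_config(noise_sd = 0.002, seed = 5))
  expect_false(identical(ds$spectra$matrix, ds2$spectra$matrix))
  # different seeds agree in expectation: mean absorbance per sample within
  # 3 * noise_sd / sqrt(n_wavelengths)
  tol <- 3 * 0.002 / sqrt(ncol(ds$spectra$matrix))
  expect_true(all(abs(rowMeans(ds$spectra$matrix) -
                      rowMeans(ds2$spectra$matrix)) < tol))
})

test_that("noiseless design data give exact multivariate prediction", {
  ds <- noiseless_window_dataset()
  vr <- reference_mixtures("multivariate")
  vd <- simulate_dataset(vr, default_profiles(), sim_config(noise_sd = 0),
                         window = c(210, 230))
  for (analyte in c("hyx", "eph", "thp")) {
    fit <- fit_pls1(ds$spectra, ds$concentrations[[analyte]], 3)
    rmsep <- evaluate_predictions(vr[[analyte]], predict(fit, vd$spectra))$rmsep
    expect_lt(rmsep, 1e-6)
  }
})

test_that("the ratio-derivative method is exact on all reference compositions", {
  profiles <- default_profiles()
  cal <- calibrate_method_a(profiles)
  mixes <- reference_mixtures("ratio")
  for (i in seq_len(nrow(mixes))) {
    truth <- c(hyx = mixes$hyx[i], eph = mixes$eph[i], thp = mixes$thp[i])
    mix <- simulate_mixture(truth, profiles, sim_config(noise_sd = 0))
    res <- quantify_with(mix, cal, true_concs = truth)
    expect_true(all(abs(res$recovery - 100) < 0.1),
                label = sprintf("mixture %d recovery", i))
  }
})
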