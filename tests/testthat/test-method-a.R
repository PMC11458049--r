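test_that("build_calibration fits exact and near-exact lines", {
  cal <- build_calibration(c(1, 2, 3), c(2, 4, 6), 271, "zero-order absorbance")
  expect_equal(cal$slope, 2)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r, 1)

  # noiseless Beer-Lambert theophylline series: perfectly linear through 0
  profiles <- default_profiles()
  concs <- seq(2, 24, by = 2)
  resp <- vapply(concs, function(cc) {
    amplitude_at(simulate_mixture(c(0, 0, cc), profiles, sim_config(noise_sd = 0)), 271)
  }, numeric(1))
  cal2 <- build_calibration(concs, resp, 271, "zero-order absorbance")
  expect_gte(cal2$r, 0.9999)
  expect_lt(abs(cal2$intercept), 1e-10)

  expect_error(build_calibration(c(1, 2), c(1, 2), 271), "3 points")
  expect_error(build_calibration(c(2, 2, 2), c(1, 2, 3), 271), "degenerate")
  expect_error(build_calibration(c(1, 2, 3), c(5, 5, 5), 271), "constant responses")
})

test_that("invert_calibration reproduces the published regression algebra", {
  cal_thp <- structure(list(slope = 0.0467, intercept = 0.0061, r = 0.9998,
                            wavelength = 271, kind = "zero-order absorbance",
                            conc_range = c(2, 24)), class = "linear_calibration")
  expect_equal(invert_calibration(cal_thp, 0.4731), 10, tolerance = 1e-9)
  expect_equal(suppressWarnings(invert_calibration(cal_thp, cal_thp$intercept)),
               0, tolerance = 1e-12)

  cal_hyx <- structure(list(slope = 0.0958, intercept = -0.0534, r = 0.9997,
                            wavelength = 234.2, kind = "ratio amplitude",
                            conc_range = c(2, 20)), class = "linear_calibration")
  expect_equal(invert_calibration(cal_hyx, 0.9046), 10, tolerance = 1e-9)

  expect_warning(invert_calibration(cal_thp, 2), "outside")
  cal0 <- cal_thp; cal0$slope <- 0
  expect_error(invert_calibration(cal0, 0.5), "zero slope")
})

test_that("noiseless ternary mixtures are resolved essentially exactly", {
  profiles <- default_profiles()
  cal <- calibrate_method_a(profiles)
  truth <- c(hyx = 10, eph = 15, thp = 10)
  mix <- simulate_mixture(truth, profiles, sim_config(noise_sd = 0))
  res <- quantify_with(mix, cal, true_concs = truth)
  expect_true(all(abs(res$recovery - 100) < 0.5))

  # a pure-theophylline sample: the other two estimates vanish
  only_thp <- simulate_mixture(c(hyx = 0, eph = 0, thp = 12), profiles,
                               sim_config(noise_sd = 0))
  res2 <- quantify_ternary(only_thp, cal$divisor, cal$cal_thp, cal$cal_hyx,
                           cal$cal_eph, true_concs = NULL)
  expect_lt(abs(res2$conc[["hyx"]]), 1e-6)
  expect_lt(abs(res2$conc[["eph"]]), 1e-6)
  expect_equal(res2$conc[["thp"]], 12, tolerance = 1e-6)
})

test_that("mean recoveries stay in [98, 103]% under instrument-level noise", {
  profiles <- default_profiles()
  cal <- calibrate_method_a(profiles)
  mixes <- reference_mixtures("ratio")
  set.seed(42)
  cfg <- sim_config(noise_sd = 0.002)
  rec <- matrix(NA_real_, 100, 3)
  for (s in 1:100) {
    i <- ((s - 1) %% nrow(mixes)) + 1
    truth <- c(hyx = mixes$hyx[i], eph = mixes$eph[i], thp = mixes$thp[i])
    mix <- ternspec:::simulate_mixture_unseeded(truth, profiles, cfg)
    rec[s, ] <- quantify_with(mix, cal, true_concs = truth)$recovery
  }
  means <- colMeans(rec)
  expect_true(all(means >= 98 & means <= 103))
})

test_that("scaling factor cancels out of inverted concentrations", {
  profiles <- default_profiles()
  gamma <- 7.5
  cal1 <- calibrate_method_a(profiles, p = derivative_params(scaling_factor = 100))
  cal2 <- calibrate_method_a(profiles, p = derivative_params(scaling_factor = 100 * gamma))
  expect_equal(cal2$cal_eph$slope / cal1$cal_eph$slope, gamma, tolerance = 1e-9)
  truth <- c(hyx = 5, eph = 10, thp = 15)
  mix <- simulate_mixture(truth, profiles, sim_config(noise_sd = 0))
  r1 <- quantify_with(mix, cal1)$conc
  r2 <- quantify_with(mix, cal2)$conc
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("changing the divisor concentration rescales slopes, not recoveries", {
  profiles <- default_profiles()
  cal22 <- calibrate_method_a(profiles, divisor_conc = 22)
  cal10 <- calibrate_method_a(profiles, divisor_conc = 10)
  expect_equal(cal10$cal_hyx$slope / cal22$cal_hyx$slope, 22 / 10,
               tolerance = 1e-9)
  truth <- c(hyx = 8, eph = 12, thp = 10)
  mix <- simulate_mixture(truth, profiles, sim_config(noise_sd = 0))
  r22 <- quantify_with(mix, cal22, true_concs = truth)$recovery
  r10 <- quantify_with(mix, cal10, true_concs = truth)$recovery
  expect_true(all(abs(r22 - 100) < 0.1))
  expect_true(all(abs(r10 - 100) < 0.1))
})

test_that("find_null_wavelength locates zero crossings and rejects degenerate input", {
  g <- seq(210, 230, 0.2)
  # interferent crossing zero at 222.0, analyte peaked nearby
  interf <- spectrum(g, g - 222)
  analyte <- spectrum(g, exp(-(g - 221)^2 / 8))
  wl <- find_null_wavelength(interf, analyte, c(215, 228))
  expect_lt(abs(wl - 222), 0.2 + 1e-9)

  zero <- spectrum(g, rep(0, length(g)))
  expect_equal(find_null_wavelength(zero, analyte, c(215, 228)), 221)
  expect_error(find_null_wavelength(interf, zero, c(215, 228)), "selection error")
})

test_that("quantification aborts when a measurement wavelength is masked", {
  profiles <- default_profiles()
  cal <- calibrate_method_a(profiles)
  mix <- simulate_mixture(c(hyx = 5, eph = 5, thp = 5), profiles,
                          sim_config(noise_sd = 0))
  # an absurd division floor masks the whole ratio spectrum
  expect_error(
    quantify_ternary(mix, cal$divisor, cal$cal_thp, cal$cal_hyx, cal$cal_eph,
                     floor = 100),
    "masked")
})

test_that("calibration lines serialize and restore losslessly", {
  cal <- build_calibration(c(2, 4, 6, 8), c(0.1, 0.21, 0.29, 0.41), 271,
                           "zero-order absorbance")
  p <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, p)
  cal2 <- read_calibration(p)
  expect_equal(cal2, cal)
})
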