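test_that("the multilevel design has balanced levels and matches the canonical table", {
  d <- generate_design()
  expect_equal(nrow(d$runs), 25L)
  expect_equal(unname(table(d$runs$hyx)), rep(5L, 5), ignore_attr = TRUE)
  expect_equal(unname(table(d$runs$eph)), rep(5L, 5), ignore_attr = TRUE)
  expect_equal(unname(table(d$runs$thp)), rep(5L, 5), ignore_attr = TRUE)
  expect_equal(sort(unique(d$runs$hyx)), c(2, 4, 6, 8, 10))
  expect_equal(sort(unique(d$runs$eph)), c(3, 6, 9, 12, 15))
  expect_equal(sort(unique(d$runs$thp)), c(2, 6, 10, 14, 18))
  # run-for-run agreement with the canonical training table
  expect_equal(unname(as.matrix(d$runs)), unname(as.matrix(canonical_training_runs())))
  # coded factors are nearly orthogonal
  cc <- cor(as.matrix(d$coded))
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.35))

  expect_error(generate_design(list(a = 1:5, b = 1:5)), "3 factors")
  expect_error(generate_design(list(hyx = c(1, 2, 4, 8, 16),
                                    eph = seq(3, 15, 3), thp = seq(2, 18, 4))),
               "equally spaced")
})

test_that("PLS-1 and PCR recover noiseless three-component data exactly", {
  ds <- noiseless_window_dataset()
  for (analyte in c("hyx", "eph", "thp")) {
    y <- ds$concentrations[[analyte]]
    m_pls <- fit_pls1(ds$spectra, y, 3)
    m_pcr <- fit_pcr(ds$spectra, y, 3)
    expect_lt(sqrt(mean((predict(m_pls, ds$spectra) - y)^2)), 1e-8)
    expect_lt(sqrt(mean((predict(m_pcr, ds$spectra) - y)^2)), 1e-8)
    # the two methods agree when k equals the number of generating components
    expect_lt(max(abs(predict(m_pls, ds$spectra) - predict(m_pcr, ds$spectra))), 1e-6)
  }
})

test_that("rank-1 PLS equals univariate regression on the single score", {
  set.seed(11)
  n <- 12; m <- 40
  u <- runif(n); v <- runif(m)
  X <- outer(u, v)
  y <- 3 * u + rnorm(n, 0, 0.05)
  fit <- fit_pls1(X, y, 1)
  # oracle: OLS of y on the centred score t = Xc w
  Xc <- sweep(X, 2, colMeans(X))
  w <- drop(crossprod(Xc, y - mean(y))); w <- w / sqrt(sum(w^2))
  t_ <- drop(Xc %*% w)
  oracle <- mean(y) + t_ * sum((y - mean(y)) * t_) / sum(t_^2)
  expect_equal(unname(predict(fit, X)), unname(oracle), tolerance = 1e-8)
})

test_that("full-rank PCR equals ordinary least squares via the pseudo-inverse", {
  set.seed(21)
  n <- 10; m <- 6
  X <- matrix(rnorm(n * m), n, m)
  y <- rnorm(n)
  fit <- fit_pcr(X, y, m)
  Xc <- sweep(X, 2, colMeans(X))
  b_ols <- MASS::ginv(Xc) %*% (y - mean(y))
  oracle <- drop(Xc %*% b_ols) + mean(y)
  expect_equal(unname(predict(fit, X)), unname(oracle), tolerance = 1e-8)
})

test_that("degenerate multivariate fits are refused", {
  ds <- noiseless_window_dataset()
  expect_error(fit_pls1(ds$spectra, rep(5, 25), 2), "zero-variance y")
  expect_error(fit_pcr(ds$spectra, rep(5, 25), 2), "zero-variance y")
  expect_error(fit_pcr(ds$spectra, ds$concentrations$hyx, 24), "rank")
  # k = 0 PCR predicts the training mean everywhere
  m0 <- fit_pcr(ds$spectra, ds$concentrations$hyx, 0)
  expect_equal(unname(predict(m0, ds$spectra)),
               rep(mean(ds$concentrations$hyx), 25))
})

test_that("score-path and regression-vector predictions coincide", {
  set.seed(5)
  ds <- simulate_dataset(canonical_training_runs(), default_profiles(),
                         sim_config(noise_sd = 0.002, seed = 5),
                         window = c(210, 230))
  y <- ds$concentrations$eph
  for (k in c(1, 3, 5)) {
    for (fitter in list(fit_pls1, fit_pcr)) {
      fit <- fitter(ds$spectra, y, k)
      expect_lt(max(abs(predict(fit, ds$spectra) -
                        ternspec:::predict_via_scores(fit, ds$spectra))), 1e-8)
    }
  }
})

test_that("predictions are invariant to a constant offset spectrum", {
  ds <- simulate_dataset(canonical_training_runs(), default_profiles(),
                         sim_config(noise_sd = 0.002, seed = 9),
                         window = c(210, 230))
  y <- ds$concentrations$thp
  shifted <- ds$spectra
  shifted$matrix <- shifted$matrix + 0.25
  for (fitter in list(fit_pls1, fit_pcr)) {
    f0 <- fitter(ds$spectra, y, 4)
    f1 <- fitter(shifted, y, 4)
    expect_lt(max(abs(predict(f0, ds$spectra) - predict(f1, shifted))), 1e-8)
  }
})

test_that("leave-one-out RMSECV matches its closed forms and detects rank", {
  ds <- noiseless_window_dataset()
  y <- ds$concentrations$hyx
  cv <- loo_rmsecv(ds$spectra, y, "pls1", kmax = 4)
  # k = 0 equals the brute-force leave-one-out SD of y
  oracle0 <- sqrt(mean(vapply(seq_along(y), function(i) {
    (y[i] - mean(y[-i]))^2
  }, numeric(1))))
  expect_equal(unname(cv$rmsecv[["k0"]]), oracle0, tolerance = 1e-12)
  expect_lt(cv$rmsecv[["k3"]], 1e-6)
  expect_gt(cv$rmsecv[["k1"]], 0.5)
  # same behaviour for PCR
  cv2 <- loo_rmsecv(ds$spectra, y, "pcr", kmax = 3)
  expect_lt(cv2$rmsecv[["k3"]], 1e-6)

  expect_warning(loo_rmsecv(ds$spectra$matrix[1:5, ], y[1:5], "pcr", kmax = 10),
                 "truncated")
  X3 <- ds$spectra$matrix[c(1, 1, 1), ]
  expect_warning(loo_rmsecv(X3, rep(4, 3), "pcr", kmax = 1), "degenerate")
})

test_that("component selection rules behave as specified", {
  ds <- noiseless_window_dataset()
  cv <- loo_rmsecv(ds$spectra, ds$concentrations$eph, "pls1", kmax = 4)
  expect_equal(select_components(cv, "fixed", k_fixed = 5), 5L)
  fake <- cv
  fake$rmsecv <- c(k0 = 5, k1 = 4, k2 = 3, k3 = 2, k4 = 1)
  fake$errors <- matrix(rep(c(5, 4, 3, 2, 1), each = 25) / 5, 25, 5)
  expect_equal(select_components(fake, "min"), 4L)
  flat <- cv
  flat$rmsecv <- c(k0 = 1, k1 = 1, k2 = 1, k3 = 1, k4 = 1)
  flat$errors <- matrix(1, 25, 5)
  expect_equal(select_components(flat, "one-se"), 1L)
})

test_that("prediction reports compute RMSEP, recoveries and the fitted line", {
  r <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$rmsep, 0)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r, 1)

  r2 <- evaluate_predictions(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r2$rmsep, 1)
  expect_equal(r2$slope, 1, tolerance = 1e-12)
  expect_equal(r2$intercept, 1, tolerance = 1e-12)

  expect_error(evaluate_predictions(1:3, 1:4), "length mismatch")

  # noiseless model predictions on a randomized validation set: unit slope
  ds <- noiseless_window_dataset()
  fit <- fit_pls1(ds$spectra, ds$concentrations$hyx, 3)
  vr <- reference_mixtures("multivariate")
  vd <- simulate_dataset(vr, default_profiles(), sim_config(noise_sd = 0),
                         window = c(210, 230))
  rep3 <- evaluate_predictions(vr$hyx, predict(fit, vd$spectra))
  expect_lt(abs(rep3$slope - 1), 1e-6)
})

test_that("multivariate models serialize to JSON and restore losslessly", {
  ds <- simulate_dataset(canonical_training_runs(), default_profiles(),
                         sim_config(noise_sd = 0.002, seed = 3),
                         window = c(210, 230))
  y <- ds$concentrations$hyx
  for (fitter in list(fit_pls1, fit_pcr)) {
    fit <- fitter(ds$spectra, y, 4)
    p <- withr::local_tempfile(fileext = ".json")
    write_mv_model(fit, p)
    fit2 <- read_mv_model(p)
    expect_equal(predict(fit2, ds$spectra), predict(fit, ds$spectra),
                 tolerance = 1e-10)
    expect_equal(ternspec:::predict_via_scores(fit2, ds$spectra),
                 ternspec:::predict_via_scores(fit, ds$spectra),
                 tolerance = 1e-10)
  }
})
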