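# small stable polynomial string hash (mod 2^32) so artifacts can embed a
# fingerprint of the configuration that produced them
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' End-to-end synthetic demonstration of both resolution methods
#'
#' Simulates the complete study on synthetic data: calibrates and applies
#' the ratio-subtraction/third-derivative method to the seven reference
#' validation mixtures, then builds the 25-run multilevel design, fits
#' mean-centred PLS-1 and PCR models per analyte, selects the component
#' count by leave-one-out cross-validation, and evaluates predictions on
#' the multivariate validation mixtures.
#'
#' @param seed integer seed controlling every random draw.
#' @param noise_sd absorbance noise level in AU (default 0.002).
#' @param k component count for the multivariate models (default 5, the
#'   package's fixed-rule default).
#' @param out_dir optional directory; when given, calibrations, models and
#'   the JSON report (embedding a hash of the run configuration) are
#'   written there.
#' @return A list of class `ternspec_demo`: `method_a` (recovery table and
#'   per-analyte [summary_stats()]), `method_b` (per-analyte, per-method
#'   [evaluate_predictions()] reports and selected components), `config`.
#' @examples
#' \donttest{
#' rep <- run_demo(seed = 1)
#' rep$method_a$summary$hyx
#' }
#' @export
run_demo <- function(seed = 0, noise_sd = 0.002, k = 5L, out_dir = NULL) {
  config <- list(seed = seed, noise_sd = noise_sd, k = k,
                 grid = c(200, 400, 0.2), window = c(210, 230),
                 divisor_conc = 22,
                 derivative = list(order = 3, delta_lambda = 4, scaling_factor = 100))
  profiles <- default_profiles()
  p <- derivative_params()

  # --- Method A: ratio-subtraction + third derivative -----------------
  cal_a <- calibrate_method_a(profiles, p = p)
  mixes <- reference_mixtures("ratio")
  set.seed(seed)
  cfg_noise <- sim_config(noise_sd = noise_sd)
  rec_a <- t(vapply(seq_len(nrow(mixes)), function(i) {
    truth <- c(hyx = mixes$hyx[i], eph = mixes$eph[i], thp = mixes$thp[i])
    mix <- simulate_mixture_unseeded(truth, profiles, cfg_noise)
    quantify_with(mix, cal_a, true_concs = truth)$recovery
  }, numeric(3L)))
  colnames(rec_a) <- c("hyx", "eph", "thp")
  method_a <- list(
    recovery = as.data.frame(rec_a),
    summary = lapply(as.data.frame(rec_a), summary_stats),
    calibration = cal_a
  )

  # --- Method B: multivariate calibration -----------------------------
  design <- generate_design()
  train <- simulate_dataset(design, profiles,
                            sim_config(noise_sd = noise_sd, seed = seed + 1L),
                            window = c(210, 230))
  valid_runs <- reference_mixtures("multivariate")
  valid <- simulate_dataset(valid_runs, profiles,
                            sim_config(noise_sd = noise_sd, seed = seed + 2L),
                            window = c(210, 230))
  method_b <- list()
  for (analyte in c("hyx", "eph", "thp")) {
    y <- train$concentrations[[analyte]]
    cv <- loo_rmsecv(train$spectra, y, method = "pls1", kmax = 8L)
    k_sel <- select_components(cv, rule = "fixed", k_fixed = k)
    fits <- list(pls1 = fit_pls1(train$spectra, y, k_sel),
                 pcr = fit_pcr(train$spectra, y, k_sel))
    method_b[[analyte]] <- list(
      selected_k = k_sel,
      rmsecv = cv$rmsecv,
      pls1 = evaluate_predictions(valid_runs[[analyte]],
                                  predict(fits$pls1, valid$spectra)),
      pcr = evaluate_predictions(valid_runs[[analyte]],
                                 predict(fits$pcr, valid$spectra)),
      models = fits
    )
  }

  out <- structure(list(method_a = method_a, method_b = method_b,
                        config = config, config_hash = config_hash(config)),
                   class = "ternspec_demo")
  if (!is.null(out_dir)) write_demo_artifacts(out, out_dir)
  out
}

write_demo_artifacts <- function(demo, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("cal_thp", "cal_hyx", "cal_eph")) {
    write_calibration(demo$method_a$calibration[[nm]],
                      file.path(out_dir, paste0(nm, ".json")))
  }
  for (analyte in names(demo$method_b)) {
    write_mv_model(demo$method_b[[analyte]]$models$pls1,
                   file.path(out_dir, sprintf("pls1_%s.json", analyte)))
    write_mv_model(demo$method_b[[analyte]]$models$pcr,
                   file.path(out_dir, sprintf("pcr_%s.json", analyte)))
  }
  report <- list(
    config = demo$config,
    config_hash = demo$config_hash,
    method_a = list(
      recovery = demo$method_a$recovery,
      mean_recovery = lapply(demo$method_a$summary, function(s)
        list(mean = s$mean, sd = s$sd, rsd_percent = s$rsd_percent))
    ),
    method_b = lapply(demo$method_b, function(mb) list(
      selected_k = mb$selected_k,
      rmsecv = as.list(mb$rmsecv),
      pls1 = list(rmsep = mb$pls1$rmsep, slope = mb$pls1$slope,
                  intercept = mb$pls1$intercept, r = mb$pls1$r,
                  mean_recovery = mean(mb$pls1$recovery)),
      pcr = list(rmsep = mb$pcr$rmsep, slope = mb$pcr$slope,
                 intercept = mb$pcr$intercept, r = mb$pcr$r,
                 mean_recovery = mean(mb$pcr$recovery))
    ))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.ternspec_demo <- function(x, ...) {
  cat("== ratio-subtraction / third-derivative method ==\n")
  for (a in c("hyx", "eph", "thp")) {
    s <- x$method_a$summary[[a]]
    cat(sprintf("  %s mean recovery %6.2f%% +/- %.3f (%%RSD %.3f)\n",
                toupper(a), s$mean, s$sd, s$rsd_percent))
  }
  cat("== multivariate calibration (PLS-1 / PCR) ==\n")
  for (a in c("hyx", "eph", "thp")) {
    mb <- x$method_b[[a]]
    cat(sprintf("  %s (k = %d): PLS-1 RMSEP %.4f, PCR RMSEP %.4f, mean recovery %.2f%% / %.2f%%\n",
                toupper(a), mb$selected_k, mb$pls1$rmsep, mb$pcr$rmsep,
                mean(mb$pls1$recovery), mean(mb$pcr$recovery)))
  }
  cat(sprintf("config hash: %s\n", x$config_hash))
  invisible(x)
}
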