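#' Build the three Method-A calibration lines from standard series
#'
#' Runs the full ratio-derivative measurement pipeline on single-component
#' standard solutions and fits the three univariate calibration lines:
#' theophylline zero-order absorbance at 271 nm, hydroxyzine
#' ratio-subtraction amplitude at 234.2 nm, and ephedrine third-derivative
#' ratio amplitude at 222 nm. The standards are simulated from the supplied
#' band models (noise per `cfg`), exactly as a bench calibration would be
#' measured; the divisor standard itself is always noiseless.
#'
#' Default concentration series cover the linear ranges 2-24 (THP), 2-20
#' (HYX) and 3-35 (EPH) ug/mL.
#'
#' @param profiles list of three [band_model()]s ([default_profiles()]).
#' @param divisor_conc divisor concentration in ug/mL (default 22).
#' @param p [derivative_params()] shared by calibration and prediction.
#' @param concs named list with numeric vectors `thp`, `hyx`, `eph`.
#' @param cfg [sim_config()] used to generate the standard spectra.
#' @param wavelengths,plateau_window,floor as in [quantify_ternary()].
#' @return A list of class `method_a_calibration`: `cal_thp`, `cal_hyx`,
#'   `cal_eph` ([build_calibration()] objects), `divisor`
#'   ([divisor_spec()]), `params`, `wavelengths`, `plateau_window`, `floor`.
#' @export
calibrate_method_a <- function(profiles = default_profiles(),
                               divisor_conc = 22,
                               p = derivative_params(),
                               concs = list(thp = seq(2, 24, by = 2),
                                            hyx = seq(2, 20, by = 2),
                                            eph = seq(3, 35, by = 4)),
                               cfg = sim_config(noise_sd = 0),
                               wavelengths = c(thp = 271, hyx = 234.2, eph = 222),
                               plateau_window = c(269, 273),
                               floor = 0.01) {
  div_spectrum <- spectrum(
    cfg$grid, divisor_conc * profile_absorbance(profiles$thp, cfg$grid),
    label = sprintf("THP %g ug/mL divisor", divisor_conc),
    meta = list(analyte = "THP", concentration = divisor_conc))
  divisor <- divisor_spec(div_spectrum, divisor_conc)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  one_component <- function(analyte, conc) {
    v <- c(hyx = 0, eph = 0, thp = 0); v[analyte] <- conc
    simulate_mixture_unseeded(v, profiles, cfg)
  }

  resp_thp <- vapply(concs$thp, function(cc) {
    amplitude_at(one_component("thp", cc), wavelengths[["thp"]])
  }, numeric(1L))

  resp_hyx <- vapply(concs$hyx, function(cc) {
    rat <- divide_spectra(one_component("hyx", cc), div_spectrum, floor = floor)
    sub <- subtract_constant(rat, plateau_constant(rat, plateau_window))
    amplitude_at(sub, wavelengths[["hyx"]])
  }, numeric(1L))

  resp_eph <- vapply(concs$eph, function(cc) {
    rat <- divide_spectra(one_component("eph", cc), div_spectrum, floor = floor)
    sub <- subtract_constant(rat, plateau_constant(rat, plateau_window))
    amplitude_at(nth_derivative(sub, p), wavelengths[["eph"]])
  }, numeric(1L))

  structure(list(
    cal_thp = build_calibration(concs$thp, resp_thp, wavelengths[["thp"]],
                                "zero-order absorbance"),
    cal_hyx = build_calibration(concs$hyx, resp_hyx, wavelengths[["hyx"]],
                                "ratio amplitude"),
    cal_eph = build_calibration(concs$eph, resp_eph, wavelengths[["eph"]],
                                "derivative amplitude"),
    divisor = divisor, params = p, wavelengths = wavelengths,
    plateau_window = plateau_window, floor = floor),
    class = "method_a_calibration")
}

#' @export
print.method_a_calibration <- function(x, ...) {
  cat("<method_a_calibration>\n")
  print(x$cal_thp); print(x$cal_hyx); print(x$cal_eph)
  invisible(x)
}

#' Quantify a mixture with a bundled Method-A calibration
#'
#' Convenience wrapper dispatching [quantify_ternary()] with the divisor,
#' derivative parameters and wavelengths stored in a
#' [calibrate_method_a()] result.
#'
#' @param mix mixture [spectrum()].
#' @param calibration a `method_a_calibration`.
#' @param true_concs optional named true concentrations for recovery
#'   reporting.
#' @return A `ternary_result`; see [quantify_ternary()].
#' @export
quantify_with <- function(mix, calibration, true_concs = NULL) {
  stopifnot(inherits(calibration, "method_a_calibration"))
  quantify_ternary(mix, calibration$divisor,
                   calibration$cal_thp, calibration$cal_hyx, calibration$cal_eph,
                   p = calibration$params,
                   wavelengths = calibration$wavelengths,
                   plateau_window = calibration$plateau_window,
                   floor = calibration$floor,
                   true_concs = true_concs)
}
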