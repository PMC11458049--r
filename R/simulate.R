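#' Gaussian band model of a pure-component spectrum
#'
#' A pure component's specific absorbance curve is modelled as a sum of
#' Gaussian bands; multiplying by concentration (ug/mL) and path length
#' (1 cm) gives its Beer-Lambert absorbance contribution.
#'
#' @param centers band centres in nm.
#' @param sigmas band widths (Gaussian sigma, nm), all > 0.
#' @param peaks peak specific absorbances (AU mL / (ug cm)), all >= 0.
#' @param label component label.
#' @return An object of class `band_model`.
#' @export
band_model <- function(centers, sigmas, peaks, label = "") {
  centers <- as.numeric(centers); sigmas <- as.numeric(sigmas); peaks <- as.numeric(peaks)
  if (length(centers) != length(sigmas) || length(centers) != length(peaks)) {
    stop("centers, sigmas, peaks must have equal length", call. = FALSE)
  }
  if (any(sigmas <= 0)) stop("sigmas must be > 0", call. = FALSE)
  if (any(peaks < 0)) stop("peaks must be >= 0", call. = FALSE)
  structure(list(centers = centers, sigmas = sigmas, peaks = peaks,
                 label = as.character(label)[1L]),
            class = "band_model")
}

#' @export
print.band_model <- function(x, ...) {
  cat(sprintf("<band_model> %s: %d band(s)\n", x$label, length(x$centers)))
  print(data.frame(center_nm = x$centers, sigma_nm = x$sigmas,
                   peak = signif(x$peaks, 4)))
  invisible(x)
}

#' Evaluate a band model on a wavelength grid
#'
#' @param model a [band_model()].
#' @param wavelengths numeric vector of wavelengths (nm).
#' @return Specific absorbance (AU mL / (ug cm)) at each wavelength.
#' @export
profile_absorbance <- function(model, wavelengths) {
  stopifnot(inherits(model, "band_model"))
  out <- numeric(length(wavelengths))
  for (j in seq_along(model$centers)) {
    out <- out + model$peaks[j] *
      exp(-(wavelengths - model$centers[j])^2 / (2 * model$sigmas[j]^2))
  }
  out
}

#' Default acquisition grid
#'
#' 200-400 nm sampled every 0.2 nm, the grid on which all default spectra
#' are generated and measured.
#'
#' @param from,to,by grid bounds and step in nm.
#' @return Numeric wavelength vector.
#' @export
default_grid <- function(from = 200, to = 400, by = 0.2) {
  seq(from, to, by = by)
}

#' Simulation configuration
#'
#' @param grid wavelength grid (nm).
#' @param noise_sd standard deviation of additive Gaussian absorbance noise
#'   (AU); the default 0.002 AU reflects routine double-beam UV
#'   photometric repeatability.
#' @param baseline constant baseline offset (AU).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param noise_model `"additive"` (homoscedastic, default) or `"shot"`
#'   (heteroscedastic: point sd `noise_sd * (1 + 2 A)`, growing with
#'   absorbance as photon-limited noise does).
#' @param excipient optional [band_model()] added once per spectrum (AU) to
#'   emulate a smooth formulation-excipient background; default none.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid = default_grid(), noise_sd = 0.002, baseline = 0,
                       seed = NULL, noise_model = c("additive", "shot"),
                       excipient = NULL) {
  noise_model <- match.arg(noise_model)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(excipient)) stopifnot(inherits(excipient, "band_model"))
  structure(list(grid = as.numeric(grid), noise_sd = noise_sd,
                 baseline = baseline, seed = seed,
                 noise_model = noise_model, excipient = excipient),
            class = "sim_config")
}

# cache for tuned default profiles, keyed by grid signature
.profile_cache <- new.env(parent = emptyenv())

#' Default pure-component band models
#'
#' Returns band models for the three components with the spectral geometry
#' the resolution methods rely on:
#' \itemize{
#'   \item theophylline (THP): maximum at 271 nm where the other two
#'     components are transparent (< 1e-6 AU per ug/mL), plus a broad
#'     underlying band so it absorbs throughout the 210-230 nm window;
#'   \item hydroxyzine (HYX): main band at 234 nm, transparent at 271 nm,
#'     plus an overlap band near 222 nm whose centre is tuned numerically
#'     (at build time, for the given grid) so that the third derivative of
#'     the HYX/THP ratio spectrum crosses zero at exactly 222.0 nm — the
#'     ephedrine measurement wavelength;
#'   \item ephedrine (EPH): absorbs only below ~232 nm (transparent at
#'     234.2 and 271 nm).
#' }
#' All three overlap strongly in 210-230 nm, which is why zero-order
#' readings other than the 271 nm theophylline band are useless and the
#' ratio/derivative or multivariate machinery is needed. The tuned
#' geometry is verified at build time with [find_null_wavelength()].
#'
#' @param grid wavelength grid on which the zero-crossing is tuned.
#' @param p [derivative_params()] defining the derivative transform for
#'   which the crossing is tuned.
#' @return Named list of [band_model()]s: `hyx`, `eph`, `thp`.
#' @export
default_profiles <- function(grid = default_grid(), p = derivative_params()) {
  key <- paste0(
    sprintf("%.9g|%.9g|%.9g|", grid[1L], grid[length(grid)], grid[2L] - grid[1L]),
    p$order, "|", p$delta_lambda, "|", p$scheme)
  if (!is.null(.profile_cache[[key]])) return(.profile_cache[[key]])

  thp <- band_model(c(271, 215), c(9, 25), c(0.0467, 0.030), label = "THP")
  eph <- band_model(c(213, 218), c(4, 3), c(0.060, 0.040), label = "EPH")
  hyx_of <- function(center2) {
    band_model(c(234, center2), c(6, 5), c(0.090, 0.050), label = "HYX")
  }

  divisor <- spectrum(grid, 22 * profile_absorbance(thp, grid), label = "divisor")
  d3_at_222 <- function(center2) {
    rat <- divide_spectra(spectrum(grid, profile_absorbance(hyx_of(center2), grid)),
                          divisor)
    amplitude_at(nth_derivative(rat, p), 222)
  }
  root <- stats::uniroot(d3_at_222, c(219, 224), tol = 1e-12)
  hyx <- hyx_of(root$root)

  # build-time verification of the nulling geometry
  rat_h <- divide_spectra(spectrum(grid, profile_absorbance(hyx, grid)), divisor)
  rat_e <- divide_spectra(spectrum(grid, profile_absorbance(eph, grid)), divisor)
  null_wl <- find_null_wavelength(nth_derivative(rat_h, p),
                                  nth_derivative(rat_e, p),
                                  window = c(219, 225))
  step <- grid[2L] - grid[1L]
  stopifnot(
    abs(null_wl - 222) <= step + 1e-9,
    profile_absorbance(hyx, 271) < 1e-6,
    profile_absorbance(eph, 271) < 1e-6,
    profile_absorbance(eph, 234.2) < 1e-6
  )
  out <- list(hyx = hyx, eph = eph, thp = thp)
  .profile_cache[[key]] <- out
  out
}

#' Simulate a ternary mixture spectrum
#'
#' Beer-Lambert additive mixture of the three component profiles, plus the
#' configured baseline, optional excipient background and Gaussian noise.
#'
#' @param concs concentrations in ug/mL: named vector with elements `hyx`,
#'   `eph`, `thp`, or an unnamed length-3 vector in that order. All >= 0.
#' @param profiles list of three [band_model()]s as from
#'   [default_profiles()].
#' @param cfg a [sim_config()]. When `cfg$seed` is non-`NULL` the RNG is
#'   seeded before drawing noise, so equal seeds give identical spectra.
#' @return A [spectrum()] with `meta$concs` recording the true composition.
#' @export
simulate_mixture <- function(concs, profiles = default_profiles(),
                             cfg = sim_config()) {
  concs <- resolve_concs(concs)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  simulate_mixture_unseeded(concs, profiles, cfg)
}

resolve_concs <- function(concs) {
  if (is.null(names(concs))) {
    if (length(concs) != 3L) stop("concs must have 3 elements (hyx, eph, thp)", call. = FALSE)
    names(concs) <- c("hyx", "eph", "thp")
  }
  concs <- concs[c("hyx", "eph", "thp")]
  if (anyNA(concs) || any(concs < 0)) {
    stop("concentrations must be named hyx/eph/thp and >= 0", call. = FALSE)
  }
  concs
}

simulate_mixture_unseeded <- function(concs, profiles, cfg) {
  g <- cfg$grid
  ab <- concs[["hyx"]] * profile_absorbance(profiles$hyx, g) +
        concs[["eph"]] * profile_absorbance(profiles$eph, g) +
        concs[["thp"]] * profile_absorbance(profiles$thp, g) +
        cfg$baseline
  if (!is.null(cfg$excipient)) ab <- ab + profile_absorbance(cfg$excipient, g)
  if (cfg$noise_sd > 0) {
    sd_vec <- if (cfg$noise_model == "shot") cfg$noise_sd * (1 + 2 * pmax(ab, 0))
              else cfg$noise_sd
    ab <- ab + stats::rnorm(length(g), 0, sd_vec)
  }
  spectrum(g, ab,
           label = sprintf("mix H%.3g E%.3g T%.3g",
                           concs[["hyx"]], concs[["eph"]], concs[["thp"]]),
           meta = list(concs = concs, path_length_cm = 1))
}

#' Simulate a full calibration data set
#'
#' One mixture spectrum per design run, optionally restricted to a working
#' window, with the concentration table attached.
#'
#' @param design a [generate_design()] result, or a data.frame/matrix with
#'   columns `hyx`, `eph`, `thp` (ug/mL).
#' @param profiles list of three [band_model()]s.
#' @param cfg a [sim_config()]; its seed (if any) is applied once before
#'   the first spectrum, making the whole set reproducible.
#' @param window optional length-2 wavelength window (nm) to which the
#'   returned set is restricted, e.g. `c(210, 230)` for the multivariate
#'   methods.
#' @return A list: `spectra` (a [spectra_set()]), `concentrations`
#'   (data.frame with columns `hyx`, `eph`, `thp`).
#' @export
simulate_dataset <- function(design, profiles = default_profiles(),
                             cfg = sim_config(), window = NULL) {
  runs <- if (inherits(design, "calibration_design")) design$runs
          else as.data.frame(design)
  if (!all(c("hyx", "eph", "thp") %in% names(runs))) {
    stop("design must provide hyx, eph, thp columns", call. = FALSE)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  mat <- t(vapply(seq_len(nrow(runs)), function(i) {
    simulate_mixture_unseeded(
      c(hyx = runs$hyx[i], eph = runs$eph[i], thp = runs$thp[i]),
      profiles, cfg)$absorbance
  }, numeric(length(cfg$grid))))
  ss <- spectra_set(cfg$grid, mat, paste0("mix", seq_len(nrow(runs))))
  if (!is.null(window)) ss <- window_spectra_set(ss, window)
  list(spectra = ss, concentrations = runs[, c("hyx", "eph", "thp")])
}
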