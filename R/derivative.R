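#' Derivative transform parameters
#'
#' Governs the derivative step of the ratio-derivative method. The default
#' settings (third derivative, lag \eqn{\Delta\lambda = 4} nm, scaling factor
#' 100) match the conditions under which the method's 222 nm measurement
#' wavelength was selected.
#'
#' Two schemes are available. `"lag-difference"` emulates instrument-style
#' derivative software: one pass maps
#' \eqn{A(\lambda) \to [A(\lambda + \Delta\lambda/2) - A(\lambda -
#' \Delta\lambda/2)] / \Delta\lambda} on the interior of the grid, and is
#' applied `order` times, shrinking the grid by `order * delta_lambda` nm in
#' total; this central half-lag form is exact for polynomials up to the
#' cubic term. `"savitzky-golay"` applies the standard smoothing-derivative
#' convolution of the given window and polynomial order (grid length
#' preserved; edge values are unreliable and should not be read).
#'
#' @param order derivative order, a positive integer (default 3).
#' @param delta_lambda lag in nm; `delta_lambda / 2` must be an integer
#'   multiple of the grid step at transform time.
#' @param scaling_factor dimensionless multiplier applied after
#'   differentiation; cancels in calibration inversion.
#' @param scheme `"lag-difference"` or `"savitzky-golay"`.
#' @param sg_window,sg_polyorder Savitzky-Golay filter length (odd) and
#'   polynomial order; only used by that scheme.
#' @return An object of class `derivative_params`.
#' @export
derivative_params <- function(order = 3L, delta_lambda = 4, scaling_factor = 100,
                              scheme = c("lag-difference", "savitzky-golay"),
                              sg_window = 15L, sg_polyorder = 4L) {
  scheme <- match.arg(scheme)
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1", call. = FALSE)
  if (!is.numeric(delta_lambda) || delta_lambda <= 0) {
    stop("delta_lambda must be > 0", call. = FALSE)
  }
  if (!is.numeric(scaling_factor) || scaling_factor <= 0) {
    stop("scaling_factor must be > 0", call. = FALSE)
  }
  if (scheme == "savitzky-golay") {
    sg_window <- as.integer(sg_window); sg_polyorder <- as.integer(sg_polyorder)
    if (sg_window %% 2L == 0L) stop("sg_window must be odd", call. = FALSE)
    if (sg_polyorder < order) stop("sg_polyorder must be >= order", call. = FALSE)
    if (sg_window <= sg_polyorder) stop("sg_window must exceed sg_polyorder", call. = FALSE)
  }
  structure(list(order = order, delta_lambda = delta_lambda,
                 scaling_factor = scaling_factor, scheme = scheme,
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder)),
            class = "derivative_params")
}

#' n-th derivative of a spectrum
#'
#' Applies the derivative transform described in [derivative_params()].
#' Masked (`NA`) points propagate: any derivative value whose support
#' touches a masked point is itself masked.
#'
#' @param s a [spectrum()] on a uniform grid.
#' @param p a [derivative_params()] object.
#' @return A [spectrum()] holding `scaling_factor` times the `order`-th
#'   derivative. For the lag-difference scheme the grid shrinks by
#'   `order * delta_lambda` nm in total.
#' @export
nth_derivative <- function(s, p = derivative_params()) {
  stopifnot(inherits(s, "spectrum"), inherits(p, "derivative_params"))
  step <- grid_step(s)
  if (is.na(step)) stop("nth_derivative requires a uniform grid", call. = FALSE)
  if (p$delta_lambda < step - 1e-9) {
    stop("delta_lambda must be at least the grid step", call. = FALSE)
  }
  if (p$scheme == "lag-difference") {
    hs <- p$delta_lambda / (2 * step)
    if (abs(hs - round(hs)) > 1e-6) {
      stop(sprintf(
        "delta_lambda/2 = %g nm is not an integer multiple of the grid step %g nm",
        p$delta_lambda / 2, step), call. = FALSE)
    }
    hs <- as.integer(round(hs))
    y <- s$absorbance
    wl <- s$wavelength
    for (pass in seq_len(p$order)) {
      n <- length(y)
      if (n <= 2L * hs) {
        stop("size error: spectrum shorter than the derivative support", call. = FALSE)
      }
      y <- (y[(2L * hs + 1L):n] - y[1L:(n - 2L * hs)]) / p$delta_lambda
      wl <- wl[(hs + 1L):(n - hs)]
    }
    out <- spectrum(wl, y * p$scaling_factor, label = s$label, meta = s$meta)
  } else {
    if (length(s$absorbance) < p$sg_window) {
      stop("size error: spectrum shorter than the Savitzky-Golay window", call. = FALSE)
    }
    if (anyNA(s$absorbance)) {
      stop("savitzky-golay scheme does not support masked points", call. = FALSE)
    }
    y <- signal::sgolayfilt(s$absorbance, p = p$sg_polyorder, n = p$sg_window,
                            m = p$order, ts = step)
    out <- spectrum(s$wavelength, y * p$scaling_factor,
                    label = s$label, meta = s$meta)
  }
  out
}

#' Build a univariate calibration line
#'
#' Ordinary least-squares fit of response on concentration, with the Pearson
#' correlation coefficient r reported as the linearity diagnostic.
#'
#' @param concs concentrations in ug/mL (>= 3 distinct values).
#' @param responses instrument responses (absorbance or derivative/ratio
#'   amplitude), same length.
#' @param wavelength measurement wavelength in nm.
#' @param kind one of `"zero-order absorbance"`, `"ratio amplitude"`,
#'   `"derivative amplitude"`.
#' @param conc_range concentration validity range; defaults to
#'   `range(concs)`.
#' @return An object of class `linear_calibration` with fields `slope`,
#'   `intercept`, `r`, `wavelength`, `kind`, `conc_range`.
#' @export
build_calibration <- function(concs, responses, wavelength,
                              kind = c("zero-order absorbance",
                                       "ratio amplitude",
                                       "derivative amplitude"),
                              conc_range = range(concs)) {
  kind <- match.arg(kind)
  concs <- as.numeric(concs); responses <- as.numeric(responses)
  if (length(concs) != length(responses)) stop("length mismatch", call. = FALSE)
  if (length(concs) < 3L) stop("fit error: need at least 3 points", call. = FALSE)
  if (stats::sd(concs) == 0) stop("fit error: degenerate design (constant concentrations)", call. = FALSE)
  if (anyNA(responses)) stop("fit error: missing responses", call. = FALSE)
  if (stats::sd(responses) == 0) {
    stop("fit error: constant responses, correlation undefined", call. = FALSE)
  }
  ft <- stats::lm.fit(cbind(1, concs), responses)
  structure(list(slope = unname(ft$coefficients[2L]),
                 intercept = unname(ft$coefficients[1L]),
                 r = stats::cor(concs, responses),
                 wavelength = wavelength, kind = kind,
                 conc_range = as.numeric(conc_range)),
            class = "linear_calibration")
}

#' @export
print.linear_calibration <- function(x, ...) {
  cat(sprintf("<linear_calibration> %s at %.4g nm\n", x$kind, x$wavelength))
  cat(sprintf("  response = %.6g * C %+.6g   r = %.5f   range %g-%g ug/mL\n",
              x$slope, x$intercept, x$r, x$conc_range[1L], x$conc_range[2L]))
  invisible(x)
}

#' Invert a calibration line
#'
#' @param cal a [build_calibration()] result.
#' @param response measured response.
#' @return Concentration in ug/mL: `(response - intercept) / slope`. A
#'   warning is raised (not an error, and the value is not clipped) when the
#'   result falls outside `cal$conc_range`.
#' @export
invert_calibration <- function(cal, response) {
  stopifnot(inherits(cal, "linear_calibration"))
  if (cal$slope == 0) stop("inversion error: zero slope", call. = FALSE)
  conc <- (response - cal$intercept) / cal$slope
  if (any(conc < cal$conc_range[1L] - 1e-9 | conc > cal$conc_range[2L] + 1e-9)) {
    warning(sprintf("inverted concentration %.4g ug/mL outside calibrated range %g-%g",
                    conc[1L], cal$conc_range[1L], cal$conc_range[2L]), call. = FALSE)
  }
  conc
}

#' Serialize / restore a calibration line
#'
#' @param cal a `linear_calibration`.
#' @param path JSON file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the restored `linear_calibration`.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "linear_calibration"))
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(slope = obj$slope, intercept = obj$intercept, r = obj$r,
                 wavelength = obj$wavelength, kind = obj$kind,
                 conc_range = as.numeric(obj$conc_range)),
            class = "linear_calibration")
}

#' Divisor standard specification
#'
#' The ratio-subtraction method divides every mixture spectrum by the
#' spectrum of a pure theophylline standard; 22 ug/mL gave the best accuracy
#' and precision among the divisor concentrations studied and is the
#' default.
#'
#' @param spectrum the divisor standard [spectrum()]; must be nonnegative
#'   on unmasked points.
#' @param concentration divisor concentration in ug/mL (> 0).
#' @param analyte analyte label.
#' @return An object of class `divisor_spec`.
#' @export
divisor_spec <- function(spectrum, concentration = 22, analyte = "THP") {
  stopifnot(inherits(spectrum, "spectrum"))
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("divisor concentration must be > 0", call. = FALSE)
  }
  if (any(spectrum$absorbance < -1e-9, na.rm = TRUE)) {
    stop("divisor spectrum must be nonnegative", call. = FALSE)
  }
  structure(list(analyte = analyte, concentration = concentration,
                 spectrum = spectrum),
            class = "divisor_spec")
}

plateau_constant <- function(ratio, window = c(269, 273)) {
  sel <- ratio$wavelength >= window[1L] - 1e-9 & ratio$wavelength <= window[2L] + 1e-9
  vals <- ratio$absorbance[sel]
  if (!length(vals) || anyNA(vals)) {
    stop("masked-read error: plateau window overlaps a masked region", call. = FALSE)
  }
  mean(vals)
}

#' Quantify a ternary mixture by ratio-subtraction + third derivative
#'
#' Implements the full univariate resolution procedure for a
#' hydroxyzine/ephedrine/theophylline mixture spectrum:
#' \enumerate{
#'   \item theophylline read directly on the zero-order spectrum at 271 nm,
#'     where the other two components do not absorb;
#'   \item the mixture divided by the theophylline divisor standard; the
#'     plateau constant (mean ratio over `plateau_window`, where only the
#'     divisor component absorbs) subtracted; hydroxyzine read at 234.2 nm;
#'   \item the subtracted ratio spectrum transformed by the third
#'     derivative (`p`); ephedrine read at 222 nm, the zero-crossing of the
#'     hydroxyzine ratio-derivative.
#' }
#' Each read is inverted through its own calibration line, which must have
#' been built with the same divisor and derivative parameters.
#'
#' @param mix mixture [spectrum()] on the divisor's grid.
#' @param divisor a [divisor_spec()].
#' @param cal_thp,cal_hyx,cal_eph [build_calibration()] lines for the
#'   zero-order, ratio-amplitude and derivative-amplitude reads.
#' @param p [derivative_params()] used for the ephedrine read.
#' @param wavelengths named numeric vector of measurement wavelengths
#'   (defaults `c(thp = 271, hyx = 234.2, eph = 222)`).
#' @param plateau_window wavelength window (nm) over which the ratio
#'   spectrum's plateau constant is averaged.
#' @param floor division floor passed to [divide_spectra()].
#' @param true_concs optional named vector `c(hyx=, eph=, thp=)` of true
#'   concentrations; when given, recoveries are reported.
#' @return An object of class `ternary_result`: fields `conc` (named vector,
#'   ug/mL), `recovery` (named vector, percent, or `NULL`), `plateau_constant`,
#'   `wavelengths`, `warnings`.
#' @export
quantify_ternary <- function(mix, divisor, cal_thp, cal_hyx, cal_eph,
                             p = derivative_params(),
                             wavelengths = c(thp = 271, hyx = 234.2, eph = 222),
                             plateau_window = c(269, 273),
                             floor = 0.01, true_concs = NULL) {
  stopifnot(inherits(mix, "spectrum"), inherits(divisor, "divisor_spec"))
  check_shared_grid(mix, divisor$spectrum, "mixture and divisor")
  warns <- character(0)
  wh <- withCallingHandlers({
    a_thp <- amplitude_at(mix, wavelengths[["thp"]])
    conc_thp <- invert_calibration(cal_thp, a_thp)

    ratio <- divide_spectra(mix, divisor$spectrum, floor = floor)
    k <- plateau_constant(ratio, plateau_window)
    sub <- subtract_constant(ratio, k)
    conc_hyx <- invert_calibration(cal_hyx, amplitude_at(sub, wavelengths[["hyx"]]))

    d3 <- nth_derivative(sub, p)
    conc_eph <- invert_calibration(cal_eph, amplitude_at(d3, wavelengths[["eph"]]))
    list(thp = conc_thp, hyx = conc_hyx, eph = conc_eph, k = k)
  }, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  conc <- c(hyx = wh$hyx, eph = wh$eph, thp = wh$thp)
  recovery <- NULL
  if (!is.null(true_concs)) {
    recovery <- 100 * conc / true_concs[c("hyx", "eph", "thp")]
  }
  structure(list(conc = conc, recovery = recovery,
                 plateau_constant = wh$k,
                 wavelengths = wavelengths, warnings = warns),
            class = "ternary_result")
}

#' @export
print.ternary_result <- function(x, ...) {
  cat("<ternary_result>\n")
  for (a in names(x$conc)) {
    cat(sprintf("  %s: %8.4f ug/mL", toupper(a), x$conc[[a]]))
    if (!is.null(x$recovery)) cat(sprintf("   recovery %6.2f%%", x$recovery[[a]]))
    cat("\n")
  }
  cat(sprintf("  plateau constant: %.6g\n", x$plateau_constant))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Select a measurement wavelength where an interferent vanishes
#'
#' Generalizes the choice of the 222 nm ephedrine wavelength: within a
#' search window, find the wavelength minimizing the interferent's
#' (absolute) derivative amplitude subject to the analyte amplitude staying
#' above a fraction of its window maximum; ties break toward the larger
#' analyte amplitude.
#'
#' @param interferent,analyte [spectrum()] objects on a shared grid
#'   (typically ratio-derivative spectra of the pure components).
#' @param window numeric length-2 wavelength window in nm.
#' @param min_analyte_frac feasibility threshold as a fraction of the
#'   analyte's maximum absolute amplitude within the window.
#' @return Selected wavelength in nm.
#' @export
find_null_wavelength <- function(interferent, analyte, window,
                                 min_analyte_frac = 0.1) {
  stopifnot(inherits(interferent, "spectrum"), inherits(analyte, "spectrum"))
  check_shared_grid(interferent, analyte)
  sel <- which(interferent$wavelength >= window[1L] - 1e-9 &
               interferent$wavelength <= window[2L] + 1e-9)
  if (!length(sel)) stop("selection error: window outside grid", call. = FALSE)
  ia <- abs(interferent$absorbance[sel])
  aa <- abs(analyte$absorbance[sel])
  if (anyNA(ia) || anyNA(aa)) {
    stop("selection error: masked points inside the search window", call. = FALSE)
  }
  amax <- max(aa)
  feasible <- aa >= min_analyte_frac * amax
  if (amax == 0 || !any(feasible)) {
    stop("selection error: no wavelength with usable analyte amplitude", call. = FALSE)
  }
  cand <- which(feasible)
  best <- cand[order(ia[cand], -aa[cand])][1L]
  interferent$wavelength[sel][best]
}
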