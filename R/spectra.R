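#' Construct a spectrum object
#'
#' A `spectrum` is the package's basic data structure: an absorbance trace on
#' a strictly increasing wavelength grid. Masked points (e.g. wavelengths
#' where a ratio spectrum's divisor fell below the division floor) are stored
#' as `NA` absorbance and are refused by [amplitude_at()].
#'
#' @param wavelength numeric vector of wavelengths in nm, strictly increasing.
#' @param absorbance numeric vector of absorbances in AU, same length as
#'   `wavelength`. `NA` marks a masked point; `NaN`/`Inf` are rejected.
#' @param label free-text label carried through arithmetic.
#' @param meta named list of metadata (analyte, concentration in ug/mL,
#'   path length in cm, ...).
#' @return An object of class `spectrum`.
#' @examples
#' s <- spectrum(seq(200, 210, 0.2), rep(0.5, 51), label = "flat")
#' amplitude_at(s, 205.1)
#' @export
spectrum <- function(wavelength, absorbance, label = "", meta = list()) {
  wavelength <- as.numeric(wavelength)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength) != length(absorbance)) {
    stop("wavelength and absorbance must have the same length", call. = FALSE)
  }
  if (length(wavelength) < 2L) {
    stop("a spectrum needs at least two points", call. = FALSE)
  }
  if (anyNA(wavelength) || any(!is.finite(wavelength))) {
    stop("wavelengths must be finite", call. = FALSE)
  }
  if (any(diff(wavelength) <= 0)) {
    stop("wavelengths must be strictly increasing (duplicates are invalid)",
         call. = FALSE)
  }
  if (any(is.nan(absorbance)) || any(is.infinite(absorbance))) {
    stop("absorbance must be finite or NA (masked)", call. = FALSE)
  }
  structure(
    list(wavelength = wavelength, absorbance = absorbance,
         label = as.character(label)[1L], meta = meta),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  n <- length(x$wavelength)
  step <- grid_step(x)
  cat(sprintf("<spectrum> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  %d points, %.6g-%.6g nm, step %s nm\n",
              n, x$wavelength[1L], x$wavelength[n],
              if (is.na(step)) "non-uniform" else format(step)))
  nm <- sum(is.na(x$absorbance))
  if (nm > 0L) cat(sprintf("  %d masked points\n", nm))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, absorbance = x$absorbance)
}

#' Grid step of a spectrum
#'
#' @param s a [spectrum()].
#' @param tol absolute tolerance for declaring the grid uniform.
#' @return The constant grid step in nm, or `NA` if the grid is non-uniform.
#' @export
grid_step <- function(s, tol = 1e-9) {
  d <- diff(s$wavelength)
  if (max(d) - min(d) > tol) return(NA_real_)
  mean(d)
}

stop_parse <- function(path, line, why) {
  stop(sprintf("parse error in '%s' at line %d: %s", path, line, why),
       call. = FALSE)
}

#' Read a spectrum from CSV or JCAMP-DX
#'
#' CSV files hold two numeric columns (wavelength nm, absorbance AU); a
#' header row and `#` comment lines are skipped. JCAMP-DX support covers
#' single-block `XYDATA=(X++(Y..Y))` records in AFFN form, honouring
#' `XFACTOR`/`YFACTOR`. Spectra stored with descending wavelengths are
#' returned in ascending order with absorbances co-permuted.
#'
#' @param path path to the file.
#' @param format `"csv"` or `"jcamp-dx"`; guessed from the file extension
#'   (`.jdx`/`.dx` mean JCAMP-DX) when missing.
#' @param label label for the resulting spectrum; defaults to the file name.
#' @return A [spectrum()].
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, format = NULL, label = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.(jdx|dx|jcamp)$", path, ignore.case = TRUE))
      "jcamp-dx" else "csv"
  }
  format <- match.arg(format, c("csv", "jcamp-dx"))
  if (is.null(label)) label <- basename(path)
  out <- switch(format,
    "csv" = read_spectrum_csv(path),
    "jcamp-dx" = read_spectrum_jcamp(path)
  )
  ord <- order(out$wavelength)
  wl <- out$wavelength[ord]
  ab <- out$absorbance[ord]
  if (anyDuplicated(wl)) {
    stop(sprintf("validation error in '%s': duplicated wavelength %g nm",
                 path, wl[which(duplicated(wl))[1L]]), call. = FALSE)
  }
  spectrum(wl, ab, label = label, meta = out$meta)
}

read_spectrum_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  wl <- ab <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, ",", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) stop_parse(path, i, "expected two comma-separated columns")
    x <- suppressWarnings(as.numeric(parts[1L]))
    y <- suppressWarnings(as.numeric(parts[2L]))
    if (is.na(x) || is.na(y)) {
      if (i == 1L || (length(wl) == 0L && grepl("[A-Za-z]", ln))) next # header
      stop_parse(path, i, sprintf("non-numeric value '%s'", ln))
    }
    wl <- c(wl, x); ab <- c(ab, y)
  }
  if (length(wl) < 2L) stop_parse(path, length(lines), "fewer than two data rows")
  list(wavelength = wl, absorbance = ab, meta = list())
}

read_spectrum_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  xfac <- 1; yfac <- 1
  firstx <- lastx <- npoints <- NA_real_
  meta <- list()
  in_data <- FALSE
  starts <- counts <- numeric(0)
  ab <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "##")) {
      if (in_data && grepl("^##END", ln)) break
      kv <- sub("^##", "", ln)
      key <- toupper(trimws(sub("=.*$", "", kv)))
      val <- trimws(sub("^[^=]*=", "", kv))
      if (key == "XYDATA") {
        if (gsub("\\s", "", val) != "(X++(Y..Y))") {
          stop_parse(path, i, sprintf("unsupported XYDATA form '%s'", val))
        }
        in_data <- TRUE
      } else if (key == "XFACTOR") xfac <- as.numeric(val)
      else if (key == "YFACTOR") yfac <- as.numeric(val)
      else if (key == "FIRSTX") firstx <- as.numeric(val)
      else if (key == "LASTX") lastx <- as.numeric(val)
      else if (key == "NPOINTS") npoints <- as.numeric(val)
      else if (key == "TITLE") meta$title <- val
      next
    }
    if (!in_data) next
    vals <- suppressWarnings(as.numeric(strsplit(ln, "[ \t,]+")[[1L]]))
    if (anyNA(vals) || length(vals) < 2L) {
      stop_parse(path, i, "malformed AFFN data line")
    }
    starts <- c(starts, vals[1L] * xfac)
    counts <- c(counts, length(vals) - 1L)
    ab <- c(ab, vals[-1L] * yfac)
  }
  if (!in_data) stop_parse(path, length(lines), "no XYDATA block found")
  n <- length(ab)
  # prefer the declared FIRSTX/LASTX/NPOINTS grid; fall back to inferring the
  # (signed) step from consecutive line starts
  if (!is.na(firstx) && !is.na(lastx) && !is.na(npoints) && npoints == n) {
    step <- (lastx - firstx) / (npoints - 1)
    wl <- firstx + step * (seq_len(n) - 1)
  } else if (length(starts) > 1L) {
    step <- (starts[2L] - starts[1L]) / counts[1L]
    wl <- unlist(lapply(seq_along(starts), function(j) {
      starts[j] + step * (seq_len(counts[j]) - 1)
    }))
  } else {
    stop_parse(path, length(lines),
               "cannot reconstruct the wavelength grid (need FIRSTX/LASTX/NPOINTS or multiple data lines)")
  }
  list(wavelength = wl, absorbance = ab, meta = meta)
}

#' Write a spectrum to CSV
#'
#' Writes `wavelength_nm,absorbance` rows preceded by a two-line comment
#' header carrying the label and the grid step. Values keep full double
#' precision so that a write/read round trip is exact to 1e-9.
#'
#' @param s a [spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  step <- grid_step(s)
  hdr <- c(sprintf("# label: %s", s$label),
           sprintf("# grid_step_nm: %s",
                   if (is.na(step)) "non-uniform" else format(step, digits = 15)),
           "wavelength_nm,absorbance")
  rows <- sprintf("%s,%s",
                  format(s$wavelength, digits = 15, trim = TRUE, scientific = FALSE),
                  format(s$absorbance, digits = 15, trim = TRUE))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Interpolate a spectrum onto a new wavelength grid
#'
#' Linear interpolation; when the requested grid equals the spectrum's own
#' grid the stored values are passed through unchanged. Extrapolation is
#' refused.
#'
#' @param s a [spectrum()].
#' @param grid target wavelength vector (nm), strictly increasing, inside
#'   the spectrum's range.
#' @return A [spectrum()] on `grid`.
#' @export
align_to_grid <- function(s, grid) {
  stopifnot(inherits(s, "spectrum"))
  grid <- as.numeric(grid)
  if (length(grid) == length(s$wavelength) &&
      max(abs(grid - s$wavelength)) < 1e-9) {
    return(s)
  }
  if (min(grid) < s$wavelength[1L] - 1e-9 ||
      max(grid) > s$wavelength[length(s$wavelength)] + 1e-9) {
    stop(sprintf(
      "range error: requested grid [%g, %g] extends past the data [%g, %g]",
      min(grid), max(grid), s$wavelength[1L], s$wavelength[length(s$wavelength)]),
      call. = FALSE)
  }
  ab <- stats::approx(s$wavelength, s$absorbance, xout = grid)$y
  spectrum(grid, ab, label = s$label, meta = s$meta)
}

check_shared_grid <- function(a, b, what = "spectra") {
  if (length(a$wavelength) != length(b$wavelength) ||
      max(abs(a$wavelength - b$wavelength)) > 1e-9) {
    stop(sprintf("alignment error: %s are not on a shared wavelength grid; use align_to_grid()",
                 what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Divide one spectrum by another (ratio spectrum)
#'
#' Pointwise quotient of a mixture spectrum by a divisor standard spectrum.
#' Wavelengths where the divisor falls below `floor` are masked (`NA`) so
#' that near-zero division noise can never reach an amplitude read.
#'
#' @param numerator,divisor [spectrum()] objects on the same grid.
#' @param floor smallest usable divisor absorbance (AU); must be > 0.
#' @return A [spectrum()] holding the ratio, masked where the divisor is
#'   below `floor`.
#' @export
divide_spectra <- function(numerator, divisor, floor = 0.01) {
  stopifnot(inherits(numerator, "spectrum"), inherits(divisor, "spectrum"))
  if (!is.numeric(floor) || floor <= 0) stop("floor must be > 0", call. = FALSE)
  check_shared_grid(numerator, divisor)
  ok <- !is.na(divisor$absorbance) & divisor$absorbance >= floor &
    !is.na(numerator$absorbance)
  ratio <- ifelse(ok, numerator$absorbance / divisor$absorbance, NA_real_)
  spectrum(numerator$wavelength, ratio,
           label = sprintf("%s / %s", numerator$label, divisor$label),
           meta = numerator$meta)
}

#' Shift a spectrum by a constant
#'
#' Used by the ratio-subtraction step to remove the plateau constant
#' contributed by the divisor component.
#'
#' @param s a [spectrum()].
#' @param k constant (AU) subtracted from every point.
#' @return A [spectrum()].
#' @export
subtract_constant <- function(s, k) {
  stopifnot(inherits(s, "spectrum"), is.numeric(k), length(k) == 1L, is.finite(k))
  spectrum(s$wavelength, s$absorbance - k, label = s$label, meta = s$meta)
}

#' Read an amplitude at a wavelength
#'
#' Returns the stored value when `lambda` lies on the grid, otherwise the
#' linear interpolation between the bracketing grid points. Reading at or
#' next to a masked point is an error: a masked region must never silently
#' contribute to a quantitation.
#'
#' @param s a [spectrum()].
#' @param lambda wavelength in nm, within the grid range.
#' @return Absorbance (AU) at `lambda`.
#' @export
amplitude_at <- function(s, lambda) {
  stopifnot(inherits(s, "spectrum"), is.numeric(lambda), length(lambda) == 1L)
  wl <- s$wavelength
  if (lambda < wl[1L] - 1e-9 || lambda > wl[length(wl)] + 1e-9) {
    stop(sprintf("range error: %g nm outside grid [%g, %g]",
                 lambda, wl[1L], wl[length(wl)]), call. = FALSE)
  }
  i <- findInterval(lambda, wl, rightmost.closed = TRUE)
  i <- max(1L, min(i, length(wl) - 1L))
  exact <- which(abs(wl - lambda) < 1e-9)
  if (length(exact) == 1L) {
    v <- s$absorbance[exact]
    if (is.na(v)) stop(sprintf("masked-read error: %g nm is masked", lambda), call. = FALSE)
    return(v)
  }
  y0 <- s$absorbance[i]; y1 <- s$absorbance[i + 1L]
  if (is.na(y0) || is.na(y1)) {
    stop(sprintf("masked-read error: %g nm lies in a masked region", lambda), call. = FALSE)
  }
  y0 + (y1 - y0) * (lambda - wl[i]) / (wl[i + 1L] - wl[i])
}

#' Collection of spectra sharing one wavelength grid
#'
#' The multivariate calibration methods operate on an `n_samples x
#' n_wavelengths` absorbance matrix whose columns are indexed by a shared
#' grid.
#'
#' @param grid shared wavelength vector (nm), strictly increasing.
#' @param matrix numeric matrix, one row per sample, `length(grid)` columns,
#'   no missing values.
#' @param sample_ids character vector of row identifiers; defaults to
#'   `"s1"`, `"s2"`, ...
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(grid, matrix, sample_ids = NULL) {
  grid <- as.numeric(grid)
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != length(grid)) {
    stop("matrix must have one column per grid wavelength", call. = FALSE)
  }
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  if (anyNA(matrix) || any(!is.finite(matrix))) {
    stop("spectra_set values must be finite (no masked points allowed)", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(matrix)))
  if (length(sample_ids) != nrow(matrix)) {
    stop("sample_ids must match the number of rows", call. = FALSE)
  }
  rownames(matrix) <- sample_ids
  colnames(matrix) <- format(grid, trim = TRUE)
  structure(list(grid = grid, matrix = matrix, sample_ids = sample_ids),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d wavelengths (%.6g-%.6g nm)\n",
              nrow(x$matrix), ncol(x$matrix), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Restrict a spectra_set to a wavelength window
#'
#' @param x a [spectra_set()].
#' @param window numeric length-2 vector, inclusive wavelength bounds in nm.
#' @return A [spectra_set()] on the windowed grid.
#' @export
window_spectra_set <- function(x, window) {
  stopifnot(inherits(x, "spectra_set"), length(window) == 2L)
  keep <- x$grid >= window[1L] - 1e-9 & x$grid <= window[2L] + 1e-9
  if (sum(keep) < 2L) stop("window contains fewer than two grid points", call. = FALSE)
  spectra_set(x$grid[keep], x$matrix[, keep, drop = FALSE], x$sample_ids)
}
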