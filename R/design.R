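# Cyclic generator for the 25-run five-level three-factor calibration
# design: run 1 sits at the centre (all factors coded 0) and each factor's
# remaining 24 runs follow this cycle, the j-th factor starting j-1 places
# into it. The cycle visits every level 5 times per factor (run 1 included)
# and keeps inter-factor correlations low, the standard construction for
# multilevel multifactor calibration sets in chemometrics.
.design_cycle <- c(1, 2, 1, 0, 2, 2, -2, 1, -2, 0, 1, 1,
                   -1, -2, -1, 0, -2, -2, 2, -1, 2, 0, -1, -1)

#' Generate the multilevel multifactor calibration design
#'
#' Builds the 25-run, five-level, three-factor training design used for the
#' multivariate calibration of the hydroxyzine/ephedrine/theophylline
#' mixture. Defaults reproduce the standard concentration levels: HYX
#' 2-10, EPH 3-15, THP 2-18 ug/mL.
#'
#' @param level_sets named list of three sorted, equally spaced five-level
#'   concentration vectors (ug/mL), in factor order.
#' @return An object of class `calibration_design`: `runs` (25 x 3
#'   data.frame of concentrations), `coded` (same shape, levels -2..2),
#'   `level_sets`.
#' @examples
#' d <- generate_design()
#' table(d$runs$hyx)  # each level 5 times
#' @export
generate_design <- function(level_sets = list(hyx = seq(2, 10, by = 2),
                                              eph = seq(3, 15, by = 3),
                                              thp = seq(2, 18, by = 4))) {
  if (length(level_sets) != 3L) {
    stop("design error: exactly 3 factors are supported", call. = FALSE)
  }
  for (nm in names(level_sets)) {
    lv <- level_sets[[nm]]
    if (length(lv) != 5L) {
      stop(sprintf("design error: factor '%s' must have 5 levels", nm), call. = FALSE)
    }
    d <- diff(lv)
    if (any(d <= 0) || max(d) - min(d) > 1e-9) {
      stop(sprintf("design error: levels of '%s' must be sorted and equally spaced", nm),
           call. = FALSE)
    }
  }
  n <- 25L
  coded <- matrix(0L, n, 3L, dimnames = list(NULL, names(level_sets)))
  for (j in 1:3) {
    idx <- ((seq_len(n - 1L) - 1L + (j - 1L)) %% 24L) + 1L
    coded[2:n, j] <- .design_cycle[idx]
  }
  runs <- as.data.frame(lapply(seq_along(level_sets), function(j) {
    level_sets[[j]][coded[, j] + 3L]
  }))
  names(runs) <- names(level_sets)
  structure(list(runs = runs, coded = as.data.frame(coded),
                 level_sets = level_sets),
            class = "calibration_design")
}

#' @export
print.calibration_design <- function(x, ...) {
  cat(sprintf("<calibration_design> %d runs, %d factors, 5 levels each\n",
              nrow(x$runs), ncol(x$runs)))
  print(utils::head(x$runs, 5))
  cat("  ...\n")
  invisible(x)
}
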