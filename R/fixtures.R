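#' Reference ternary mixture compositions
#'
#' The seven laboratory-style mixture compositions used to validate each
#' method, spanning the calibration ranges and including the 2:3:24
#' hydroxyzine:ephedrine:theophylline dose ratio of the commercial tablet
#' formulation.
#'
#' @param set `"ratio"` for the ratio-derivative method's validation
#'   mixtures, `"multivariate"` for the multivariate models' external
#'   validation set.
#' @return data.frame with columns `hyx`, `eph`, `thp` (ug/mL).
#' @export
reference_mixtures <- function(set = c("ratio", "multivariate")) {
  set <- match.arg(set)
  if (set == "ratio") {
    data.frame(
      hyx = c(10, 3, 5, 6, 5, 8, 2),
      eph = c(10, 6, 10, 10, 5, 10, 3),
      thp = c(10, 9, 15, 20, 5, 14, 24)
    )
  } else {
    data.frame(
      hyx = c(8, 6, 6, 2, 2, 4, 4),
      eph = c(9, 15, 12, 6, 3, 6, 12),
      thp = c(18, 18, 14, 10, 18, 14, 18)
    )
  }
}

#' Example recovery table
#'
#' Recovery percentages (one column per analyte) from a seven-mixture
#' validation of the ratio-subtraction/derivative assay, bundled as example
#' input for the validation statistics functions.
#'
#' @return data.frame with columns `hyx`, `eph`, `thp` (recovery %).
#' @examples
#' summary_stats(example_recoveries()$hyx)
#' @export
example_recoveries <- function() {
  data.frame(
    hyx = c(102.60, 101.33, 101.40, 99.17, 101.00, 99.62, 103.00),
    eph = c(102.00, 98.00, 101.70, 98.80, 101.00, 102.90, 102.33),
    thp = c(103.50, 101.55, 101.60, 99.50, 100.60, 102.28, 101.25)
  )
}
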