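#' Summary statistics for assay recoveries
#'
#' Mean, sample standard deviation (n-1 denominator), percent relative
#' standard deviation and variance, as reported in ICH-style validation
#' tables.
#'
#' @param values numeric vector, length >= 2 (typically recovery percentages).
#' @return An object of class `summary_stats`: `n`, `mean`, `sd`,
#'   `rsd_percent` (`100 * sd / mean`), `variance` (`sd^2`).
#' @examples
#' summary_stats(c(102.60, 101.33, 101.40, 99.17, 101.00, 99.62, 103.00))
#' @export
summary_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (anyNA(values)) stop("missing values not allowed", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  structure(list(n = length(values), mean = m, sd = s,
                 rsd_percent = 100 * s / m, variance = s^2),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> n = %d\n", x$n))
  cat(sprintf("  mean %.4f +/- %.4f   %%RSD %.3f   variance %.4f\n",
              x$mean, x$sd, x$rsd_percent, x$variance))
  invisible(x)
}

as_group <- function(g, name) {
  if (is.numeric(g) && length(g) > 1L && is.null(names(g))) {
    return(list(mean = mean(g), sd = stats::sd(g), n = length(g)))
  }
  g <- as.list(g)
  if (!all(c("mean", "sd", "n") %in% names(g))) {
    stop(sprintf("%s must be a numeric vector or a list/vector with mean, sd, n", name),
         call. = FALSE)
  }
  list(mean = g$mean, sd = g$sd, n = g$n)
}

#' Two-sample comparison: pooled t-test and variance-ratio F-test
#'
#' Compares a proposed assay against a reference method the way method
#' comparison tables do: a two-sided pooled-variance Student's t-test on the
#' means and an F-test with the larger variance in the numerator, both at
#' `alpha` (default 0.05). Groups may be given as raw value vectors or as
#' `(mean, sd, n)` summaries, so printed table rows can be replayed
#' directly.
#'
#' @param a,b numeric vectors, or lists/named vectors with elements `mean`,
#'   `sd`, `n`.
#' @param alpha significance level.
#' @return An object of class `comparison_result`: `t_stat`, `t_critical`
#'   (df `n1 + n2 - 2`), `f_stat` (>= 1), `f_critical` (numerator df from
#'   the larger-variance group), `t_pass`, `f_pass` (statistic < critical).
#' @examples
#' two_sample_t(list(mean = 98.00, sd = 1.489, n = 6),
#'              list(mean = 97.32, sd = 1.222, n = 6))
#' @export
two_sample_t <- function(a, b, alpha = 0.05) {
  ga <- as_group(a, "a"); gb <- as_group(b, "b")
  if (ga$n < 2L || gb$n < 2L) stop("each group needs n >= 2", call. = FALSE)
  df <- ga$n + gb$n - 2L
  sp2 <- ((ga$n - 1) * ga$sd^2 + (gb$n - 1) * gb$sd^2) / df
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  t_stat <- (ga$mean - gb$mean) / sqrt(sp2 * (1 / ga$n + 1 / gb$n))
  t_crit <- stats::qt(1 - alpha / 2, df)
  if (ga$sd^2 >= gb$sd^2) {
    f_stat <- ga$sd^2 / gb$sd^2; df1 <- ga$n - 1L; df2 <- gb$n - 1L
  } else {
    f_stat <- gb$sd^2 / ga$sd^2; df1 <- gb$n - 1L; df2 <- ga$n - 1L
  }
  f_crit <- stats::qf(1 - alpha, df1, df2)
  structure(list(t_stat = t_stat, t_critical = t_crit, t_df = df,
                 f_stat = f_stat, f_critical = f_crit, f_df = c(df1, df2),
                 t_pass = abs(t_stat) < t_crit, f_pass = f_stat < f_crit,
                 alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>\n")
  cat(sprintf("  t = %.3f (critical %.3f, df %d)  %s\n",
              x$t_stat, x$t_critical, x$t_df,
              if (x$t_pass) "no significant difference" else "SIGNIFICANT"))
  cat(sprintf("  F = %.3f (critical %.3f, df %d,%d)  %s\n",
              x$f_stat, x$f_critical, x$f_df[1L], x$f_df[2L],
              if (x$f_pass) "comparable precision" else "SIGNIFICANT"))
  invisible(x)
}

#' Standard-addition recovery analysis
#'
#' Quantifies excipient interference: known amounts of pure analyte are
#' spiked into a formulation sample, and the recovery of each added amount
#' is `100 * (spiked_found - base_found) / added`.
#'
#' @param base_found concentration found in the unspiked formulation sample
#'   (ug/mL).
#' @param spiked_found vector of concentrations found after spiking (ug/mL).
#' @param added vector of spiked amounts (ug/mL, all > 0), same length.
#' @return An object of class `standard_addition_result`: `added`, `found`
#'   (recovered added amount), `recovery_percent`, `summary`
#'   ([summary_stats()] of the recoveries), `negative_flag`.
#' @export
standard_addition <- function(base_found, spiked_found, added) {
  spiked_found <- as.numeric(spiked_found); added <- as.numeric(added)
  if (length(spiked_found) != length(added)) stop("length mismatch", call. = FALSE)
  if (any(added <= 0)) stop("added amounts must be > 0", call. = FALSE)
  found <- spiked_found - base_found
  rec <- 100 * found / added
  neg <- rec < 0
  if (any(neg)) {
    warning(sprintf("%d negative recovery value(s) flagged", sum(neg)), call. = FALSE)
  }
  structure(list(added = added, found = found, recovery_percent = rec,
                 summary = if (length(rec) >= 2L) summary_stats(rec) else NULL,
                 negative_flag = neg),
            class = "standard_addition_result")
}

#' @export
print.standard_addition_result <- function(x, ...) {
  cat("<standard_addition_result>\n")
  print(data.frame(added = x$added, found = x$found,
                   recovery_percent = round(x$recovery_percent, 2)))
  if (!is.null(x$summary)) {
    cat(sprintf("  mean recovery %.2f +/- %.3f %%\n", x$summary$mean, x$summary$sd))
  }
  invisible(x)
}
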