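as_x_matrix <- function(X) {
  if (inherits(X, "spectra_set")) return(X$matrix)
  as.matrix(X)
}

x_grid <- function(X) {
  if (inherits(X, "spectra_set")) return(X$grid)
  g <- suppressWarnings(as.numeric(colnames(as.matrix(X))))
  if (anyNA(g)) g <- seq_len(ncol(as.matrix(X)))
  g
}

# fixed sign convention: flip so the largest-magnitude element of v is
# positive, for platform-reproducible loadings
sign_fix <- function(v) if (v[which.max(abs(v))] < 0) -1 else 1

new_mv_model <- function(method, k, grid, x_mean, y_mean, b, extra) {
  structure(c(list(method = method, k = k, grid = grid,
                   x_mean = x_mean, y_mean = y_mean, b = b), extra),
            class = "mv_model")
}

#' Fit a PLS-1 calibration model (NIPALS)
#'
#' Mean-centred univariate-response partial least squares, computed by the
#' NIPALS algorithm: for each component the weight \eqn{w = X^T y} is
#' normalized, scores \eqn{t = Xw}, loadings \eqn{p = X^T t / t^T t},
#' y-loading \eqn{q = y^T t / t^T t}, then `X` and `y` are deflated. The
#' regression vector in original wavelength space is
#' \eqn{b = W (P^T W)^{-1} q}.
#'
#' @param X a [spectra_set()] (already restricted to the working window,
#'   e.g. 210-230 nm) or a numeric matrix, samples in rows.
#' @param y response vector (concentration of one analyte, ug/mL).
#' @param k number of latent variables, `1 <= k <= min(n-1, n_wavelengths)`.
#' @param center mean-centre `X` columns and `y` (default `TRUE`, matching
#'   the conditions under which the models were developed).
#' @param scale divide `X` columns by their standard deviation
#'   (autoscaling; default `FALSE`).
#' @return An object of class `mv_model` with fields `method`, `k`, `grid`,
#'   `x_mean`, `y_mean`, `b` (regression vector), `W`, `P`, `q`.
#' @seealso [fit_pcr()], [predict.mv_model()], [loo_rmsecv()]
#' @export
fit_pls1 <- function(X, y, k, center = TRUE, scale = FALSE) {
  grid <- x_grid(X)
  X <- as_x_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); m <- ncol(X)
  if (length(y) != n) stop("X and y dimensions disagree", call. = FALSE)
  if (stats::sd(y) == 0) stop("fit error: zero-variance y", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > min(n - 1L, m)) {
    stop(sprintf("fit error: k must be in 1..%d", min(n - 1L, m)), call. = FALSE)
  }
  x_mean <- if (center) colMeans(X) else rep(0, m)
  y_mean <- if (center) mean(y) else 0
  x_scale <- if (scale) apply(X, 2L, stats::sd) else rep(1, m)
  if (any(x_scale == 0)) stop("fit error: zero-variance wavelength under autoscaling", call. = FALSE)
  Xc <- sweep(sweep(X, 2L, x_mean), 2L, x_scale, "/")
  yc <- y - y_mean
  W <- P <- matrix(0, m, k)
  q <- numeric(k)
  for (a in seq_len(k)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      # residual covariance exhausted (e.g. noiseless data of lower rank):
      # keep the components extracted so far
      if (a == 1L) stop("fit error: X'y is zero at the first component", call. = FALSE)
      warning(sprintf("residual X'y vanished; using %d of %d requested components",
                      a - 1L, k), call. = FALSE)
      k <- a - 1L
      W <- W[, seq_len(k), drop = FALSE]
      P <- P[, seq_len(k), drop = FALSE]
      q <- q[seq_len(k)]
      break
    }
    w <- w / nw
    w <- w * sign_fix(w)
    t_ <- drop(Xc %*% w)
    tt <- sum(t_^2)
    p <- drop(crossprod(Xc, t_)) / tt
    qa <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, p)
    yc <- yc - t_ * qa
    W[, a] <- w; P[, a] <- p; q[a] <- qa
  }
  b <- drop(W %*% solve(crossprod(P, W), q)) / x_scale
  new_mv_model("PLS1", k, grid, x_mean, y_mean, b,
               list(W = W, P = P, q = q, x_scale = x_scale))
}

#' Fit a principal component regression model
#'
#' Principal components of the mean-centred spectral matrix (via singular
#' value decomposition), ordinary least squares of the centred response on
#' the first `k` scores, and the regression vector mapped back to
#' wavelength space. `k = 0` yields the mean-only model.
#'
#' @inheritParams fit_pls1
#' @param k number of principal components, `0 <= k <= rank(X)`.
#' @return An object of class `mv_model` with fields `method`, `k`, `grid`,
#'   `x_mean`, `y_mean`, `b`, `loadings` (right singular vectors), `gamma`
#'   (score regression coefficients).
#' @export
fit_pcr <- function(X, y, k, center = TRUE, scale = FALSE) {
  grid <- x_grid(X)
  X <- as_x_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); m <- ncol(X)
  if (length(y) != n) stop("X and y dimensions disagree", call. = FALSE)
  if (stats::sd(y) == 0) stop("fit error: zero-variance y", call. = FALSE)
  k <- as.integer(k)
  x_mean <- if (center) colMeans(X) else rep(0, m)
  y_mean <- if (center) mean(y) else 0
  x_scale <- if (scale) apply(X, 2L, stats::sd) else rep(1, m)
  if (any(x_scale == 0)) stop("fit error: zero-variance wavelength under autoscaling", call. = FALSE)
  Xc <- sweep(sweep(X, 2L, x_mean), 2L, x_scale, "/")
  sv <- svd(Xc)
  rank <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1L])
  if (k < 0L || k > rank) {
    stop(sprintf("fit error: k must be in 0..rank(X) = %d", rank), call. = FALSE)
  }
  if (k == 0L) {
    return(new_mv_model("PCR", 0L, grid, x_mean, y_mean, rep(0, m),
                        list(loadings = matrix(0, m, 0), gamma = numeric(0),
                             x_scale = x_scale)))
  }
  V <- sv$v[, seq_len(k), drop = FALSE]
  flips <- apply(V, 2L, sign_fix)
  V <- sweep(V, 2L, flips, "*")
  scores <- Xc %*% V
  gamma <- drop(crossprod(scores, y - y_mean)) / (sv$d[seq_len(k)]^2)
  b <- drop(V %*% gamma) / x_scale
  new_mv_model("PCR", k, grid, x_mean, y_mean, b,
               list(loadings = V, gamma = gamma, x_scale = x_scale))
}

#' @export
print.mv_model <- function(x, ...) {
  cat(sprintf("<mv_model> %s, %d component%s, %d wavelengths (%g-%g nm)\n",
              x$method, x$k, if (x$k == 1) "" else "s", length(x$grid),
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' Predict concentrations from a multivariate model
#'
#' @param object an `mv_model` from [fit_pls1()] or [fit_pcr()].
#' @param newdata a [spectra_set()] or matrix on the model's wavelength
#'   grid.
#' @param ... unused.
#' @return Numeric vector of predicted concentrations (ug/mL), computed
#'   through the regression vector `b`.
#' @export
predict.mv_model <- function(object, newdata, ...) {
  X <- as_x_matrix(newdata)
  if (ncol(X) != length(object$x_mean)) {
    stop("newdata wavelength count disagrees with the model", call. = FALSE)
  }
  drop(sweep(X, 2L, object$x_mean) %*% object$b) + object$y_mean
}

# score-path prediction, kept as an internal cross-check of the assembled
# regression vector
predict_via_scores <- function(object, newdata) {
  X <- as_x_matrix(newdata)
  Xc <- sweep(sweep(X, 2L, object$x_mean), 2L, object$x_scale, "/")
  if (object$method == "PLS1") {
    R <- object$W %*% solve(crossprod(object$P, object$W))
    drop(Xc %*% R %*% object$q) + object$y_mean
  } else {
    if (object$k == 0L) return(rep(object$y_mean, nrow(Xc)))
    drop(Xc %*% object$loadings %*% object$gamma) + object$y_mean
  }
}

#' Leave-one-out cross-validation RMSECV curve
#'
#' For every component count `k = 0..kmax`, each sample is held out once,
#' the model refit on the remaining samples (re-centred each time), and the
#' held-out sample predicted; `RMSECV(k)` is the root mean squared error
#' over the n holds. `k = 0` is the mean-only model.
#'
#' @inheritParams fit_pls1
#' @param method `"pls1"` or `"pcr"`.
#' @param kmax largest component count examined; silently truncated (with a
#'   warning) to `n - 2` so every training fold supports the fit.
#' @return An object of class `cv_result`: `rmsecv` (named vector indexed
#'   `k0..k<kmax>`), `errors` (n x (kmax+1) matrix of held-out errors),
#'   `kmax`, `method`.
#' @export
loo_rmsecv <- function(X, y, method = c("pls1", "pcr"), kmax = 10L,
                       center = TRUE, scale = FALSE) {
  method <- match.arg(method)
  Xm <- as_x_matrix(X)
  y <- as.numeric(y)
  n <- nrow(Xm)
  if (n < 3L) stop("need at least 3 samples for leave-one-out", call. = FALSE)
  if (stats::sd(y) == 0) warning("degenerate: constant y across samples", call. = FALSE)
  kmax <- as.integer(kmax)
  if (kmax >= n - 1L) {
    warning(sprintf("kmax truncated from %d to %d (leave-one-out training size)",
                    kmax, n - 2L), call. = FALSE)
    kmax <- n - 2L
  }
  errors <- matrix(NA_real_, n, kmax + 1L,
                   dimnames = list(NULL, paste0("k", 0:kmax)))
  fit_fun <- if (method == "pls1") fit_pls1 else fit_pcr
  for (i in seq_len(n)) {
    Xtr <- Xm[-i, , drop = FALSE]; ytr <- y[-i]
    Xte <- Xm[i, , drop = FALSE]
    errors[i, 1L] <- mean(ytr) - y[i]  # k = 0: mean-only model
    for (k in seq_len(kmax)) {
      fit <- tryCatch(suppressWarnings(fit_fun(Xtr, ytr, k, center = center, scale = scale)),
                      error = function(e) NULL)
      errors[i, k + 1L] <- if (is.null(fit)) NA_real_ else
        predict(fit, Xte) - y[i]
    }
  }
  rmsecv <- sqrt(colMeans(errors^2))
  structure(list(rmsecv = rmsecv, errors = errors, kmax = kmax,
                 method = method),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s leave-one-out, k = 0..%d\n", x$method, x$kmax))
  print(signif(x$rmsecv, 4))
  invisible(x)
}

#' Choose the number of components from a cross-validation curve
#'
#' @param cv a [loo_rmsecv()] result.
#' @param rule `"fixed"` (return `k_fixed`, the package default of 5
#'   components), `"min"` (argmin of RMSECV over k >= 1), or `"one-se"`
#'   (smallest k >= 1 whose RMSECV is within one standard error of the
#'   minimum, the parsimony rule).
#' @param k_fixed component count returned by the `"fixed"` rule.
#' @return Integer component count.
#' @export
select_components <- function(cv, rule = c("fixed", "min", "one-se"),
                              k_fixed = 5L) {
  rule <- match.arg(rule)
  stopifnot(inherits(cv, "cv_result"))
  if (rule == "fixed") return(as.integer(k_fixed))
  r <- cv$rmsecv[-1L]  # selection considers k >= 1
  ks <- seq_along(r)
  if (rule == "min") return(ks[which.min(r)])
  # one-se: standard error of the minimum-k mean squared error
  kmin <- which.min(r)
  sq <- cv$errors[, kmin + 1L]^2
  se_mse <- stats::sd(sq) / sqrt(length(sq))
  thresh <- sqrt(mean(sq) + se_mse)
  ks[which(r <= thresh + 1e-12)[1L]]
}

#' Prediction diagnostics: RMSEP, recoveries, predicted-vs-actual line
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2 (ug/mL).
#' @return An object of class `prediction_report`: `rmsep`, `recovery`
#'   (percent, elementwise `100 * y_pred / y_true`), and the OLS fit of
#'   predicted on actual (`slope`, `intercept`, `r`).
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("validation error: length mismatch", call. = FALSE)
  }
  if (length(y_true) < 2L) stop("validation error: need >= 2 samples", call. = FALSE)
  rmsep <- sqrt(mean((y_pred - y_true)^2))
  ft <- stats::lm.fit(cbind(1, y_true), y_pred)
  structure(list(rmsep = rmsep,
                 recovery = 100 * y_pred / y_true,
                 slope = unname(ft$coefficients[2L]),
                 intercept = unname(ft$coefficients[1L]),
                 r = stats::cor(y_true, y_pred),
                 y_true = y_true, y_pred = y_pred),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> n = %d\n", length(x$y_true)))
  cat(sprintf("  RMSEP %.4g   mean recovery %.2f%%\n", x$rmsep, mean(x$recovery)))
  cat(sprintf("  predicted vs actual: slope %.4f, intercept %.4f, r %.5f\n",
              x$slope, x$intercept, x$r))
  invisible(x)
}

#' Serialize / restore a multivariate model as JSON
#'
#' @param model an `mv_model`.
#' @param path JSON file path.
#' @return `write_mv_model` returns `path` invisibly; `read_mv_model`
#'   returns the restored `mv_model` (regression-vector fields only; the
#'   score path is reconstructed for PLS from W, P, q).
#' @export
write_mv_model <- function(model, path) {
  stopifnot(inherits(model, "mv_model"))
  obj <- list(method = model$method, k = model$k, grid = model$grid,
              x_mean = model$x_mean, y_mean = model$y_mean, b = model$b,
              x_scale = model$x_scale)
  if (model$method == "PLS1") {
    obj$W <- model$W; obj$P <- model$P; obj$q <- model$q
  } else {
    obj$loadings <- model$loadings; obj$gamma <- model$gamma
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mv_model
#' @export
read_mv_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- length(obj$x_mean)
  as_mat <- function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (nrow(x) != m && ncol(x) == m) x <- t(x)
    x
  }
  extra <- list(x_scale = as.numeric(obj$x_scale))
  if (obj$method == "PLS1") {
    extra$W <- as_mat(obj$W); extra$P <- as_mat(obj$P)
    extra$q <- as.numeric(obj$q)
  } else {
    extra$loadings <- if (obj$k > 0) as_mat(obj$loadings) else matrix(0, m, 0)
    extra$gamma <- as.numeric(obj$gamma)
  }
  new_mv_model(obj$method, as.integer(obj$k), as.numeric(obj$grid),
               as.numeric(obj$x_mean), as.numeric(obj$y_mean),
               as.numeric(obj$b), extra)
}
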