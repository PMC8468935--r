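#' Fit a univariate PLSR model (NIPALS)
#'
#' Partial least squares regression for a single response: mean-centers `X`
#' and `y` and extracts components by the NIPALS recursion
#' `w = X'y / ||X'y||`, `t = X w`, `p = X't / t't`, `q = y't / t't`,
#' deflating `X <- X - t p'` and `y <- y - t q` after each component. The
#' composite regression vector on centered data is
#' `b = W (P'W)^{-1} q`, so predictions are
#' `y_mean + (X_new - x_mean) b`. Optionally autoscales columns
#' (`scale = TRUE`); the default is mean-centering only, the standard choice
#' for spectra.
#'
#' @param X calibration spectra matrix (samples x wavelengths).
#' @param y numeric response vector, `length(y) == nrow(X)`.
#' @param n_components number of latent variables to extract,
#'   `<= min(nrow(X) - 1, ncol(X))`.
#' @param scale logical; autoscale columns of `X` to unit SD before fitting.
#' @param property_name label stored on the model.
#' @return object of class `plsr_model` with elements `x_mean`, `x_scale`,
#'   `y_mean`, `weights` (W), `x_loadings` (P), `y_loadings` (q),
#'   `scores` (T), `coefficients` (b for the full model), `n_components`,
#'   `property_name`.
#' @export
fit_plsr <- function(X, y, n_components, scale = FALSE,
                     property_name = "y") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("fit_plsr: nrow(X) must equal length(y)")
  if (n_components < 1 || n_components > min(n - 1, p)) {
    stop("fit_plsr: n_components must be in [1, min(nrow(X)-1, ncol(X))]")
  }
  if (stats::var(y) < 1e-24) stop("fit_plsr: y has zero variance")
  x_mean <- colMeans(X)
  x_scale <- if (scale) {
    s <- apply(X, 2, stats::sd)
    s[s < 1e-12] <- 1
    s
  } else rep(1, p)
  y_mean <- mean(y)
  Xd <- sweep(sweep(X, 2, x_mean), 2, x_scale, `/`)
  yd <- y - y_mean

  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  k_done <- 0L
  for (k in seq_len(n_components)) {
    s <- crossprod(Xd, yd)  # p x 1
    ns <- sqrt(sum(s^2))
    if (ns < 1e-12) {
      warning(sprintf("fit_plsr: residual covariance vanished at component %d; returning %d components", k, k_done))
      break
    }
    w <- s / ns
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) {
      warning(sprintf("fit_plsr: score norm vanished at component %d; returning %d components", k, k_done))
      break
    }
    pl <- drop(crossprod(Xd, t)) / tt
    qk <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pl)
    yd <- yd - t * qk
    W[, k] <- w
    P[, k] <- pl
    Tm[, k] <- t
    q[k] <- qk
    k_done <- k
  }
  if (k_done == 0L) stop("fit_plsr: no component could be extracted")
  W <- W[, seq_len(k_done), drop = FALSE]
  P <- P[, seq_len(k_done), drop = FALSE]
  Tm <- Tm[, seq_len(k_done), drop = FALSE]
  q <- q[seq_len(k_done)]
  b <- plsr_coefficients(W, P, q, k_done) / x_scale
  structure(list(x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
                 weights = W, x_loadings = P, y_loadings = q, scores = Tm,
                 coefficients = b, n_components = k_done,
                 property_name = property_name),
            class = "plsr_model")
}

# b = W (P'W)^{-1} q using the first k components. P'W is unit upper
# triangular for NIPALS, so a triangular solve suffices.
plsr_coefficients <- function(W, P, q, k) {
  Wk <- W[, seq_len(k), drop = FALSE]
  R <- crossprod(P[, seq_len(k), drop = FALSE], Wk)
  drop(Wk %*% backsolve(R, q[seq_len(k)]))
}

#' Regression coefficient path of a PLSR model
#'
#' @param model a `plsr_model`.
#' @return matrix (wavelengths x components); column `k` is the regression
#'   vector of the `k`-component model (on the original, unscaled X).
#' @export
coefficient_path <- function(model) {
  stopifnot(inherits(model, "plsr_model"))
  k_max <- model$n_components
  B <- sapply(seq_len(k_max), function(k) {
    plsr_coefficients(model$weights, model$x_loadings, model$y_loadings, k) /
      model$x_scale
  })
  matrix(B, ncol = k_max)
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %s: %d latent variable(s), %d wavelengths\n",
              x$property_name, x$n_components, length(x$x_mean)))
  invisible(x)
}

#' Predict from a PLSR model
#'
#' `y_hat = y_mean + (X_new - x_mean) b`.
#'
#' @param object a `plsr_model`.
#' @param newdata matrix (or vector: one sample) with the training grid's
#'   column count, or a [spectra_set()].
#' @param ncomp number of components to use (default: the fitted count).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, newdata, ncomp = object$n_components,
                               ...) {
  if (inherits(newdata, "spectra_set")) newdata <- newdata$reflectance
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$x_mean)) {
    stop("predict.plsr_model: column count does not match the training grid")
  }
  stopifnot(ncomp >= 1, ncomp <= object$n_components)
  b <- if (ncomp == object$n_components) object$coefficients else
    plsr_coefficients(object$weights, object$x_loadings, object$y_loadings,
                      ncomp) / object$x_scale
  drop(sweep(newdata, 2, object$x_mean) %*% b) + object$y_mean
}

#' Select the number of latent variables by leave-one-out cross-validation
#'
#' For each component count `k = 1..max_components`, every sample is left
#' out in turn, the model is refitted on the remaining samples and the
#' left-out sample predicted; RMSECV(k) is the root mean square of those
#' prediction errors. The chosen count minimizes RMSECV, ties broken toward
#' fewer components. Each fold is fitted once to the maximum reachable
#' order, and its whole coefficient path is evaluated, so the brute-force
#' definition is honoured at one NIPALS run per fold.
#'
#' @inheritParams fit_plsr
#' @param max_components largest component count to consider (default 15).
#' @return object of class `cv_result`: list with `rmsecv` (numeric vector,
#'   `NA` for counts no fold could fit), `n_components` (chosen count).
#' @export
select_components <- function(X, y, max_components = 15, scale = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(max_components >= 1, n >= 3)
  k_cap <- min(max_components, n - 2, ncol(X))
  press <- matrix(NA_real_, n, k_cap)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      suppressWarnings(fit_plsr(X[-i, , drop = FALSE], y[-i], k_cap,
                                scale = scale)),
      error = function(e) NULL)
    if (is.null(fit)) next
    Bp <- coefficient_path(fit)
    xc <- X[i, ] - fit$x_mean
    pred <- fit$y_mean + drop(xc %*% Bp)
    press[i, seq_len(fit$n_components)] <- (pred - y[i])^2
  }
  valid <- colSums(is.na(press)) == 0
  if (!any(valid)) stop("select_components: every component count failed in at least one fold")
  rmsecv <- rep(NA_real_, k_cap)
  rmsecv[valid] <- sqrt(colMeans(press[, valid, drop = FALSE]))
  best <- which(rmsecv == min(rmsecv, na.rm = TRUE))[1]
  structure(list(rmsecv = rmsecv, n_components = as.integer(best)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> chosen %d LV (RMSECV %.4g); %d counts evaluated\n",
              x$n_components, x$rmsecv[x$n_components], length(x$rmsecv)))
  invisible(x)
}
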