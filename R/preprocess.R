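#' Trim a spectra set to a wavelength window
#'
#' Retains the columns with `low <= lambda <= high` (closed interval),
#' preserving order. The usual first step: instrument extremes are noisy, so
#' models are built on 400--1000 nm.
#'
#' @param s a [spectra_set()].
#' @param low,high window bounds in nm, `low < high`.
#' @return the trimmed `spectra_set`.
#' @export
trim_wavelengths <- function(s, low, high) {
  stopifnot(inherits(s, "spectra_set"), low < high)
  keep <- s$wavelengths >= low & s$wavelengths <= high
  if (!any(keep)) stop("trim_wavelengths: no wavelengths inside [low, high]")
  spectra_set(s$wavelengths[keep], s$reflectance[, keep, drop = FALSE],
              s$sample_ids, s$metadata)
}

#' Standard normal variate (SNV) transform
#'
#' Standardizes each spectrum to mean 0 and (sample, n-1 denominator) SD 1.
#' Removes per-spectrum additive baseline and multiplicative scaling, the two
#' dominant scatter artefacts in diffuse reflectance.
#'
#' @param s a [spectra_set()].
#' @return transformed `spectra_set`.
#' @export
snv <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  with_matrix(s, snv_matrix(s$reflectance, s$sample_ids))
}

snv_matrix <- function(X, ids = rownames(X)) {
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1))
  bad <- which(sdv < 1e-12)
  if (length(bad)) {
    stop("snv: constant spectrum (zero spread) for sample(s): ",
         paste(if (is.null(ids)) bad else ids[bad], collapse = ", "))
  }
  (X - mu) / sdv
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses each spectrum on a reference spectrum, `x ~ a + b * ref`, by
#' ordinary least squares and returns `(x - a)/b`. The reference defaults to
#' the column-wise mean spectrum of `s` and is stored on the result
#' (attribute `"msc_reference"`) so a calibration-set reference can be
#' replayed, frozen, on prediction spectra.
#'
#' @param s a [spectra_set()].
#' @param reference optional reference spectrum (length = grid length).
#' @return corrected `spectra_set` carrying the fitted reference.
#' @export
msc <- function(s, reference = NULL) {
  stopifnot(inherits(s, "spectra_set"))
  if (is.null(reference)) reference <- colMeans(s$reflectance)
  if (length(reference) != length(s$wavelengths)) {
    stop("msc: reference length must equal the wavelength grid length")
  }
  out <- with_matrix(s, msc_matrix(s$reflectance, reference, s$sample_ids))
  attr(out, "msc_reference") <- as.numeric(reference)
  out
}

msc_matrix <- function(X, ref, ids = rownames(X)) {
  ref <- as.numeric(ref)
  rc <- ref - mean(ref)
  vr <- sum(rc^2)
  if (vr < 1e-24) stop("msc: reference spectrum has (near) zero spread")
  b <- as.numeric((X - rowMeans(X)) %*% rc) / vr
  bad <- which(abs(b) < 1e-12)
  if (length(bad)) {
    stop("msc: spectrum uncorrelated with reference (|b| < 1e-12) for: ",
         paste(if (is.null(ids)) bad else ids[bad], collapse = ", "))
  }
  a <- rowMeans(X) - b * mean(ref)
  (X - a) / b
}

#' Polynomial detrend
#'
#' Subtracts, per spectrum, the least-squares polynomial in wavelength of the
#' given degree (default 2, the conventional SNV-detrend choice). The output
#' has zero projection onto all polynomials up to that degree, removing
#' smooth baseline curvature.
#'
#' @param s a [spectra_set()].
#' @param order polynomial degree, `>= 0` and `< ` grid length.
#' @return detrended `spectra_set`.
#' @export
detrend <- function(s, order = 2) {
  stopifnot(inherits(s, "spectra_set"), order >= 0,
            length(s$wavelengths) > order)
  with_matrix(s, detrend_matrix(s$reflectance, s$wavelengths, order))
}

detrend_matrix <- function(X, lam, order) {
  # scaled Vandermonde + QR for conditioning; subtract orthogonal projection
  u <- (lam - mean(lam)) / (diff(range(lam)) / 2 + (diff(range(lam)) == 0))
  B <- outer(u, 0:order, `^`)
  Q <- qr.Q(qr(B))
  X - (X %*% Q) %*% t(Q)
}

#' Savitzky--Golay filtering (smoothing and derivatives)
#'
#' Local least-squares polynomial filtering on a uniform wavelength grid.
#' Interior points use the classical convolution coefficients; the first and
#' last half-windows are handled by fitting the polynomial on the first/last
#' full window and evaluating it (or its derivative) at the edge points, so
#' the filter is exact on polynomials up to `polyorder` everywhere, including
#' the edges. Derivatives are scaled by `(1/step)^deriv` (per-nm units).
#'
#' @param s a [spectra_set()].
#' @param window odd window length `>= 3`.
#' @param polyorder local polynomial degree, `< window`.
#' @param deriv derivative order (0, 1 or 2), `<= polyorder`.
#' @return filtered `spectra_set`.
#' @export
sg_filter <- function(s, window = 5, polyorder = 2, deriv = 0) {
  stopifnot(inherits(s, "spectra_set"))
  lam <- s$wavelengths
  if (deriv > 0) {
    steps <- diff(lam)
    if (max(abs(steps - steps[1])) > 1e-6 * abs(steps[1])) {
      stop("sg_filter: derivative filtering requires a uniform wavelength grid")
    }
  }
  step <- if (length(lam) > 1) lam[2] - lam[1] else 1
  F <- sg_filter_matrix(length(lam), window, polyorder, deriv)
  with_matrix(s, (s$reflectance %*% t(F)) / step^deriv)
}

#' Savitzky--Golay coefficient matrix
#'
#' Returns the `n x n` linear operator (in index units; divide by
#' `step^deriv` for physical units) applied by [sg_filter()]. Exported
#' mainly for inspection and testing.
#'
#' @param n grid length.
#' @inheritParams sg_filter
#' @return `n x n` matrix `F` such that the filtered row is `F %*% x`.
#' @export
sg_filter_matrix <- function(n, window = 5, polyorder = 2, deriv = 0) {
  if (window %% 2 != 1 || window < 3) stop("sg_filter: window must be odd, >= 3")
  if (polyorder >= window) stop("sg_filter: polyorder must be < window")
  if (deriv > polyorder) stop("sg_filter: deriv must be <= polyorder")
  if (n < window) stop("sg_filter: grid shorter than window")
  half <- (window - 1L) / 2L
  # weights for evaluating the deriv-th derivative of the LS polynomial
  # fitted on points at offsets `x`, evaluated at offset x0
  eval_weights <- function(x, x0) {
    V <- outer(x, 0:polyorder, `^`)
    A <- solve(crossprod(V), t(V))   # (p+1) x window: poly coefficients
    j <- deriv:polyorder
    fac <- factorial(j) / factorial(j - deriv)
    drop((fac * x0^(j - deriv)) %*% A[j + 1, , drop = FALSE])
  }
  offs <- -half:half
  central <- eval_weights(offs, 0)
  F <- matrix(0, n, n)
  for (i in (half + 1):(n - half)) F[i, (i - half):(i + half)] <- central
  head_x <- 0:(window - 1)
  for (i in 1:half) F[i, 1:window] <- eval_weights(head_x, i - 1)
  tail_x <- -(window - 1):0
  for (i in (n - half + 1):n) F[i, (n - window + 1):n] <-
      eval_weights(tail_x, i - n)
  F
}

#' Convert reflectance to apparent absorbance
#'
#' `log10(1/R)`; optional first step of a preprocessing chain for users who
#' prefer scatter correction on the absorbance scale.
#'
#' @param s a [spectra_set()]; all reflectance values must be positive.
#' @return transformed `spectra_set`.
#' @export
absorbance <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  if (any(s$reflectance <= 0)) {
    stop("absorbance: reflectance must be strictly positive")
  }
  with_matrix(s, -log10(s$reflectance))
}

#' Build a preprocessing chain
#'
#' An ordered, parameterized list of spectral transforms applied with
#' [apply_chain()]. Valid step names: `sg_smooth`, `first_derivative`,
#' `second_derivative`, `msc`, `snv`, `detrend`, `absorbance`.
#'
#' @param steps list of steps; each step is either a step name or a list
#'   `list(name = ..., <parameters>)` (e.g.
#'   `list(name = "sg_smooth", window = 5, polyorder = 2)`).
#' @param label display label for reports.
#' @return object of class `preprocessing_chain`.
#' @export
preprocessing_chain <- function(steps = list(), label = NULL) {
  norm <- lapply(steps, function(st) {
    if (is.character(st)) st <- list(name = st)
    if (is.null(st$name)) stop("preprocessing_chain: every step needs a name")
    st$name <- match.arg(st$name, c("sg_smooth", "first_derivative",
                                    "second_derivative", "msc", "snv",
                                    "detrend", "absorbance"))
    if (st$name %in% c("sg_smooth", "first_derivative", "second_derivative")) {
      if (is.null(st$window)) st$window <- 5
      if (is.null(st$polyorder)) st$polyorder <- 2
    }
    if (st$name == "detrend" && is.null(st$order)) st$order <- 2
    st
  })
  names_used <- vapply(norm, `[[`, "", "name")
  if (all(c("msc", "snv") %in% names_used)) {
    stop("preprocessing_chain: msc and snv must not both appear in one chain")
  }
  if (is.null(label)) {
    label <- if (length(norm) == 0) "Original spectra" else
      paste(vapply(norm, `[[`, "", "name"), collapse = " + ")
  }
  structure(list(steps = norm, label = label), class = "preprocessing_chain")
}

#' @export
print.preprocessing_chain <- function(x, ...) {
  cat(sprintf("<preprocessing_chain> %s (%d step%s)\n", x$label,
              length(x$steps), if (length(x$steps) == 1) "" else "s"))
  invisible(x)
}

#' Named preprocessing presets
#'
#' The eight standard variants compared in multi-cut meat calibration work:
#' no preprocessing, MSC, SNV, 5-point Savitzky--Golay smoothing, S--G
#' smoothed first and second derivatives, and S--G + detrend followed by MSC
#' or SNV.
#'
#' @param name preset name; see `chain_presets()` for the list.
#' @return `chain_preset()`: a [preprocessing_chain()];
#'   `chain_presets()`: character vector of preset names.
#' @export
chain_preset <- function(name) {
  name <- match.arg(name, chain_presets())
  sg <- list(name = "sg_smooth", window = 5, polyorder = 2)
  dt <- list(name = "detrend", order = 2)
  switch(name,
    original = preprocessing_chain(list(), "Original spectra"),
    msc = preprocessing_chain(list("msc"), "MSC"),
    snv = preprocessing_chain(list("snv"), "SNV"),
    sg = preprocessing_chain(list(sg), "S-G smoothing"),
    sg_1der = preprocessing_chain(
      list(list(name = "first_derivative", window = 5, polyorder = 2)),
      "S-G + 1st Der"),
    sg_2der = preprocessing_chain(
      list(list(name = "second_derivative", window = 5, polyorder = 2)),
      "S-G + 2nd Der"),
    sg_detrend_msc = preprocessing_chain(list(sg, dt, "msc"),
                                         "S-G + Detrend + MSC"),
    sg_detrend_snv = preprocessing_chain(list(sg, dt, "snv"),
                                         "S-G + Detrend + SNV"))
}

#' @rdname chain_preset
#' @export
chain_presets <- function() {
  c("original", "msc", "snv", "sg", "sg_1der", "sg_2der",
    "sg_detrend_msc", "sg_detrend_snv")
}

#' Apply a preprocessing chain, fitting or replaying its state
#'
#' Applies the chain's steps in order. The only stateful step is MSC: when
#' `state` is `NULL` the MSC reference is fitted (calibration-set mean) and
#' returned in the state; when a previously returned `state` is supplied the
#' stored reference is replayed frozen, which is how prediction spectra must
#' be treated for honest validation.
#'
#' @param s a [spectra_set()].
#' @param chain a [preprocessing_chain()] or preset name.
#' @param state `NULL` to fit, or the `state` element of a previous call.
#' @return list with elements `spectra` (transformed set) and `state`.
#' @export
apply_chain <- function(s, chain, state = NULL) {
  stopifnot(inherits(s, "spectra_set"))
  if (is.character(chain)) chain <- chain_preset(chain)
  stopifnot(inherits(chain, "preprocessing_chain"))
  fitting <- is.null(state)
  if (fitting) state <- list(grid = s$wavelengths, steps = vector("list", length(chain$steps)))
  else {
    if (length(state$grid) != length(s$wavelengths) ||
        max(abs(state$grid - s$wavelengths)) > 1e-9) {
      stop("apply_chain: wavelength grid does not match the fitted state")
    }
  }
  for (i in seq_along(chain$steps)) {
    st <- chain$steps[[i]]
    s <- switch(st$name,
      sg_smooth = sg_filter(s, st$window, st$polyorder, 0),
      first_derivative = sg_filter(s, st$window, st$polyorder, 1),
      second_derivative = sg_filter(s, st$window, st$polyorder, 2),
      snv = snv(s),
      detrend = detrend(s, st$order),
      absorbance = absorbance(s),
      msc = {
        ref <- if (fitting) NULL else state$steps[[i]]$reference
        out <- msc(s, ref)
        if (fitting) state$steps[[i]] <- list(reference = attr(out, "msc_reference"))
        attr(out, "msc_reference") <- NULL
        out
      })
  }
  list(spectra = s, state = state)
}
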