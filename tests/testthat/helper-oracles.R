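# Independent oracles and small fixture builders used across test files.

# SIMPLS (de Jong 1993) for a univariate response: an algorithmically
# independent PLS implementation. For PLS1 its regression coefficients agree
# exactly with NIPALS, so it serves as the reference implementation in the
# agreement tests.
simpls_coef_path <- function(X, y, ncomp) {
  X0 <- scale(X, center = TRUE, scale = FALSE)
  y0 <- y - mean(y)
  p <- ncol(X)
  S <- crossprod(X0, y0)
  V <- matrix(0, p, 0)
  R <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    r <- S
    t <- X0 %*% r
    nt <- sqrt(sum(t^2))
    t <- t / nt
    r <- r / nt
    pl <- crossprod(X0, t)
    q[a] <- sum(y0 * t)
    v <- pl
    if (ncol(V) > 0) v <- v - V %*% crossprod(V, pl)
    v <- v / sqrt(sum(v^2))
    V <- cbind(V, v)
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r
  }
  sapply(seq_len(ncomp), function(k) R[, 1:k, drop = FALSE] %*% q[1:k])
}

# small spectra_set with arbitrary rows
toy_spectra <- function(mat, wavelengths = seq_len(ncol(mat)), meta = NULL) {
  ids <- if (!is.null(meta) && "sample_id" %in% names(meta)) meta$sample_id
         else paste0("S", seq_len(nrow(mat)))
  spectra_set(wavelengths, mat, sample_ids = ids, metadata = meta)
}

# metadata for a d-day, c-carcass, k-cut design (mirrors the generator's)
toy_design_metadata <- function(n_days, carcasses_per_day, cuts) {
  g <- expand.grid(cut_type = cuts,
                   carcass_in_day = seq_len(carcasses_per_day),
                   day = seq_len(n_days), stringsAsFactors = FALSE)
  g$carcass_id <- (g$day - 1L) * carcasses_per_day + g$carcass_in_day
  g$sample_id <- sprintf("D%dC%02d_%s", g$day, g$carcass_id, g$cut_type)
  g[, c("sample_id", "cut_type", "carcass_id", "day")]
}

# fast generator settings: coarse grid, otherwise defaults
coarse_config <- function(...) {
  generator_config(wavelength_step = 3, ...)
}
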