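test_that("trim_wavelengths keeps the closed interval", {
  lam <- seq(200, 1100, by = 0.6)
  s <- toy_spectra(matrix(runif(3 * length(lam)), 3), lam)
  tr <- trim_wavelengths(s, 400, 1000)
  expect_true(all(tr$wavelengths >= 400 & tr$wavelengths <= 1000))
  expect_equal(ncol(tr$reflectance), length(tr$wavelengths))

  # identity on the full range
  tr_full <- trim_wavelengths(s, min(lam), max(lam))
  expect_equal(tr_full$reflectance, s$reflectance)

  # boundary inclusion
  s3 <- toy_spectra(matrix(1:6, 2), c(390, 400, 400.6))
  expect_equal(trim_wavelengths(s3, 400, 1000)$wavelengths, c(400, 400.6))

  expect_error(trim_wavelengths(s3, 500, 600), "no wavelengths")
})

test_that("snv standardizes each spectrum with the n-1 denominator", {
  s <- toy_spectra(rbind(c(1, 2, 3), c(10, 20, 60)))
  out <- snv(s)
  expect_equal(out$reflectance[1, ], c(-1, 0, 1), ignore_attr = TRUE)

  # frozen hand computation: mean 5, sample sd sqrt(32/7)
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  out2 <- snv(toy_spectra(matrix(x, 1)))
  expect_equal(out2$reflectance[1, ], (x - 5) / 2.1380899352994,
               tolerance = 1e-12, ignore_attr = TRUE)

  # idempotence and the row-moment invariant
  set.seed(1)
  r <- toy_spectra(matrix(rnorm(200), 10))
  once <- snv(r)
  expect_equal(snv(once)$reflectance, once$reflectance, tolerance = 1e-12)
  expect_lt(max(abs(rowMeans(once$reflectance))), 1e-10)
  expect_lt(max(abs(apply(once$reflectance, 1, sd) - 1)), 1e-10)

  flat <- toy_spectra(rbind(c(1, 2, 3), c(4, 4, 4)),
                      meta = data.frame(sample_id = c("a", "bad_row")))
  expect_error(snv(flat), "bad_row")
})

test_that("msc fits and removes per-spectrum affine scatter", {
  ref <- sin(seq(0, 3, length.out = 40)) + 2
  # a single spectrum is its own mean reference: identity
  s1 <- toy_spectra(matrix(ref, 1))
  expect_equal(msc(s1)$reflectance[1, ], ref, tolerance = 1e-10,
               ignore_attr = TRUE)

  # exact affine scatter against an explicit reference
  s2 <- toy_spectra(matrix(3 + 2 * ref, 1))
  expect_equal(msc(s2, reference = ref)$reflectance[1, ], ref,
               tolerance = 1e-10, ignore_attr = TRUE)

  # two-spectrum set: closed-form two-parameter OLS computed independently
  set.seed(42)
  eps <- rnorm(40, sd = 0.01)
  X <- rbind(ref + eps, 2 * ref - eps)
  out <- msc(toy_spectra(X), reference = ref)
  for (i in 1:2) {
    x <- X[i, ]
    b_hat <- sum((x - mean(x)) * (ref - mean(ref))) /
      sum((ref - mean(ref))^2)
    a_hat <- mean(x) - b_hat * mean(ref)
    expect_equal(out$reflectance[i, ], (x - a_hat) / b_hat,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }

  # the fitted reference (mean spectrum) maps to itself
  set.seed(7)
  Xm <- matrix(rnorm(5 * 40, rep(ref, each = 5), 0.2), 5)
  m <- colMeans(Xm)
  out2 <- msc(toy_spectra(rbind(Xm, m)))
  expect_equal(out2$reflectance[6, ], attr(out2, "msc_reference"),
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(msc(toy_spectra(matrix(ref, 1)), reference = ref[-1]),
               "length")
})

test_that("detrend removes the least-squares polynomial baseline", {
  lam <- seq(400, 1000, by = 5)
  # annihilation of a polynomial of the detrend degree
  s <- toy_spectra(matrix(5 + 0.01 * lam, 1), lam)
  expect_lt(max(abs(detrend(s, 2)$reflectance)), 1e-9)

  # order 0 is row-mean centering
  set.seed(3)
  X <- matrix(rnorm(4 * length(lam)), 4)
  sX <- toy_spectra(X, lam)
  expect_equal(detrend(sX, 0)$reflectance, X - rowMeans(X),
               tolerance = 1e-10, ignore_attr = TRUE)

  # independent normal-equations oracle on a sine + quadratic row
  y <- sin(lam / 50) + 1e-4 * (lam - 700)^2
  u <- (lam - mean(lam)) / (diff(range(lam)) / 2)
  V <- outer(u, 0:2, `^`)
  beta <- solve(crossprod(V), crossprod(V, y))
  expect_equal(detrend(toy_spectra(matrix(y, 1), lam), 2)$reflectance[1, ],
               y - drop(V %*% beta), tolerance = 1e-8, ignore_attr = TRUE)

  # residuals orthogonal to the Vandermonde columns up to the degree
  dt <- detrend(sX, 3)$reflectance
  Vb <- outer(u, 0:3, `^`)
  rel <- abs(dt %*% Vb) / (sqrt(rowSums(dt^2)) %o% sqrt(colSums(Vb^2)))
  expect_lt(max(rel), 1e-8)
})

test_that("savitzky-golay filter is exact on polynomials, edges included", {
  lam <- seq(400, 430, by = 1.5)
  quad <- 2 + 0.3 * lam - 0.001 * lam^2
  s <- toy_spectra(rbind(quad, 5 - 0.2 * lam + 0.002 * lam^2), lam)
  sm <- sg_filter(s, window = 5, polyorder = 2, deriv = 0)
  expect_equal(sm$reflectance, s$reflectance, tolerance = 1e-9)

  # first derivative of a line is its slope everywhere, in per-nm units
  line <- toy_spectra(matrix(3 * lam + 1, 1), lam)
  d1 <- sg_filter(line, 5, 2, deriv = 1)
  expect_equal(d1$reflectance[1, ], rep(3, length(lam)), tolerance = 1e-9,
               ignore_attr = TRUE)

  # second derivative of the quadratic is constant 2*a
  d2 <- sg_filter(toy_spectra(matrix(quad, 1), lam), 5, 2, deriv = 2)
  expect_equal(d2$reflectance[1, ], rep(-0.002, length(lam)),
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(sg_filter(s, window = 4), "odd")
  expect_error(sg_filter(s, window = 5, polyorder = 5), "polyorder")
  expect_error(sg_filter(s, 5, 2, deriv = 3), "deriv")
  bumpy <- toy_spectra(matrix(1:8, 1), c(1, 2, 3, 5, 8, 9, 10, 11))
  expect_error(sg_filter(bumpy, 5, 2, deriv = 1), "uniform")
})

test_that("classical 5-point quadratic coefficients and noise reduction", {
  F <- sg_filter_matrix(9, window = 5, polyorder = 2, deriv = 0)
  expect_equal(F[5, 3:7], c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rowSums(F), rep(1, 9), tolerance = 1e-12)

  # central value on a spike row by direct dot product
  row <- c(1, 2, 3, 10, 3, 2, 1)
  sm <- sg_filter(toy_spectra(matrix(row, 1)), 5, 2, 0)
  expect_equal(sm$reflectance[1, 4],
               sum(c(-3, 12, 17, 12, -3) / 35 * row[2:6]),
               tolerance = 1e-12, ignore_attr = TRUE)

  # white-noise variance shrinks by ~ sum of squared coefficients (0.4857)
  set.seed(10)
  noise <- matrix(rnorm(30 * 1000), 30)
  sm2 <- sg_filter(toy_spectra(noise), 5, 2, 0)
  interior <- sm2$reflectance[, 3:998]
  ratio <- mean(apply(interior, 1, var)) / mean(apply(noise, 1, var))
  expect_lt(abs(ratio - sum((c(-3, 12, 17, 12, -3) / 35)^2)), 0.05)
})

test_that("preprocessing chains compose, fit and replay correctly", {
  set.seed(5)
  lam <- seq(400, 1000, by = 10)
  base <- sin(lam / 80) / 2 + 1
  X <- matrix(rep(base, each = 12), 12) * (1 + rnorm(12, 0, 0.2)) +
    rnorm(12, 0, 0.1) + matrix(rnorm(12 * length(lam), 0, 0.01), 12)
  s <- toy_spectra(X, lam, meta = data.frame(sample_id = paste0("S", 1:12),
                                             cut_type = rep(c("a", "b"), 6)))

  # empty chain is the identity with an empty state
  out0 <- apply_chain(s, preprocessing_chain())
  expect_equal(out0$spectra$reflectance, s$reflectance)

  # chain application equals manual sequential application
  chain <- chain_preset("sg_detrend_snv")
  manual <- snv(detrend(sg_filter(s, 5, 2, 0), 2))
  expect_equal(apply_chain(s, chain)$spectra$reflectance,
               manual$reflectance, tolerance = 1e-12)

  # msc state: frozen calibration reference differs from refitting
  cal <- subset_samples(s, paste0("S", 1:8))
  prd <- subset_samples(s, paste0("S", 9:12))
  fit <- apply_chain(cal, "sg_detrend_msc")
  replay <- apply_chain(prd, "sg_detrend_msc", state = fit$state)
  refit <- apply_chain(prd, "sg_detrend_msc")
  expect_false(isTRUE(all.equal(replay$spectra$reflectance,
                                refit$spectra$reflectance)))
  # replaying calibration data reproduces the fitted output
  cal_replay <- apply_chain(cal, "sg_detrend_msc", state = fit$state)
  expect_equal(cal_replay$spectra$reflectance, fit$spectra$reflectance,
               tolerance = 1e-12)

  # grid mismatch is refused on replay
  expect_error(apply_chain(trim_wavelengths(prd, 500, 900), "sg_detrend_msc",
                           state = fit$state), "grid")

  # msc and snv are mutually exclusive in one chain
  expect_error(preprocessing_chain(list("msc", "snv")), "both")

  # all presets exist and the named set is complete
  expect_length(chain_presets(), 8)
  for (nm in chain_presets()) {
    expect_s3_class(chain_preset(nm), "preprocessing_chain")
  }
})

test_that("operators are permutation-equivariant and keep metadata", {
  set.seed(9)
  lam <- seq(400, 460, by = 2)
  X <- matrix(rnorm(6 * length(lam), 10), 6)
  meta <- data.frame(sample_id = paste0("S", 1:6), cut_type = letters[1:6])
  s <- toy_spectra(X, lam, meta = meta)
  perm <- c(4, 1, 6, 2, 5, 3)
  sp <- subset_samples(s, paste0("S", perm))
  for (op in list(snv, function(z) detrend(z, 2),
                  function(z) sg_filter(z, 5, 2, 1),
                  function(z) msc(z, reference = colMeans(X)))) {
    a <- op(s)
    b <- op(sp)
    expect_equal(b$reflectance, a$reflectance[perm, ], tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(b$metadata$cut_type, meta$cut_type[perm])
  }
})
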