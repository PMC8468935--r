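test_that("generated dataset matches the sampling design and is seeded", {
  d <- generate_dataset(coarse_config(seed = 7))
  expect_equal(nrow(d$spectra$reflectance), 150)
  expect_equal(nrow(d$references), 150)
  expect_equal(nrow(d$latent_concentrations), 150)
  expect_equal(d$spectra$sample_ids, d$references$sample_id)
  expect_equal(sort(unique(d$spectra$metadata$day)), 1:5)
  expect_equal(length(unique(d$spectra$metadata$carcass_id)), 25)
  expect_setequal(unique(d$spectra$metadata$cut_type), default_cut_types())

  d2 <- generate_dataset(coarse_config(seed = 7))
  expect_identical(d, d2)

  d3 <- generate_dataset(coarse_config(seed = 8))
  expect_false(identical(d$spectra$reflectance, d3$spectra$reflectance))

  # tiny design product
  tiny <- generate_dataset(coarse_config(
    n_days = 1, carcasses_per_day = 1,
    cut_types = c("fillet", "oyster"), seed = 1))
  expect_equal(nrow(tiny$references), 2)
})

test_that("generator seeding does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_dataset(coarse_config(
    n_days = 1, carcasses_per_day = 1, seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("zero contamination yields clean Beer-Lambert spectra", {
  clean_cfg <- function(reps) coarse_config(
    scatter_multiplicative_sd = 0, scatter_additive_sd = 0,
    baseline_tilt_sd = 0, noise_sd = 0,
    replicates_per_sample = reps, seed = 3)
  d1 <- generate_dataset(clean_cfg(1))
  d5 <- generate_dataset(clean_cfg(5))
  # replicate averaging of noiseless replicates is exact
  expect_equal(d1$spectra$reflectance, d5$spectra$reflectance,
               tolerance = 1e-12)

  # reconstruct band absorbance from the stored latent concentrations: the
  # remainder must be the shared fixed baseline, identical for all samples
  cfg <- d1$config
  lam <- d1$spectra$wavelengths
  G <- sapply(seq_along(cfg$band_centers), function(k) {
    exp(-(lam - cfg$band_centers[k])^2 / (2 * cfg$band_widths[k]^2))
  })
  resid <- -log10(d1$spectra$reflectance) - d1$latent_concentrations %*% t(G)
  spread <- apply(resid, 2, function(col) diff(range(col)))
  expect_lt(max(spread), 1e-10)
})

test_that("generated properties respect bounds and configured moments", {
  d <- generate_dataset(coarse_config(seed = 11))
  pd <- default_property_distributions()
  meta <- d$spectra$metadata
  cut <- meta$cut_type[match(d$references$sample_id, meta$sample_id)]
  for (g in default_cut_types()) {
    for (p in property_names()) {
      v <- d$references[[p]][cut == g]
      row <- pd[pd$cut == g & pd$property == p, ]
      expect_true(all(v >= row$min & v <= row$max),
                  label = sprintf("%s/%s inside configured bounds", g, p))
    }
  }
  # per-cut pH sample moments within 3 standard errors of the configuration
  for (g in default_cut_types()) {
    v <- d$references$pH[cut == g]
    row <- pd[pd$cut == g & pd$property == "pH", ]
    n <- length(v)
    expect_lt(abs(mean(v) - row$mean), 3 * row$sd / sqrt(n))
    expect_lt(abs(sd(v) - row$sd), 3 * row$sd / sqrt(2 * n))
  }
})

test_that("pooled property correlations converge to the configured target", {
  # 40 days x 25 carcasses x 6 cuts = 6000 samples; spectra on a very coarse
  # grid since only the reference table matters here
  d <- generate_dataset(generator_config(
    n_days = 40, carcasses_per_day = 25, wavelength_step = 50, seed = 5))
  emp <- cor(as.matrix(d$references[property_names()]))
  expect_lt(max(abs(emp - default_property_correlations())), 0.05)
})

test_that("invalid generator configurations are rejected", {
  bad_corr <- matrix(0.99, 6, 6)
  bad_corr[1, 2] <- bad_corr[2, 1] <- -0.99
  diag(bad_corr) <- 1
  dimnames(bad_corr) <- list(property_names(), property_names())
  expect_error(generator_config(property_correlations = bad_corr),
               "positive definite")
  expect_error(generator_config(band_centers = c(200, 550),
                                band_widths = c(20, 20)), "inside")
  expect_error(generator_config(band_centers = c(430, 550)), "lengths")
  expect_error(generator_config(noise_sd = -1), ">= 0")
  expect_error(generator_config(replicates_per_sample = 0))
  pd <- default_property_distributions()
  pd$min[1] <- pd$max[1] + 1
  expect_error(generator_config(property_distributions = pd), "min >= max")
})

test_that("simulate_acquisition implements two-point calibration", {
  nw <- 11
  dark <- rep(100, nw)
  white <- seq(2000, 3000, length.out = nw)
  expect_equal(drop(simulate_acquisition(white, dark, white)), rep(1, nw))
  expect_equal(drop(simulate_acquisition(dark, dark, white)), rep(0, nw))
  expect_equal(drop(simulate_acquisition((white + dark) / 2, dark, white)),
               rep(0.5, nw))
  expect_error(simulate_acquisition(white, white, dark), "positive")
  expect_warning(out <- simulate_acquisition(white * 2, dark, white),
                 "clipped")
  expect_true(all(out <= 1.2))
})

test_that("cooking_loss evaluates the mass-loss formula and validates input", {
  expect_equal(cooking_loss(100, 100), 0)
  expect_equal(cooking_loss(100, 80), 20)
  expect_equal(cooking_loss(98.37, 76.22), 22.51702755, tolerance = 1e-8)
  expect_error(cooking_loss(0, 0), "mass_before")
  expect_error(cooking_loss(100, 101), "mass_after")
  expect_error(cooking_loss(100, -1), "mass_after")
})
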