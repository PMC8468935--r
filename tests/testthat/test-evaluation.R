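test_that("rmse uses the n divisor and scales homogeneously", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3), tolerance = 1e-12)
  set.seed(1)
  o <- rnorm(50)
  p <- rnorm(50)
  for (c_ in c(-3, 0.5, 10)) {
    expect_equal(rmse(c_ * o, c_ * p), abs(c_) * rmse(o, p),
                 tolerance = 1e-12)
  }
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("r_squared implements 1 - SSE/SST with an optional r^2 variant", {
  o <- c(1, 2, 3, 4)
  expect_equal(r_squared(o, o), 1)
  expect_equal(r_squared(o, rep(mean(o), 4)), 0)
  # hand arithmetic: SSE = 0.10, SST = 5.0
  expect_equal(r_squared(o, c(1.1, 1.9, 3.2, 3.8)), 1 - 0.10 / 5.0,
               tolerance = 1e-12)
  # the squared-correlation variant ignores bias; the default does not
  biased <- o + 10
  expect_equal(r_squared(o, biased, method = "squared_correlation"), 1)
  expect_lt(r_squared(o, biased), 0)
  expect_error(r_squared(rep(2, 4), o), "constant")
})

test_that("rpd is the prediction-set SD over RMSEP", {
  # two-point vectors with SD set exactly to the printed value
  refs_with_sd <- function(s) c(-s / sqrt(2), s / sqrt(2))
  expect_equal(rpd(refs_with_sd(0.14), 0.04), 3.50, tolerance = 1e-12)
  expect_equal(round(rpd(refs_with_sd(7.41), 2.64), 2), 2.81)
  expect_equal(rpd(refs_with_sd(1), 1), 1)
  expect_error(rpd(1, 0.5), "at least 2")
  expect_error(rpd(c(1, 2), 0), "positive")
})

test_that("rpd_grade maps values to the standard bands", {
  expect_equal(rpd_grade(3.50), "process control")
  expect_equal(rpd_grade(1.99), "not recommended")
  expect_equal(rpd_grade(2.81), "screening")
  expect_equal(rpd_grade(c(0, 2.0, 2.49, 2.5, 3.0, 3.49, 3.99, 4.0, 9)),
               c("not recommended", "rough screening", "rough screening",
                 "screening", "quality control", "quality control",
                 "process control", "excellent", "excellent"))
  expect_error(rpd_grade(-0.1), ">= 0")
})

test_that("cv_percent reproduces printed coefficient-of-variation cells", {
  expect_equal(round(cv_percent(0.12, 5.90), 2), 2.03)
  expect_equal(round(cv_percent(7.41, 43.76), 2), 16.93)
  expect_equal(round(cv_percent(6.93, 43.90), 2), 15.79)
  expect_error(cv_percent(1, 0), "nonzero")
})

test_that("model_report rows are internally consistent", {
  set.seed(2)
  for (rep in 1:5) {
    o_cal <- rnorm(40, 20, 4)
    f_cal <- o_cal + rnorm(40, sd = 1)
    o_prd <- rnorm(15, 20, 4)
    p_prd <- o_prd + rnorm(15, sd = 1.5)
    row <- model_report("pH", "SNV", 5, o_cal, f_cal, o_prd, p_prd)
    expect_equal(row$rpd, sd(o_prd) / row$rmsep, tolerance = 1e-9)
    expect_equal(row$grade, rpd_grade(row$rpd))
    expect_equal(row$rmsec, rmse(o_cal, f_cal))
  }

  # on fixed prediction references, lower RMSEP implies higher R2p
  o <- rnorm(30, 10, 2)
  p1 <- o + rnorm(30, sd = 2)
  p2 <- o + 0.5 * (p1 - o)  # strictly smaller errors
  expect_lt(rmse(o, p2), rmse(o, p1))
  expect_gt(r_squared(o, p2), r_squared(o, p1))
})

test_that("descriptive_table gives per-cut and pooled summaries", {
  refs <- data.frame(sample_id = paste0("S", 1:5),
                     pH = c(5.8, 6.0, 6.1, 5.9, 6.2))
  meta <- data.frame(sample_id = paste0("S", 1:5),
                     cut_type = c("a", "a", "b", "b", "c"))
  tab <- descriptive_table(refs, meta)
  expect_equal(nrow(tab), 4)  # a, b, c, all cuts
  a_row <- tab[tab$cut == "a", ]
  expect_equal(a_row$mean, 5.9)
  expect_equal(a_row$sd, sd(c(5.8, 6.0)))
  all_row <- tab[tab$cut == "all cuts", ]
  expect_equal(all_row$cv, cv_percent(sd(refs$pH), mean(refs$pH)))
  # single-value group reports missing SD/CV
  c_row <- tab[tab$cut == "c", ]
  expect_true(is.na(c_row$sd) && is.na(c_row$cv))
})

test_that("correlation_table matches the textbook formula and flags stars", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.0)
  y <- c(2.0, 1.8, 3.9, 4.4, 6.1)
  z <- c(9.1, 7.2, 8.3, 2.2, 1.0)
  refs <- data.frame(sample_id = paste0("S", 1:5), pH = x, Lstar = y,
                     astar = z)
  ct <- correlation_table(refs)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ct$r["pH", "Lstar"], r_hand, tolerance = 1e-12)
  expect_equal(diag(ct$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(ct$r, t(ct$r))
  # p-value via the t transform with n-2 df
  tv <- r_hand * sqrt((5 - 2) / (1 - r_hand^2))
  expect_equal(ct$p_value["pH", "Lstar"], 2 * pt(abs(tv), 3, lower.tail = FALSE),
               tolerance = 1e-12)

  # exactly proportional properties: r = 1, p ~ 0, two stars
  refs2 <- data.frame(sample_id = paste0("S", 1:6),
                      pH = 1:6, Lstar = 2 * (1:6) + 3)
  ct2 <- correlation_table(refs2)
  expect_equal(ct2$r["pH", "Lstar"], 1, tolerance = 1e-12)
  expect_lt(ct2$p_value["pH", "Lstar"], 1e-10)
  expect_equal(ct2$stars["pH", "Lstar"], "**")

  expect_error(correlation_table(refs[1:2, ]), "at least 3")
  refs3 <- data.frame(sample_id = paste0("S", 1:5), pH = rep(6, 5),
                      Lstar = y)
  expect_warning(correlation_table(refs3), "constant")
})
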