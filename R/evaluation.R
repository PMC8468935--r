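#' Root mean square error
#'
#' `sqrt(mean((observed - predicted)^2))`, divisor `n`. RMSEC when computed
#' on the calibration set, RMSEP on the prediction set.
#'
#' @param observed,predicted numeric vectors of equal length (>= 1).
#' @return RMSE in the units of the property.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("rmse: observed and predicted must have equal length")
  }
  if (length(observed) < 1) stop("rmse: empty input")
  sqrt(mean((observed - predicted)^2))
}

#' Coefficient of determination
#'
#' Default `1 - SSE/SST` with SST about the observed mean. The squared
#' Pearson correlation variant is available via
#' `method = "squared_correlation"` for comparison; the two agree for
#' fitted values of a linear model with intercept and differ otherwise.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param method `"one_minus_sse_sst"` (default) or `"squared_correlation"`.
#' @return dimensionless R-squared.
#' @export
r_squared <- function(observed, predicted,
                      method = c("one_minus_sse_sst", "squared_correlation")) {
  method <- match.arg(method)
  if (length(observed) != length(predicted)) {
    stop("r_squared: observed and predicted must have equal length")
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst < 1e-24) stop("r_squared: observed values are constant")
  if (method == "one_minus_sse_sst") {
    1 - sum((observed - predicted)^2) / sst
  } else {
    stats::cor(observed, predicted)^2
  }
}

#' Residual predictive deviation (RPD)
#'
#' SD (n-1 denominator) of the prediction-set reference values divided by
#' RMSEP. The conventional scale-free index of NIR calibration quality.
#'
#' @param prediction_references reference values of the prediction set
#'   (>= 2 values).
#' @param rmsep prediction root mean square error, > 0.
#' @return dimensionless RPD.
#' @export
rpd <- function(prediction_references, rmsep) {
  if (length(prediction_references) < 2) {
    stop("rpd: need at least 2 prediction samples")
  }
  if (!is.finite(rmsep) || rmsep <= 0) {
    stop("rpd: rmsep must be a positive number")
  }
  stats::sd(prediction_references) / rmsep
}

#' Grade an RPD value
#'
#' Standard interpretation bands: `< 2.0` not recommended; `[2.0, 2.5)`
#' rough screening; `[2.5, 3.0)` screening; `[3.0, 3.5)` quality control;
#' `[3.5, 4.0)` process control; `>= 4.0` excellent.
#'
#' @param rpd_value non-negative RPD value(s).
#' @return character grade label(s).
#' @export
rpd_grade <- function(rpd_value) {
  if (any(rpd_value < 0)) stop("rpd_grade: RPD must be >= 0")
  labels <- c("not recommended", "rough screening", "screening",
              "quality control", "process control", "excellent")
  idx <- findInterval(rpd_value, c(2.0, 2.5, 3.0, 3.5, 4.0)) + 1L
  labels[idx]
}

#' Coefficient of variation in percent
#'
#' `100 * sd / mean`.
#'
#' @param sd_value standard deviation.
#' @param mean_value mean (nonzero).
#' @return CV in percent.
#' @export
cv_percent <- function(sd_value, mean_value) {
  if (any(mean_value == 0)) stop("cv_percent: mean must be nonzero")
  100 * sd_value / mean_value
}

#' Assemble one model report row
#'
#' @param property property label.
#' @param chain_label preprocessing chain label.
#' @param n_lv latent variable count.
#' @param obs_cal,fit_cal calibration-set observed and fitted values.
#' @param obs_pred,pred_pred prediction-set observed and predicted values.
#' @param r2_method passed to [r_squared()].
#' @return one-row data.frame with columns `property`, `preprocessing`,
#'   `n_lv`, `r2_c`, `rmsec`, `r2_p`, `rmsep`, `rpd`, `grade`.
#' @export
model_report <- function(property, chain_label, n_lv, obs_cal, fit_cal,
                         obs_pred, pred_pred,
                         r2_method = "one_minus_sse_sst") {
  rmsec <- rmse(obs_cal, fit_cal)
  rmsep <- rmse(obs_pred, pred_pred)
  rpd_v <- rpd(obs_pred, rmsep)
  data.frame(property = property, preprocessing = chain_label,
             n_lv = as.integer(n_lv),
             r2_c = r_squared(obs_cal, fit_cal, r2_method),
             rmsec = rmsec,
             r2_p = r_squared(obs_pred, pred_pred, r2_method),
             rmsep = rmsep, rpd = rpd_v, grade = rpd_grade(rpd_v),
             stringsAsFactors = FALSE)
}

#' Per-cut descriptive statistics
#'
#' Max, min, mean, SD (n-1) and CV% per cut type plus a pooled
#' `"all cuts"` row, per property. Single-value groups report SD/CV as `NA`.
#'
#' @param references data.frame with `sample_id` and property columns.
#' @param metadata data.frame with `sample_id` and `cut_type`.
#' @param properties properties to summarize (default: all six present).
#' @return data.frame with columns `property`, `cut`, `max`, `min`, `mean`,
#'   `sd`, `cv`.
#' @export
descriptive_table <- function(references, metadata,
                              properties = intersect(property_names(),
                                                     names(references))) {
  cut <- metadata$cut_type[match(references$sample_id, metadata$sample_id)]
  one <- function(p, label, v) {
    s <- if (length(v) > 1) stats::sd(v) else NA_real_
    data.frame(property = p, cut = label, max = max(v), min = min(v),
               mean = mean(v), sd = s,
               cv = if (is.na(s)) NA_real_ else cv_percent(s, mean(v)),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(properties, function(p) {
    v <- references[[p]]
    rows <- lapply(unique(cut), function(g) one(p, g, v[cut == g]))
    rbind(do.call(rbind, rows), one(p, "all cuts", v))
  }))
  rownames(out) <- NULL
  out
}

#' Pearson correlation table with significance
#'
#' Pairwise Pearson correlations between the property columns, two-sided
#' p-values from the t transform `t = r sqrt((n-2)/(1-r^2))` with `n - 2`
#' degrees of freedom, and significance stars at 0.05 / 0.01.
#'
#' @param references data.frame with `sample_id` and property columns.
#' @param properties properties to correlate (default: all six present).
#' @return object of class `correlation_table`: list with matrices `r`,
#'   `p_value`, `stars` and the sample size `n`.
#' @export
correlation_table <- function(references,
                              properties = intersect(property_names(),
                                                     names(references))) {
  M <- as.matrix(references[, properties, drop = FALSE])
  n <- nrow(M)
  if (n < 3) stop("correlation_table: need at least 3 samples")
  sds <- apply(M, 2, stats::sd)
  if (any(sds < 1e-12)) {
    warning("correlation_table: constant property column(s): ",
            paste(properties[sds < 1e-12], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(M))
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  structure(list(r = r, p_value = p, stars = stars, n = n),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, digits = 3, ...) {
  cat(sprintf("<correlation_table> n = %d\n", x$n))
  disp <- matrix(paste0(format(round(x$r, digits)), x$stars),
                 nrow(x$r), dimnames = dimnames(x$r))
  print(disp, quote = FALSE)
  invisible(x)
}
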