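#' Run a preprocessing x property experiment grid
#'
#' The full modelling experiment: for every requested property and
#' preprocessing chain, split the samples into calibration and prediction
#' sets, fit the chain on the calibration spectra and replay its frozen
#' state on the prediction spectra, choose the latent-variable count by
#' leave-one-out cross-validation on the calibration set, fit the final
#' PLSR model and report R2c, RMSEC, R2p, RMSEP, RPD and the RPD grade.
#' The best chain per property (highest RPD, ties toward fewer LVs) is
#' flagged.
#'
#' @param dataset a `synthetic_dataset`, or a list with elements `spectra`
#'   (a [spectra_set()] whose metadata has `cut_type`, `carcass_id`, `day`)
#'   and `references` (data.frame `sample_id` + property columns).
#' @param chains character vector of preset names (see [chain_presets()])
#'   and/or a list of [preprocessing_chain()] objects.
#' @param properties properties to model (default: all six present).
#' @param split_method `"gradient"` (concentration gradient, per property)
#'   or `"carcass"` (whole-carcass hold-out, shared).
#' @param seed integer seed for the gradient split draws.
#' @param trim length-2 wavelength window applied before everything
#'   (default `c(400, 1000)`); `NULL` to skip.
#' @param max_components LV selection cap (default 15).
#' @param block_size gradient split block length (default 4).
#' @param schedule carcass hold-out schedule (default `c(2, 2, 1, 1, 1)`).
#' @param r2_method passed to [r_squared()].
#' @return object of class `experiment_report`: a data.frame with one row
#'   per property x chain (columns of [model_report()] plus `best` and
#'   `error`), with attributes `splits` (the split assignments used) and
#'   `models` (the best fitted model and chain state per property).
#' @export
run_experiment_grid <- function(dataset,
                                chains = chain_presets(),
                                properties = NULL,
                                split_method = c("gradient", "carcass"),
                                seed = 1,
                                trim = c(400, 1000),
                                max_components = 15,
                                block_size = 4,
                                schedule = c(2, 2, 1, 1, 1),
                                r2_method = "one_minus_sse_sst") {
  split_method <- match.arg(split_method)
  spectra <- dataset$spectra
  references <- dataset$references
  stopifnot(inherits(spectra, "spectra_set"), is.data.frame(references))
  if (is.null(properties)) {
    properties <- intersect(property_names(), names(references))
  }
  chain_list <- lapply(chains, function(ch) {
    if (is.character(ch)) chain_preset(ch) else ch
  })
  if (!is.null(trim)) spectra <- trim_wavelengths(spectra, trim[1], trim[2])

  shared_split <- if (split_method == "carcass") {
    carcass_split(spectra$metadata, schedule = schedule)
  } else NULL

  splits <- list()
  models <- list()
  rows <- list()
  for (prop in properties) {
    y_all <- references[[prop]][match(spectra$sample_ids,
                                      references$sample_id)]
    sp <- if (split_method == "gradient") {
      concentration_gradient_split(y_all, spectra$sample_ids, seed = seed,
                                   property_name = prop,
                                   block_size = block_size)
    } else shared_split
    splits[[prop]] <- sp
    cal <- subset_samples(spectra, sp$calibration_ids)
    prd <- subset_samples(spectra, sp$prediction_ids)
    y_cal <- references[[prop]][match(sp$calibration_ids,
                                      references$sample_id)]
    y_prd <- references[[prop]][match(sp$prediction_ids,
                                      references$sample_id)]
    best_row <- NULL
    for (ci in seq_along(chain_list)) {
      chain <- chain_list[[ci]]
      row <- tryCatch({
        fitted <- apply_chain(cal, chain)
        replayed <- apply_chain(prd, chain, state = fitted$state)
        Xc <- fitted$spectra$reflectance
        Xp <- replayed$spectra$reflectance
        cv <- select_components(Xc, y_cal, max_components)
        model <- fit_plsr(Xc, y_cal, cv$n_components, property_name = prop)
        out <- model_report(prop, chain$label, model$n_components,
                            y_cal, predict(model, Xc),
                            y_prd, predict(model, Xp),
                            r2_method = r2_method)
        out$error <- NA_character_
        attr(out, "model") <- model
        attr(out, "state") <- fitted$state
        attr(out, "chain") <- chain
        out
      }, error = function(e) {
        data.frame(property = prop, preprocessing = chain$label,
                   n_lv = NA_integer_, r2_c = NA_real_, rmsec = NA_real_,
                   r2_p = NA_real_, rmsep = NA_real_, rpd = NA_real_,
                   grade = NA_character_, error = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- row
      if (is.na(row$error) &&
          (is.null(best_row) || row$rpd > best_row$row$rpd ||
           (row$rpd == best_row$row$rpd && row$n_lv < best_row$row$n_lv))) {
        best_row <- list(row = row, model = attr(row, "model"),
                         state = attr(row, "state"),
                         chain = attr(row, "chain"))
      }
    }
    if (!is.null(best_row)) {
      models[[prop]] <- list(model = best_row$model, state = best_row$state,
                             chain = best_row$chain,
                             wavelengths = spectra$wavelengths,
                             split = sp)
    }
  }
  report <- do.call(rbind, lapply(rows, function(r) {
    attr(r, "model") <- attr(r, "state") <- attr(r, "chain") <- NULL
    r
  }))
  rownames(report) <- NULL
  report$best <- FALSE
  for (prop in properties) {
    ok <- which(report$property == prop & is.na(report$error))
    if (!length(ok)) next
    r <- report[ok, ]
    pick <- ok[order(-r$rpd, r$n_lv)[1]]
    report$best[pick] <- TRUE
  }
  structure(report, class = c("experiment_report", "data.frame"),
            splits = splits, models = models,
            split_method = split_method, seed = seed)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d rows (%s split)\n",
              nrow(x), attr(x, "split_method")))
  print(format_report(x))
  invisible(x)
}

#' Round and format a report the way such tables are printed
#'
#' Two decimals for all statistics; the best row per property marked.
#'
#' @param report an `experiment_report` (or compatible data.frame).
#' @return data.frame of formatted columns.
#' @export
format_report <- function(report) {
  df <- as.data.frame(report)
  num <- c("r2_c", "rmsec", "r2_p", "rmsep", "rpd")
  for (nm in num) df[[nm]] <- sprintf("%.2f", df[[nm]])
  df[df == "NA"] <- ""
  cols <- c("property", "preprocessing", "n_lv", num, "grade")
  if ("best" %in% names(df)) {
    df$preprocessing[df$best] <- paste0(df$preprocessing[df$best], " *")
  }
  df[, cols]
}

#' Write an experiment report as CSV and aligned text
#'
#' @param report an `experiment_report`.
#' @param csv_path,txt_path output paths (`NULL` to skip either).
#' @return invisible list of written paths.
#' @export
write_report <- function(report, csv_path = NULL, txt_path = NULL) {
  written <- list()
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
    written$csv <- csv_path
  }
  if (!is.null(txt_path)) {
    fmt <- format_report(report)
    widths <- pmax(nchar(names(fmt)), apply(fmt, 2, function(cl) max(nchar(cl))))
    line <- function(vals) paste(mapply(formatC, vals, width = widths,
                                        MoreArgs = list(flag = "-")),
                                 collapse = "  ")
    writeLines(c(line(names(fmt)), apply(fmt, 1, line)), txt_path)
    written$txt <- txt_path
  }
  invisible(written)
}
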