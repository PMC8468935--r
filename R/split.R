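#' Concentration-gradient calibration/prediction split
#'
#' Ranks samples by a reference property value (ties broken by sample id),
#' walks the ranked list in consecutive blocks of `block_size` (the final
#' block may be smaller) and draws exactly one sample per block, uniformly at
#' random, into the prediction set; the rest form the calibration set. With
#' `block_size = 4` this is the usual "1/3 principle" giving a roughly 3:1
#' calibration:prediction split whose prediction values track the full
#' concentration range. Performed independently per property.
#'
#' @param values numeric vector of per-sample reference values.
#' @param sample_ids character sample ids (defaults to names of `values` or
#'   `"S1"`, ...).
#' @param seed integer seed; the split is deterministic given
#'   (`values`, `sample_ids`, `seed`).
#' @param property_name label stored on the assignment.
#' @param block_size block length (default 4).
#' @return object of class `split_assignment`: list with `property_name`,
#'   `calibration_ids`, `prediction_ids`, `method`, `seed`.
#' @export
concentration_gradient_split <- function(values, sample_ids = NULL, seed = 1,
                                         property_name = "property",
                                         block_size = 4) {
  value_names <- names(values)
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("concentration_gradient_split: values must be finite")
  }
  n <- length(values)
  if (n < block_size) {
    stop(sprintf("concentration_gradient_split: need at least %d samples",
                 block_size))
  }
  if (is.null(sample_ids)) {
    sample_ids <- value_names
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  }
  stopifnot(length(sample_ids) == n, !anyDuplicated(sample_ids))
  ord <- order(values, sample_ids)
  blocks <- split(ord, ceiling(seq_len(n) / block_size))
  pred_idx <- with_rng_seed(seed, {
    vapply(blocks, function(b) b[sample.int(length(b), 1L)], integer(1))
  })
  structure(list(property_name = property_name,
                 calibration_ids = sample_ids[sort(setdiff(ord, pred_idx))],
                 prediction_ids = sample_ids[sort(pred_idx)],
                 method = "concentration_gradient",
                 seed = as.integer(seed)),
            class = "split_assignment")
}

#' Whole-carcass hold-out split
#'
#' Places every cut of the held-out carcasses in the prediction set and all
#' remaining samples in the calibration set (grouped validation: no carcass
#' contributes to both sets). By default the hold-out follows a per-day
#' schedule -- `c(2, 2, 1, 1, 1)` reproduces a 7-carcass hold-out over five
#' days -- taking the lowest carcass ids within each day; an explicit
#' `held_out_carcasses` vector overrides the schedule.
#'
#' @param metadata data.frame with columns `sample_id`, `carcass_id`, `day`.
#' @param schedule integer vector, carcasses to hold out per (sorted) day.
#' @param held_out_carcasses optional explicit carcass ids to hold out.
#' @return a `split_assignment` with `method = "carcass"` and
#'   `property_name = "all"`.
#' @export
carcass_split <- function(metadata, schedule = c(2, 2, 1, 1, 1),
                          held_out_carcasses = NULL) {
  need <- c("sample_id", "carcass_id", "day")
  if (!all(need %in% names(metadata))) {
    stop("carcass_split: metadata needs columns ", paste(need, collapse = ", "))
  }
  if (is.null(held_out_carcasses)) {
    days <- sort(unique(metadata$day))
    if (length(schedule) > length(days)) {
      stop(sprintf("carcass_split: schedule names %d days but metadata has %d",
                   length(schedule), length(days)))
    }
    held_out_carcasses <- unlist(lapply(seq_along(schedule), function(i) {
      ids <- sort(unique(metadata$carcass_id[metadata$day == days[i]]))
      if (schedule[i] > length(ids)) {
        stop(sprintf("carcass_split: day %s has only %d carcasses, schedule asks %d",
                     days[i], length(ids), schedule[i]))
      }
      ids[seq_len(schedule[i])]
    }))
  } else {
    unknown <- setdiff(held_out_carcasses, metadata$carcass_id)
    if (length(unknown)) {
      stop("carcass_split: unknown carcass id(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  pred <- metadata$carcass_id %in% held_out_carcasses
  if (!any(pred)) stop("carcass_split: prediction set would be empty")
  if (all(pred)) stop("carcass_split: calibration set would be empty")
  structure(list(property_name = "all",
                 calibration_ids = metadata$sample_id[!pred],
                 prediction_ids = metadata$sample_id[pred],
                 method = "carcass",
                 seed = NA_integer_),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment> %s (%s): %d calibration / %d prediction\n",
              x$method, x$property_name,
              length(x$calibration_ids), length(x$prediction_ids)))
  invisible(x)
}

#' Summary statistics of a calibration/prediction split
#'
#' Per subset and property: n, min--max range, mean, SD (n-1) and
#' CV% = 100 * SD / mean. For a singleton subset SD and CV are reported as
#' `NA`.
#'
#' @param split a `split_assignment`.
#' @param references data.frame with `sample_id` and property columns.
#' @param properties properties to summarize; defaults to the split's own
#'   property, or all six for a carcass split.
#' @return data.frame with columns `property`, `subset`, `n`, `min`, `max`,
#'   `mean`, `sd`, `cv`.
#' @export
split_summary <- function(split, references, properties = NULL) {
  stopifnot(inherits(split, "split_assignment"))
  if (is.null(properties)) {
    properties <- if (split$property_name %in% names(references)) {
      split$property_name
    } else {
      intersect(property_names(), names(references))
    }
  }
  ids <- list(calibration = split$calibration_ids,
              prediction = split$prediction_ids)
  missing_ids <- setdiff(unlist(ids), references$sample_id)
  if (length(missing_ids)) {
    stop("split_summary: ids not found in references: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  rows <- lapply(properties, function(p) {
    do.call(rbind, lapply(names(ids), function(sub) {
      v <- references[[p]][match(ids[[sub]], references$sample_id)]
      s <- if (length(v) > 1) stats::sd(v) else NA_real_
      m <- mean(v)
      data.frame(property = p, subset = sub, n = length(v),
                 min = min(v), max = max(v), mean = m, sd = s,
                 cv = if (is.na(s)) NA_real_ else cv_percent(s, m),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize / read split assignments as CSV
#'
#' Long format: one row per sample with columns `sample_id`, `property`,
#' `subset`, `method`, `seed`, allowing exact re-runs.
#'
#' @param splits a `split_assignment` or list of them.
#' @param path CSV path.
#' @return `write_splits_csv`: the path, invisibly. `read_splits_csv`: a
#'   named list of `split_assignment` objects.
#' @export
write_splits_csv <- function(splits, path) {
  if (inherits(splits, "split_assignment")) splits <- list(splits)
  rows <- do.call(rbind, lapply(splits, function(sp) {
    data.frame(
      sample_id = c(sp$calibration_ids, sp$prediction_ids),
      property = sp$property_name,
      subset = rep(c("calibration", "prediction"),
                   c(length(sp$calibration_ids), length(sp$prediction_ids))),
      method = sp$method, seed = sp$seed, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_splits_csv
#' @export
read_splits_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$property), function(d) {
    structure(list(property_name = d$property[1],
                   calibration_ids = d$sample_id[d$subset == "calibration"],
                   prediction_ids = d$sample_id[d$subset == "prediction"],
                   method = d$method[1],
                   seed = d$seed[1]),
              class = "split_assignment")
  })
  out
}
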