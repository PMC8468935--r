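#' Write / read a spectra set as CSV
#'
#' Layout: header row `sample_id` followed by the wavelengths in nm; one row
#' per sample. UTF-8, `.` decimal separator.
#'
#' @param s a [spectra_set()].
#' @param path CSV path.
#' @return `write_spectra_csv`: the path, invisibly; `read_spectra_csv`:
#'   a `spectra_set` (without metadata).
#' @export
write_spectra_csv <- function(s, path) {
  stopifnot(inherits(s, "spectra_set"))
  df <- data.frame(sample_id = s$sample_ids, s$reflectance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("sample_id", format_wavelength(s$wavelengths))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("read_spectra_csv: file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (names(df)[1] != "sample_id") {
    stop("read_spectra_csv: first column must be 'sample_id'")
  }
  lam <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(lam)) stop("read_spectra_csv: non-numeric wavelength header")
  if (length(lam) > 1 && any(diff(lam) <= 0)) {
    stop("read_spectra_csv: wavelength header must be strictly increasing")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)
    stop("read_spectra_csv: missing values in rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  spectra_set(lam, m, df$sample_id)
}

#' Write a synthetic dataset to a directory
#'
#' Writes `spectra.csv`, `metadata.csv` (`sample_id`, `cut_type`,
#' `carcass_id`, `day`), `references.csv` (`sample_id` + properties),
#' `concentrations.csv` (latent ground truth) and `manifest.json` (seed,
#' config hash, file list).
#'
#' @param dataset a `synthetic_dataset` (or compatible list).
#' @param dir output directory (created if needed).
#' @return invisible named vector of file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("write_dataset: cannot create directory ", dir)
  paths <- c(spectra = file.path(dir, "spectra.csv"),
             metadata = file.path(dir, "metadata.csv"),
             references = file.path(dir, "references.csv"))
  write_spectra_csv(dataset$spectra, paths["spectra"])
  utils::write.csv(dataset$spectra$metadata, paths["metadata"],
                   row.names = FALSE, fileEncoding = "UTF-8")
  refs <- dataset$references
  utils::write.csv(refs, paths["references"], row.names = FALSE,
                   fileEncoding = "UTF-8")
  if (!is.null(dataset$latent_concentrations)) {
    paths["concentrations"] <- file.path(dir, "concentrations.csv")
    conc <- data.frame(sample_id = rownames(dataset$latent_concentrations),
                       dataset$latent_concentrations, check.names = FALSE)
    utils::write.csv(conc, paths["concentrations"], row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  manifest <- list(
    seed = if (!is.null(dataset$config)) dataset$config$seed else NA,
    config_hash = if (!is.null(dataset$config)) config_hash(dataset$config)
                  else NA,
    n_samples = nrow(dataset$references),
    files = basename(unname(paths)))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths["manifest"] <- manifest_path
  invisible(paths)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' Validates the schema strictly: matching sample ids across the three
#' files, required metadata columns and a monotone wavelength header.
#'
#' @param dir directory containing `spectra.csv`, `metadata.csv`,
#'   `references.csv`.
#' @return list with `spectra` (a [spectra_set()] carrying the metadata)
#'   and `references`.
#' @export
read_dataset <- function(dir) {
  need <- file.path(dir, c("spectra.csv", "metadata.csv", "references.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("read_dataset: missing file(s): ", paste(missing, collapse = ", "))
  }
  s <- read_spectra_csv(need[1])
  meta <- utils::read.csv(need[2], stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  mcols <- c("sample_id", "cut_type", "carcass_id", "day")
  if (!all(mcols %in% names(meta))) {
    stop("read_dataset: metadata.csv needs columns ",
         paste(mcols, collapse = ", "))
  }
  refs <- utils::read.csv(need[3], stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (!"sample_id" %in% names(refs)) {
    stop("read_dataset: references.csv needs a sample_id column")
  }
  bad <- which(!s$sample_ids %in% meta$sample_id |
               !s$sample_ids %in% refs$sample_id)
  if (length(bad)) {
    stop("read_dataset: sample ids absent from metadata/references, rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  s <- spectra_set(s$wavelengths, s$reflectance, s$sample_ids,
                   meta[match(s$sample_ids, meta$sample_id), , drop = FALSE])
  list(spectra = s, references = refs)
}

#' Hash a configuration object
#'
#' MD5 of the canonical JSON serialization; stamped into manifests so mixed
#' provenance inputs can be detected.
#'
#' @param cfg any jsonlite-serializable list.
#' @return character MD5 hash.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE, dataframe = "columns")
  unname(tools::md5sum(tmp))
}

#' Serialize / load a fitted prediction model
#'
#' Plain-JSON schema holding everything needed to predict new spectra: the
#' wavelength grid, the preprocessing chain and its frozen state (MSC
#' reference), centering vectors, the regression coefficient vector and the
#' latent-variable count.
#'
#' @param bundle list with elements `model` (a `plsr_model`), `chain`,
#'   `state`, `wavelengths` — as stored per property in the `models`
#'   attribute of [run_experiment_grid()].
#' @param path JSON path.
#' @return `write_model`: path invisibly; `read_model`: the bundle.
#' @export
write_model <- function(bundle, path) {
  m <- bundle$model
  obj <- list(
    schema = "nirmeat-plsr-model/1",
    property = m$property_name,
    wavelengths = bundle$wavelengths,
    chain = list(label = bundle$chain$label, steps = bundle$chain$steps),
    state = bundle$state,
    x_mean = as.numeric(m$x_mean),
    x_scale = as.numeric(m$x_scale),
    y_mean = m$y_mean,
    coefficients = as.numeric(m$coefficients),
    n_components = m$n_components)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "nirmeat-plsr-model/1")) {
    stop("read_model: unrecognized model schema")
  }
  model <- structure(list(
    x_mean = obj$x_mean, x_scale = obj$x_scale, y_mean = obj$y_mean,
    weights = NULL, x_loadings = NULL, y_loadings = NULL, scores = NULL,
    coefficients = obj$coefficients,
    n_components = obj$n_components,
    property_name = obj$property), class = "plsr_model")
  steps <- obj$chain$steps
  if (is.data.frame(steps)) {
    steps <- lapply(seq_len(nrow(steps)), function(i) {
      as.list(steps[i, !is.na(steps[i, ]), drop = FALSE])
    })
  }
  chain <- preprocessing_chain(steps, label = obj$chain$label)
  state <- obj$state
  if (!is.null(state$steps) && is.data.frame(state$steps)) {
    state$steps <- apply(state$steps, 1, as.list)
  }
  if (!is.null(state$steps)) {
    # JSON drops NULL list slots; restore one slot per chain step
    steps_state <- vector("list", length(chain$steps))
    for (i in seq_along(state$steps)) {
      if (length(state$steps[[i]])) steps_state[[i]] <- state$steps[[i]]
    }
    state$steps <- steps_state
  }
  list(model = model, chain = chain, state = state,
       wavelengths = obj$wavelengths)
}

#' Read an experiment configuration file
#'
#' JSON mapping with (all optional) top-level keys: `generator` (fields of
#' [generator_config()]), `data_dir` (pre-existing dataset directory),
#' `trim` (two bounds), `chains`, `properties`, `split_method`, `seed`,
#' `max_components`, `out_dir`.
#'
#' @param path JSON config path.
#' @return named list of settings with defaults filled in.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(trim = c(400, 1000), chains = chain_presets(),
                   properties = property_names(),
                   split_method = "gradient", seed = 1L,
                   max_components = 15L, out_dir = ".")
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg
}
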