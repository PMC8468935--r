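#' Construct a spectra set
#'
#' A `spectra_set` bundles a wavelength grid, a samples-by-wavelengths
#' reflectance matrix and per-sample metadata. It is the X block of every
#' downstream operation: preprocessing chains transform it, splitters index
#' into it and PLSR models are fitted on its matrix.
#'
#' @param wavelengths numeric vector of wavelengths in nm, strictly increasing.
#' @param reflectance numeric matrix, one row per sample, one column per
#'   wavelength. Unitless reflectance (0--1 for physical spectra, but
#'   transformed sets may take any real values).
#' @param sample_ids character vector of unique sample labels; defaults to
#'   the rownames of `reflectance` or `"S1"`, `"S2"`, ...
#' @param metadata optional data.frame with one row per sample; if it has a
#'   `sample_id` column it is matched against `sample_ids`.
#'
#' @return An object of class `spectra_set`: a list with elements
#'   `wavelengths`, `reflectance` (rownames = sample ids), `sample_ids`,
#'   `metadata`.
#' @export
spectra_set <- function(wavelengths, reflectance, sample_ids = NULL,
                        metadata = NULL) {
  wavelengths <- as.numeric(wavelengths)
  if (!is.matrix(reflectance)) reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  if (anyNA(wavelengths) || anyNA(reflectance)) {
    stop("spectra_set: missing values are not allowed")
  }
  if (length(wavelengths) != ncol(reflectance)) {
    stop("spectra_set: length(wavelengths) must equal ncol(reflectance)")
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    stop("spectra_set: wavelengths must be strictly increasing")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(reflectance)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(reflectance)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(reflectance)) {
    stop("spectra_set: one sample_id per row of reflectance required")
  }
  if (anyDuplicated(sample_ids)) stop("spectra_set: sample_ids must be unique")
  rownames(reflectance) <- sample_ids
  colnames(reflectance) <- format_wavelength(wavelengths)
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (nrow(metadata) != length(sample_ids)) {
      stop("spectra_set: metadata must have one row per sample")
    }
    if ("sample_id" %in% names(metadata)) {
      if (!setequal(metadata$sample_id, sample_ids)) {
        stop("spectra_set: metadata sample_id does not match sample_ids")
      }
      metadata <- metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
      rownames(metadata) <- NULL
    } else {
      metadata$sample_id <- sample_ids
    }
  }
  structure(
    list(wavelengths = wavelengths, reflectance = reflectance,
         sample_ids = sample_ids, metadata = metadata),
    class = "spectra_set"
  )
}

format_wavelength <- function(w) {
  # stable, locale-independent column labels
  sub("\\.?0+$", "", formatC(w, format = "f", digits = 4))
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d wavelengths (%.1f-%.1f nm)\n",
              nrow(x$reflectance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  if (!is.null(x$metadata)) {
    extra <- setdiff(names(x$metadata), "sample_id")
    if (length(extra)) cat("  metadata:", paste(extra, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$reflectance)

#' Subset a spectra set by sample
#'
#' @param s a [spectra_set()].
#' @param ids character vector of sample ids (order preserved) or an
#'   integer/logical row index.
#' @return a `spectra_set` containing the requested samples.
#' @export
subset_samples <- function(s, ids) {
  stopifnot(inherits(s, "spectra_set"))
  if (is.character(ids)) {
    idx <- match(ids, s$sample_ids)
    if (anyNA(idx)) stop("subset_samples: unknown sample id(s): ",
                         paste(ids[is.na(idx)], collapse = ", "))
  } else {
    idx <- seq_along(s$sample_ids)[ids]
  }
  spectra_set(s$wavelengths, s$reflectance[idx, , drop = FALSE],
              s$sample_ids[idx],
              if (!is.null(s$metadata)) s$metadata[idx, , drop = FALSE])
}

#' Replace the reflectance matrix of a spectra set
#'
#' Internal helper used by preprocessing operators: keeps grid, ids and
#' metadata, swaps in a transformed matrix of identical shape.
#' @noRd
with_matrix <- function(s, m) {
  stopifnot(identical(dim(m), dim(s$reflectance)))
  s$reflectance <- m
  rownames(s$reflectance) <- s$sample_ids
  colnames(s$reflectance) <- format_wavelength(s$wavelengths)
  s
}

#' The six physicochemical property names used throughout the package
#'
#' `pH`, CIELAB lightness (`Lstar`), redness (`astar`), yellowness (`bstar`),
#' `cooking_loss` (percent mass lost on cooking) and `shear_force` (N).
#'
#' @return character vector of length 6.
#' @export
property_names <- function() {
  c("pH", "Lstar", "astar", "bstar", "cooking_loss", "shear_force")
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package operations never
#' disturb the caller's RNG stream.
#' @noRd
with_rng_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
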