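#' Construct a spectra set
#'
#' The central container of the package: a samples-by-wavelengths absorbance
#' matrix together with its wavelength grid (nm, strictly increasing), a
#' two-level class label per sample (`"A"` = acid-degraded, `"E"` =
#' enzyme-hydrolyzed) and an integer batch id per sample.
#'
#' @param absorbance Numeric matrix, samples in rows, wavelengths in columns.
#' @param wavelengths Numeric vector of wavelengths in nm, strictly increasing,
#'   one per column of `absorbance`.
#' @param labels Character vector of class labels, one per row, values in
#'   `c("A", "E")` (a single dummy class is also accepted for perturbation
#'   series used by 2D correlation analysis).
#' @param batch Integer vector of batch ids, one per row.
#' @param sample_ids Character vector of unique sample identifiers; generated
#'   as `s001`, `s002`, ... when omitted.
#'
#' @return An object of class `spectra_set` with elements `wavelength`
#'   (numeric), `absorbance` (matrix, rownames = sample ids) and `meta`
#'   (tibble with columns `sample_id`, `label`, `batch`).
#' @export
spectra_set <- function(absorbance, wavelengths, labels, batch,
                        sample_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  n <- nrow(absorbance)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(n))
  x <- structure(
    list(
      wavelength = as.numeric(wavelengths),
      absorbance = absorbance,
      meta = tibble::tibble(
        sample_id = as.character(sample_ids),
        label = as.character(labels),
        batch = as.integer(batch)
      )
    ),
    class = "spectra_set"
  )
  validate_spectra_set(x)
  rownames(x$absorbance) <- x$meta$sample_id
  colnames(x$absorbance) <- format_wavelength(x$wavelength)
  x
}

format_wavelength <- function(w) sprintf("%.6f", w)

validate_spectra_set <- function(x) {
  w <- x$wavelength
  if (length(w) < 1) stop("spectra_set: empty wavelength grid", call. = FALSE)
  if (any(!is.finite(w))) stop("spectra_set: non-finite wavelengths", call. = FALSE)
  if (length(w) > 1 && any(diff(w) <= 0)) {
    bad <- which(diff(w) <= 0)[1]
    stop(sprintf(
      "spectra_set: wavelengths must be strictly increasing (violated at column %d: %g >= %g)",
      bad, w[bad], w[bad + 1]
    ), call. = FALSE)
  }
  if (ncol(x$absorbance) != length(w)) {
    stop(sprintf(
      "spectra_set: %d absorbance columns but %d wavelengths",
      ncol(x$absorbance), length(w)
    ), call. = FALSE)
  }
  if (nrow(x$absorbance) != nrow(x$meta)) {
    stop("spectra_set: row count of absorbance does not match metadata", call. = FALSE)
  }
  if (anyDuplicated(x$meta$sample_id)) {
    stop("spectra_set: duplicated sample ids", call. = FALSE)
  }
  if (any(!is.finite(x$absorbance))) {
    bad <- which(!is.finite(x$absorbance), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "spectra_set: non-finite absorbance at row %d ('%s'), column %d",
      bad[1], x$meta$sample_id[bad[1]], bad[2]
    ), call. = FALSE)
  }
  if (any(is.na(x$meta$batch))) {
    stop("spectra_set: missing batch ids", call. = FALSE)
  }
  x
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf(
    "<spectra_set> %d samples x %d wavelengths (%.1f-%.1f nm)\n",
    n_samples(x), n_wavelengths(x), min(x$wavelength), max(x$wavelength)
  ))
  tab <- table(x$meta$label)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "| batches:", length(unique(x$meta$batch)), "\n")
  invisible(x)
}

#' Number of samples / wavelengths in a spectra set
#' @param x A `spectra_set`.
#' @return An integer.
#' @export
n_samples <- function(x) nrow(x$absorbance)

#' @rdname n_samples
#' @export
n_wavelengths <- function(x) length(x$wavelength)

#' Default instrument wavelength grid
#'
#' FT-NIR instruments acquire on a grid that is linear in wavenumber; the
#' default grid runs from 12800 down to 4000 cm^-1 sampled at exactly
#' `n_points` equally spaced wavenumbers and is returned in nm, ascending
#' (781.25 nm to 2500 nm).
#'
#' @param n_points Number of grid points (default 4148).
#' @return Numeric vector of wavelengths in nm, strictly increasing.
#' @export
default_grid <- function(n_points = 4148) {
  stopifnot(n_points >= 2)
  nu <- seq(12800, 4000, length.out = n_points)
  wavenumber_to_nm(nu)
}

#' Convert between wavelength (nm) and wavenumber (cm^-1)
#'
#' `nu = 1e7 / lambda`; the conversion is its own inverse.
#'
#' @param nm Wavelengths in nm.
#' @param wavenumber Wavenumbers in cm^-1.
#' @return Numeric vector.
#' @export
nm_to_wavenumber <- function(nm) 1e7 / nm

#' @rdname nm_to_wavenumber
#' @export
wavenumber_to_nm <- function(wavenumber) 1e7 / wavenumber

subset_samples <- function(x, idx) {
  spectra_set(
    x$absorbance[idx, , drop = FALSE], x$wavelength,
    x$meta$label[idx], x$meta$batch[idx], x$meta$sample_id[idx]
  )
}

#' Split a spectra set by batch membership
#'
#' Partitions samples into a training and a test set by batch id, the
#' batch-wise hold-out used throughout the package (e.g. batches 1-8 train,
#' batch 9 test for the default 9-batch design).
#'
#' @param data A `spectra_set`.
#' @param train_batches Integer vector of batch ids forming the training set.
#' @param test_batches Integer vector of batch ids forming the test set.
#' @return A list with elements `train` and `test`, both `spectra_set`s;
#'   within-set sample order is preserved.
#' @export
split_by_batch <- function(data, train_batches, test_batches) {
  train_batches <- as.integer(train_batches)
  test_batches <- as.integer(test_batches)
  if (length(test_batches) == 0 || length(train_batches) == 0) {
    stop("split_by_batch: train and test batch sets must both be non-empty", call. = FALSE)
  }
  if (length(intersect(train_batches, test_batches)) > 0) {
    stop("split_by_batch: overlapping batch ids: ",
         paste(intersect(train_batches, test_batches), collapse = ", "),
         call. = FALSE)
  }
  present <- unique(data$meta$batch)
  unknown <- setdiff(c(train_batches, test_batches), present)
  if (length(unknown) > 0) {
    stop("split_by_batch: unknown batch ids: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  uncovered <- setdiff(present, c(train_batches, test_batches))
  if (length(uncovered) > 0) {
    stop("split_by_batch: batches not assigned to either set: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  list(
    train = subset_samples(data, which(data$meta$batch %in% train_batches)),
    test = subset_samples(data, which(data$meta$batch %in% test_batches))
  )
}

#' Restrict a spectra set to a wavelength window
#'
#' Keeps the columns with wavelengths in the closed interval
#' `[lo_nm, hi_nm]`; rows are unchanged. The 1300-1600 nm window (first
#' overtone of the O-H stretch and of water hydrogen bonds) is the region of
#' interest for the 2D correlation and aquaphotomics stages.
#'
#' @param data A `spectra_set`.
#' @param lo_nm,hi_nm Window bounds in nm, `lo_nm < hi_nm`.
#' @return A `spectra_set` on the restricted grid.
#' @export
spc_window <- function(data, lo_nm, hi_nm) {
  if (!(lo_nm < hi_nm)) stop("spc_window: lo_nm must be < hi_nm", call. = FALSE)
  keep <- data$wavelength >= lo_nm & data$wavelength <= hi_nm
  if (!any(keep)) {
    stop(sprintf("spc_window: no grid points in [%g, %g] nm", lo_nm, hi_nm),
         call. = FALSE)
  }
  spectra_set(
    data$absorbance[, keep, drop = FALSE], data$wavelength[keep],
    data$meta$label, data$meta$batch, data$meta$sample_id
  )
}

#' Read a spectra set from CSV
#'
#' Expected dialect: UTF-8, comma separated, `.` decimal; first column
#' `sample_id`, second `label` (A or E), third `batch`, remaining columns
#' absorbance with the wavelength in nm as column header.
#'
#' @param path Path to a CSV file.
#' @return A validated `spectra_set`.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) {
    stop("read_spectra_csv: need sample_id, label, batch plus at least one wavelength column",
         call. = FALSE)
  }
  if (!identical(tolower(names(df)[1:3]), c("sample_id", "label", "batch"))) {
    stop("read_spectra_csv: first three columns must be sample_id, label, batch (got: ",
         paste(names(df)[1:3], collapse = ", "), ")", call. = FALSE)
  }
  wl_head <- names(df)[-(1:3)]
  wl <- suppressWarnings(as.numeric(wl_head))
  if (any(is.na(wl))) {
    bad <- wl_head[which(is.na(wl))[1]]
    stop(sprintf("read_spectra_csv: malformed wavelength header '%s'", bad),
         call. = FALSE)
  }
  labels <- as.character(df$label)
  known <- labels %in% c("A", "E")
  if (!all(known)) {
    stop(sprintf("read_spectra_csv: unknown label '%s' in data row %d",
                 labels[which(!known)[1]], which(!known)[1]), call. = FALSE)
  }
  mat <- as.matrix(df[, -(1:3), drop = FALSE])
  if (!is.numeric(mat)) {
    stop("read_spectra_csv: non-numeric absorbance values", call. = FALSE)
  }
  if (any(!is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("read_spectra_csv: missing/non-finite absorbance in data row %d, wavelength column '%s'",
                 bad[1], wl_head[bad[2]]), call. = FALSE)
  }
  spectra_set(mat, wl, labels, df$batch, df$sample_id)
}

#' Write a spectra set to CSV
#'
#' Writes the dialect accepted by [read_spectra_csv()] at full double
#' precision, so a write/read round trip is lossless.
#'
#' @param data A `spectra_set` with at least one sample.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(data, path) {
  if (n_samples(data) == 0) {
    stop("write_spectra_csv: refusing to write an empty sample set", call. = FALSE)
  }
  df <- tibble::as_tibble(data$meta)
  ab <- tibble::as_tibble(data$absorbance, .name_repair = "minimal")
  names(ab) <- format_wavelength(data$wavelength)
  readr::write_csv(dplyr::bind_cols(df, ab), path)
  invisible(path)
}

#' Tidy a spectra set into long format
#'
#' @param x A `spectra_set`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `label`, `batch`, `wavelength`,
#'   `absorbance`, one row per (sample, wavelength).
#' @importFrom generics tidy
#' @export
tidy.spectra_set <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(x$meta$sample_id, each = n_wavelengths(x)),
    label = rep(x$meta$label, each = n_wavelengths(x)),
    batch = rep(x$meta$batch, each = n_wavelengths(x)),
    wavelength = rep(x$wavelength, times = n_samples(x)),
    absorbance = as.vector(t(x$absorbance))
  )
}

#' @importFrom generics glance
#' @export
glance.spectra_set <- function(x, ...) {
  tibble::tibble(
    n_samples = n_samples(x),
    n_wavelengths = n_wavelengths(x),
    n_batches = length(unique(x$meta$batch)),
    n_class_a = sum(x$meta$label == "A"),
    n_class_e = sum(x$meta$label == "E"),
    lo_nm = min(x$wavelength),
    hi_nm = max(x$wavelength)
  )
}
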