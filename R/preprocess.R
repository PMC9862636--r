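#' Preprocessing configuration
#'
#' Fixed stage order: Savitzky-Golay smoothing, multiplicative scatter
#' correction, then global min-max normalization of the whole matrix. Window
#' and polynomial order default to 11 points / order 2, common NIR practice
#' that preserves the broad water bands.
#'
#' @param sg_window Odd SG window length in points (>= 3).
#' @param sg_polyorder SG polynomial order (< `sg_window`).
#' @param msc_reference `"mean_of_training"` or a numeric reference spectrum.
#' @param normalization `"global_minmax"` or `"none"`.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_window = 11, sg_polyorder = 2,
                              msc_reference = "mean_of_training",
                              normalization = c("global_minmax", "none")) {
  normalization <- match.arg(normalization)
  if (sg_window %% 2 == 0 || sg_window < 3) {
    stop("preprocess_config: sg_window must be odd and >= 3", call. = FALSE)
  }
  if (sg_polyorder >= sg_window) {
    stop("preprocess_config: sg_polyorder must be < sg_window", call. = FALSE)
  }
  structure(
    list(sg_window = as.integer(sg_window), sg_polyorder = as.integer(sg_polyorder),
         msc_reference = msc_reference, normalization = normalization),
    class = "preprocess_config"
  )
}

#' Savitzky-Golay smoothing of each spectrum
#'
#' Least-squares polynomial smoothing along the wavelength axis; exact on
#' polynomial rows up to the fitted order. Edges are filled by evaluating the
#' polynomial fitted on the first/last full window off-center, so the output
#' has the same shape as the input.
#'
#' @param data A `spectra_set`.
#' @param window Odd window length in points.
#' @param polyorder Polynomial order, `< window`.
#' @return A smoothed `spectra_set`.
#' @export
sg_smooth <- function(data, window = 11, polyorder = 2) {
  if (window %% 2 == 0) stop("sg_smooth: window must be odd", call. = FALSE)
  if (window < 3 || window > n_wavelengths(data)) {
    stop("sg_smooth: window must be in [3, n_wavelengths]", call. = FALSE)
  }
  if (polyorder >= window) stop("sg_smooth: polyorder must be < window", call. = FALSE)
  sm <- t(apply(data$absorbance, 1, signal::sgolayfilt, p = polyorder, n = window))
  spectra_set(sm, data$wavelength, data$meta$label, data$meta$batch,
              data$meta$sample_id)
}

msc_coefficients <- function(x, reference) {
  rc <- reference - mean(reference)
  a <- sum((x - mean(x)) * rc) / sum(rc^2)
  b <- mean(x) - a * mean(reference)
  c(a = a, b = b)
}

#' Multiplicative scatter correction
#'
#' Each spectrum `x` is regressed on the reference spectrum by ordinary least
#' squares, `x ~ a * r + b`, and corrected to `(x - b) / a`, removing
#' per-sample multiplicative and additive scatter.
#'
#' @param data A `spectra_set`.
#' @param reference Numeric reference spectrum of length `n_wavelengths(data)`;
#'   the mean spectrum of `data` when `NULL`.
#' @return A corrected `spectra_set`; the fitted per-sample coefficients are
#'   attached as attribute `"msc_coefficients"` (tibble `sample_id`, `a`, `b`).
#' @export
msc <- function(data, reference = NULL) {
  if (is.null(reference)) reference <- colMeans(data$absorbance)
  if (length(reference) != n_wavelengths(data)) {
    stop("msc: reference length does not match the grid", call. = FALSE)
  }
  if (stats::sd(reference) == 0) stop("msc: constant reference spectrum", call. = FALSE)
  co <- t(apply(data$absorbance, 1, msc_coefficients, reference = reference))
  small <- abs(co[, "a"]) < 1e-8
  if (any(small)) {
    stop("msc: degenerate spectrum (fitted slope below 1e-8) for sample ",
         data$meta$sample_id[which(small)[1]], call. = FALSE)
  }
  corrected <- (data$absorbance - co[, "b"]) / co[, "a"]
  out <- spectra_set(corrected, data$wavelength, data$meta$label,
                     data$meta$batch, data$meta$sample_id)
  attr(out, "msc_coefficients") <- tibble::tibble(
    sample_id = data$meta$sample_id,
    a = unname(co[, "a"]), b = unname(co[, "b"])
  )
  out
}

#' Global min-max normalization of a matrix
#'
#' `X' = (X - X_min) / (X_max - X_min)` with scalar extrema taken over the
#' whole matrix, so the matrix minimum maps to 0 and the maximum to 1. When
#' `x_min`/`x_max` are supplied (e.g. fitted on a training set) they are used
#' unchanged and outputs may fall outside \[0, 1\].
#'
#' @param x Numeric matrix.
#' @param x_min,x_max Optional fixed extrema.
#' @return Normalized matrix with attributes `x_min` and `x_max`.
#' @export
minmax_normalize <- function(x, x_min = NULL, x_max = NULL) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("minmax_normalize: non-finite input", call. = FALSE)
  if (is.null(x_min)) x_min <- min(x)
  if (is.null(x_max)) x_max <- max(x)
  if (x_max <= x_min) {
    stop("minmax_normalize: constant matrix (max == min); refusing silent zeros",
         call. = FALSE)
  }
  out <- (x - x_min) / (x_max - x_min)
  attr(out, "x_min") <- x_min
  attr(out, "x_max") <- x_max
  out
}

#' Train/test preprocessing pipeline without information leakage
#'
#' Applies Savitzky-Golay smoothing and multiplicative scatter correction to
#' both sets, then global min-max normalization; the MSC reference (the mean
#' training spectrum after smoothing) and the min/max scalars are fitted on
#' the training set only and applied unchanged to the test set. Test values
#' outside the training range therefore normalize outside \[0, 1\] and are kept.
#'
#' @param train,test `spectra_set`s on identical grids.
#' @param config A [preprocess_config()].
#' @return A list with `train`, `test` (preprocessed `spectra_set`s) and
#'   `params` (fitted reference and extrema, plus the config used).
#' @export
preprocess_pipeline <- function(train, test, config = preprocess_config()) {
  if (n_samples(train) == 0) stop("preprocess_pipeline: empty training set", call. = FALSE)
  if (!isTRUE(all.equal(train$wavelength, test$wavelength))) {
    stop("preprocess_pipeline: train and test grids differ", call. = FALSE)
  }
  tr <- sg_smooth(train, config$sg_window, config$sg_polyorder)
  te <- sg_smooth(test, config$sg_window, config$sg_polyorder)
  reference <- if (is.numeric(config$msc_reference)) {
    config$msc_reference
  } else {
    colMeans(tr$absorbance)
  }
  tr <- msc(tr, reference)
  te <- msc(te, reference)
  params <- list(msc_reference = reference, config = config,
                 x_min = NA_real_, x_max = NA_real_)
  if (config$normalization == "global_minmax") {
    ntr <- minmax_normalize(tr$absorbance)
    params$x_min <- attr(ntr, "x_min")
    params$x_max <- attr(ntr, "x_max")
    nte <- minmax_normalize(te$absorbance, params$x_min, params$x_max)
    tr <- spectra_set(ntr, tr$wavelength, tr$meta$label, tr$meta$batch, tr$meta$sample_id)
    te <- spectra_set(nte, te$wavelength, te$meta$label, te$meta$batch, te$meta$sample_id)
  }
  list(train = tr, test = te, params = params)
}
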