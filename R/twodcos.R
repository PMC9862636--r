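#' Hilbert-Noda transform matrix
#'
#' The antisymmetric matrix implementing the discrete Hilbert transform used
#' for asynchronous 2D correlation: `N[j, k] = 0` if `j == k`, else
#' `1 / (pi * (k - j))`.
#'
#' @param m Number of spectra in the perturbation series (>= 2).
#' @return An `m x m` matrix.
#' @export
hilbert_noda_matrix <- function(m) {
  if (m < 2) stop("hilbert_noda_matrix: m must be >= 2", call. = FALSE)
  k <- seq_len(m)
  d <- outer(k, k, function(j, k) k - j)
  n <- 1 / (pi * d)
  n[d == 0] <- 0
  n
}

#' Generalized 2D correlation spectra (synchronous and asynchronous)
#'
#' Mean-centers the perturbation series (dynamic spectra) and computes the
#' synchronous map `Phi = t(Xd) %*% Xd / (m - 1)` (a covariance matrix) and
#' the asynchronous map `Psi = t(Xd) %*% N %*% Xd / (m - 1)` through the
#' Hilbert-Noda transform. `Phi` is symmetric with non-negative diagonal
#' auto-peaks; `Psi` is antisymmetric with zero diagonal.
#'
#' @param series A `spectra_set` of at least 3 spectra ordered along the
#'   perturbation variable.
#' @param window_lo,window_hi Optional wavelength window in nm (closed).
#' @return An object of class `twodcos`: list with `wavelength`, `sync`,
#'   `async`, `n_perturbation`.
#' @export
compute_2dcos <- function(series, window_lo = NULL, window_hi = NULL) {
  if (n_samples(series) < 3) {
    stop("compute_2dcos: need at least 3 spectra in the perturbation series",
         call. = FALSE)
  }
  if (!is.null(window_lo) || !is.null(window_hi)) {
    series <- spc_window(series,
                         if (is.null(window_lo)) min(series$wavelength) else window_lo,
                         if (is.null(window_hi)) max(series$wavelength) else window_hi)
  }
  m <- n_samples(series)
  xd <- scale(series$absorbance, center = TRUE, scale = FALSE)
  sync <- crossprod(xd) / (m - 1)
  async <- t(xd) %*% hilbert_noda_matrix(m) %*% xd / (m - 1)
  structure(
    list(wavelength = series$wavelength,
         sync = unname(sync), async = unname(async),
         n_perturbation = m),
    class = "twodcos"
  )
}

#' @export
print.twodcos <- function(x, ...) {
  cat(sprintf("<twodcos> %d x %d maps (%.1f-%.1f nm), m = %d spectra\n",
              nrow(x$sync), ncol(x$sync), min(x$wavelength), max(x$wavelength),
              x$n_perturbation))
  invisible(x)
}

#' Auto-peak spectrum of a 2D correlation object
#'
#' The diagonal of the synchronous map: the variance-like sensitivity of each
#' wavelength to the perturbation. Always non-negative.
#'
#' @param corr A `twodcos` object.
#' @return A tibble with columns `wavelength`, `intensity`.
#' @export
auto_peaks <- function(corr) {
  tibble::tibble(wavelength = corr$wavelength, intensity = pmax(diag(corr$sync), 0))
}

#' Noda sequential-order verdict for a wavelength pair
#'
#' Reads the cross-peak signs at `(lambda1, lambda2)`: identical synchronous
#' and asynchronous signs mean the intensity change at `lambda1` occurs before
#' that at `lambda2`; opposite signs mean `lambda2` changes first. A sign
#' whose magnitude falls below `noise_floor * max(abs(sync))` is treated as
#' zero and the verdict is `"indeterminate"`.
#'
#' @param corr A `twodcos` object.
#' @param lambda1,lambda2 Wavelengths in nm; snapped to the nearest grid point.
#' @param noise_floor Relative magnitude floor for sign calls (default 1e-3).
#' @return A one-row tibble: `lambda1`, `lambda2` (snapped values),
#'   `sync_sign`, `async_sign`, `verdict`.
#' @export
sequential_order <- function(corr, lambda1, lambda2, noise_floor = 1e-3) {
  rng <- range(corr$wavelength)
  for (l in c(lambda1, lambda2)) {
    if (l < rng[1] - 1e-9 || l > rng[2] + 1e-9) {
      stop(sprintf("sequential_order: wavelength %g nm outside window [%g, %g]",
                   l, rng[1], rng[2]), call. = FALSE)
    }
  }
  i <- which.min(abs(corr$wavelength - lambda1))
  j <- which.min(abs(corr$wavelength - lambda2))
  floor_abs <- noise_floor * max(abs(corr$sync))
  sgn <- function(v) if (abs(v) <= floor_abs) 0L else as.integer(sign(v))
  s <- sgn(corr$sync[i, j])
  a <- sgn(corr$async[i, j])
  verdict <- if (s == 0L || a == 0L) {
    "indeterminate"
  } else if (s == a) {
    "lambda1_first"
  } else {
    "lambda2_first"
  }
  tibble::tibble(
    lambda1 = corr$wavelength[i], lambda2 = corr$wavelength[j],
    sync_sign = s, async_sign = a, verdict = verdict
  )
}

#' Tidy a 2D correlation object
#'
#' @param x A `twodcos` object.
#' @param ... Unused.
#' @return Long tibble with `lambda1`, `lambda2`, `sync`, `async`.
#' @export
tidy.twodcos <- function(x, ...) {
  n <- length(x$wavelength)
  tibble::tibble(
    lambda1 = rep(x$wavelength, times = n),
    lambda2 = rep(x$wavelength, each = n),
    sync = as.vector(x$sync),
    async = as.vector(x$async)
  )
}

#' Write the synchronous and asynchronous maps as CSV
#'
#' @param corr A `twodcos` object.
#' @param sync_path,async_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_2dcos_csv <- function(corr, sync_path, async_path) {
  wl <- format_wavelength(corr$wavelength)
  for (part in c("sync", "async")) {
    m <- corr[[part]]
    df <- tibble::as_tibble(m, .name_repair = "minimal")
    names(df) <- wl
    df <- dplyr::bind_cols(tibble::tibble(wavelength = wl), df)
    readr::write_csv(df, if (part == "sync") sync_path else async_path)
  }
  invisible(c(sync_path, async_path))
}
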