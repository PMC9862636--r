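#' Gaussian absorbance band specification
#'
#' @param center_nm Band center in nm.
#' @param width_nm Gaussian sigma in nm (> 0).
#' @param amplitude Peak absorbance (>= 0, absorbance units).
#' @return A one-row tibble describing the band.
#' @export
band_spec <- function(center_nm, width_nm, amplitude) {
  if (any(width_nm <= 0)) stop("band_spec: width_nm must be > 0", call. = FALSE)
  if (any(amplitude < 0)) stop("band_spec: amplitude must be >= 0", call. = FALSE)
  tibble::tibble(center_nm = center_nm, width_nm = width_nm, amplitude = amplitude)
}

band_profile <- function(wavelength, bands) {
  out <- numeric(length(wavelength))
  for (i in seq_len(nrow(bands))) {
    out <- out + bands$amplitude[i] *
      exp(-(wavelength - bands$center_nm[i])^2 / (2 * bands$width_nm[i]^2))
  }
  out
}

#' Configuration of the synthetic LMWHA spectrum generator
#'
#' Emulates the study design the analysis assumes: 9 batches of 10 aqueous
#' LMWHA solutions (5 acid-degraded "A" + 5 enzyme-hydrolyzed "E" per batch)
#' measured on the 4148-point FT-NIR grid, with water-dominated absorbance
#' (bands near 970, 1190, 1450 and 1940 nm, the 1940 nm combination band
#' strongest), a class-A excess band inside 1346-1375 nm, a class-E excess
#' band inside 1480-1513 nm, per-sample multiplicative scatter, a per-batch
#' low-order polynomial baseline, and additive white noise.
#'
#' @param n_batches Number of batches (default 9).
#' @param per_batch_per_class Samples per class per batch (default 5).
#' @param grid Wavelength grid in nm (default [default_grid()]).
#' @param base_bands Tibble of water bands ([band_spec()] rows).
#' @param class_delta_a,class_delta_e Class-specific excess bands.
#' @param delta_scale Dimensionless multiplier of the class bands. The default
#'   `1` puts classical linear classifiers near (not at) perfect accuracy;
#'   `regime = "separable"` sets `10`, a cleanly separable regime.
#' @param scatter_slope_sd,scatter_offset_sd Multiplicative-scatter slope and
#'   offset standard deviations (slope ~ 1 + N(0, sd)).
#' @param noise_sd Additive absorbance noise sd.
#' @param batch_shift_sd Sd of the coefficients of the shared per-batch
#'   quadratic baseline.
#' @param seed RNG seed.
#' @param regime `"default"` or `"separable"` (only changes `delta_scale`).
#' @return A list of class `lmwha_generator_config`.
#' @export
generator_config <- function(n_batches = 9,
                             per_batch_per_class = 5,
                             grid = default_grid(),
                             base_bands = band_spec(
                               center_nm = c(970, 1190, 1450, 1940),
                               width_nm = c(25, 35, 45, 60),
                               amplitude = c(0.10, 0.16, 0.85, 1.25)
                             ),
                             class_delta_a = band_spec(1360, 9, 8e-4),
                             class_delta_e = band_spec(1496, 10, 8e-4),
                             delta_scale = if (regime == "separable") 10 else 1,
                             scatter_slope_sd = 0.05,
                             scatter_offset_sd = 0.01,
                             noise_sd = 3e-3,
                             batch_shift_sd = 3e-3,
                             seed = 1,
                             regime = c("default", "separable")) {
  regime <- match.arg(regime)
  cfg <- list(
    n_batches = as.integer(n_batches),
    per_batch_per_class = as.integer(per_batch_per_class),
    grid = as.numeric(grid),
    base_bands = base_bands,
    class_delta_a = class_delta_a,
    class_delta_e = class_delta_e,
    delta_scale = delta_scale,
    scatter_slope_sd = scatter_slope_sd,
    scatter_offset_sd = scatter_offset_sd,
    noise_sd = noise_sd,
    batch_shift_sd = batch_shift_sd,
    seed = as.integer(seed),
    regime = regime
  )
  class(cfg) <- "lmwha_generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (cfg$per_batch_per_class < 1) {
    stop("generator_config: per_batch_per_class must be >= 1", call. = FALSE)
  }
  if (length(cfg$grid) < 2 || any(diff(cfg$grid) <= 0)) {
    stop("generator_config: degenerate wavelength grid", call. = FALSE)
  }
  sds <- c(cfg$scatter_slope_sd, cfg$scatter_offset_sd, cfg$noise_sd, cfg$batch_shift_sd)
  if (any(sds < 0)) stop("generator_config: sd parameters must be >= 0", call. = FALSE)
  if (cfg$delta_scale < 0) stop("generator_config: delta_scale must be >= 0", call. = FALSE)
  cfg
}

#' Noise-free class mean spectrum of the generator
#'
#' The deterministic part of the generator's closed form for one class,
#' excluding scatter, batch and noise terms. Used by tests as an analytic
#' reference.
#'
#' @param config A `lmwha_generator_config`.
#' @param label `"A"` or `"E"`.
#' @return Numeric vector over `config$grid`.
#' @export
generator_class_mean <- function(config, label) {
  delta <- if (label == "A") config$class_delta_a else config$class_delta_e
  band_profile(config$grid, config$base_bands) +
    config$delta_scale * band_profile(config$grid, delta)
}

#' Generate a synthetic two-class LMWHA spectra set
#'
#' Deterministic for a fixed `config$seed`. Per sample i of class c in batch b:
#' `a_i(lambda) = slope_i * (base(lambda) + delta_scale * delta_c(lambda) +
#' batch_b(lambda)) + offset_i + eps_i(lambda)`. Samples are laid out batch by
#' batch, the A samples of a batch before its E samples.
#'
#' @param config A [generator_config()].
#' @return A `spectra_set`.
#' @export
generate_lmwha_spectra <- function(config = generator_config()) {
  config <- validate_generator_config(config)
  withr::with_seed(config$seed, {
    wl <- config$grid
    p <- length(wl)
    per_batch <- 2L * config$per_batch_per_class
    n <- config$n_batches * per_batch
    base_a <- generator_class_mean(config, "A")
    base_e <- generator_class_mean(config, "E")
    u <- 2 * (wl - min(wl)) / (max(wl) - min(wl)) - 1
    labels <- character(n)
    batch <- integer(n)
    ab <- matrix(0, n, p)
    row <- 0L
    for (b in seq_len(config$n_batches)) {
      coef <- stats::rnorm(3, 0, config$batch_shift_sd)
      batch_baseline <- coef[1] + coef[2] * u + coef[3] * u^2
      for (lab in c("A", "E")) {
        cls <- if (lab == "A") base_a else base_e
        for (k in seq_len(config$per_batch_per_class)) {
          row <- row + 1L
          slope <- abs(1 + stats::rnorm(1, 0, config$scatter_slope_sd))
          offset <- stats::rnorm(1, 0, config$scatter_offset_sd)
          eps <- stats::rnorm(p, 0, config$noise_sd)
          ab[row, ] <- slope * (cls + batch_baseline) + offset + eps
          labels[row] <- lab
          batch[row] <- b
        }
      }
    }
    ids <- sprintf("b%02d_%s%d", batch, labels,
                   stats::ave(seq_len(n), batch, labels, FUN = seq_along))
    spectra_set(ab, wl, labels, batch, ids)
  })
}

#' Construct a sequential two-band perturbation series
#'
#' A fixture for 2D correlation spectroscopy: `n_spectra` spectra in which the
#' `lead_band` amplitude rises (sigmoidally in the spectrum index) earlier
#' than the `lag_band` amplitude, so the intensity change at the lead center
#' occurs before the change at the lag center and the Noda sign rules have a
#' known ground truth.
#'
#' @param n_spectra Number of spectra in the series (>= 4).
#' @param lead_band,lag_band One-row [band_spec()] tibbles with distinct
#'   centers inside `grid`.
#' @param grid Wavelength grid in nm.
#' @return A `spectra_set` with a single dummy class `"S"`.
#' @export
make_sequential_perturbation_series <- function(n_spectra,
                                                lead_band = band_spec(1350, 12, 1),
                                                lag_band = band_spec(1500, 12, 1),
                                                grid = seq(1300, 1600, by = 1)) {
  if (n_spectra < 4) stop("make_sequential_perturbation_series: need n_spectra >= 4", call. = FALSE)
  if (abs(lead_band$center_nm - lag_band$center_nm) < 1e-9) {
    stop("make_sequential_perturbation_series: coincident band centers make the order degenerate",
         call. = FALSE)
  }
  rng <- range(grid)
  if (lead_band$center_nm < rng[1] || lead_band$center_nm > rng[2] ||
      lag_band$center_nm < rng[1] || lag_band$center_nm > rng[2]) {
    stop("make_sequential_perturbation_series: band centers must lie inside the grid",
         call. = FALSE)
  }
  t <- seq(0, 1, length.out = n_spectra)
  amp_lead <- stats::plogis((t - 0.35) / 0.08)
  amp_lag <- stats::plogis((t - 0.65) / 0.08)
  g_lead <- band_profile(grid, lead_band)
  g_lag <- band_profile(grid, lag_band)
  ab <- outer(amp_lead, g_lead) + outer(amp_lag, g_lag)
  spectra_set(ab, grid, rep("S", n_spectra), rep(1L, n_spectra),
              sprintf("t%03d", seq_len(n_spectra)))
}
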