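#' Default water matrix coordinates (WAMACs)
#'
#' Twelve non-overlapping absorbance bands in the 1300-1600 nm first overtone
#' region of water, following the standard aquaphotomics C1-C12 coordinates
#' with endpoints adjusted so that the two class-diagnostic ranges of aqueous
#' LMWHA — 1346-1375 nm (acid-degraded) and 1480-1513 nm (enzyme-hydrolyzed)
#' — are fully covered. These are configurable literature defaults, not
#' instrument-calibrated values; override via [aquagram()]'s `bands` argument.
#'
#' @return A 12-row tibble with columns `label`, `lo_nm`, `hi_nm`,
#'   `assignment`, ordered and pairwise non-overlapping.
#' @export
default_wamacs <- function() {
  tibble::tibble(
    label = sprintf("C%d", 1:12),
    lo_nm = c(1336, 1346, 1361, 1380, 1398, 1421, 1432, 1448, 1458, 1470, 1480, 1516),
    hi_nm = c(1345, 1360.5, 1375, 1388, 1418, 1430, 1444, 1454, 1468, 1479, 1513, 1526),
    assignment = c(
      "nu3, H2O asymmetric stretch",
      "nu3 shoulder, water solvation shell OH-(H2O)1,2,4",
      "nu1 + nu3, asymmetric/symmetric stretch combination",
      "water solvation shell OH-(H2O)1,4",
      "free water and free OH (S0)",
      "water hydration band",
      "water molecules with one hydrogen bond (S1)",
      "water solvation shell OH-(H2O)4,5",
      "water molecules with two hydrogen bonds (S2)",
      "water molecules with three hydrogen bonds (S3)",
      "water molecules with four hydrogen bonds (S4)",
      "strongly bound water, nu1 + nu2 combination"
    )
  )
}

validate_wamacs <- function(bands) {
  stopifnot(all(c("label", "lo_nm", "hi_nm") %in% names(bands)))
  if (any(bands$lo_nm >= bands$hi_nm)) {
    stop("wamac bands: lo_nm must be < hi_nm", call. = FALSE)
  }
  if (any(bands$lo_nm < 1300) || any(bands$hi_nm > 1600)) {
    stop("wamac bands: bands must lie within 1300-1600 nm", call. = FALSE)
  }
  o <- order(bands$lo_nm)
  b <- bands[o, ]
  if (any(b$lo_nm[-1] <= b$hi_nm[-nrow(b)])) {
    stop("wamac bands: bands must be non-overlapping", call. = FALSE)
  }
  bands
}

#' Aquagram over WAMAC bands
#'
#' For each band, each sample's absorbance is averaged over the grid points in
#' the band's closed interval, the per-band values are standardized across all
#' samples (z-score), and the aquagram value of a class at a band is the mean
#' standardized value over that class's samples. Classes absorbing more at a
#' band than the overall mean get positive values; for two balanced classes
#' the values are antisymmetric across classes.
#'
#' @param data A preprocessed `spectra_set` with at least 2 samples per class.
#' @param bands A WAMAC band tibble (default [default_wamacs()]).
#' @return A tibble of class `aquagram` with columns `class`, `band_label`,
#'   `lo_nm`, `hi_nm`, `value`.
#' @export
aquagram <- function(data, bands = default_wamacs()) {
  bands <- validate_wamacs(bands)
  counts <- table(data$meta$label)
  if (any(counts < 2)) {
    stop("aquagram: every class needs at least 2 samples (got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), ")",
         call. = FALSE)
  }
  band_means <- vapply(seq_len(nrow(bands)), function(i) {
    keep <- data$wavelength >= bands$lo_nm[i] & data$wavelength <= bands$hi_nm[i]
    if (!any(keep)) {
      stop(sprintf("aquagram: band %s (%g-%g nm) contains no grid points",
                   bands$label[i], bands$lo_nm[i], bands$hi_nm[i]), call. = FALSE)
    }
    rowMeans(data$absorbance[, keep, drop = FALSE])
  }, numeric(n_samples(data)))
  sds <- apply(band_means, 2, stats::sd)
  if (any(sds == 0)) {
    stop("aquagram: zero standard deviation in band ",
         bands$label[which(sds == 0)[1]], call. = FALSE)
  }
  z <- scale(band_means)
  classes <- sort(unique(data$meta$label))
  out <- purrr::map_dfr(classes, function(cl) {
    tibble::tibble(
      class = cl,
      band_label = bands$label,
      lo_nm = bands$lo_nm,
      hi_nm = bands$hi_nm,
      value = colMeans(z[data$meta$label == cl, , drop = FALSE])
    )
  })
  class(out) <- c("aquagram", class(out))
  out
}

#' Write / read an aquagram as long-format CSV
#'
#' Header is exactly `class,band_label,lo_nm,hi_nm,value`, suitable for
#' external radar plotting; the round trip is lossless at double precision.
#'
#' @param ag An `aquagram`.
#' @param path File path.
#' @return `path` invisibly ([aquagram_to_csv()]) or an `aquagram`
#'   ([read_aquagram_csv()]).
#' @export
aquagram_to_csv <- function(ag, path) {
  stopifnot(inherits(ag, "aquagram"))
  readr::write_csv(ag[, c("class", "band_label", "lo_nm", "hi_nm", "value")], path)
  invisible(path)
}

#' @rdname aquagram_to_csv
#' @export
read_aquagram_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           class = readr::col_character(),
                           band_label = readr::col_character(),
                           lo_nm = readr::col_double(),
                           hi_nm = readr::col_double(),
                           value = readr::col_double()
                         ))
  class(out) <- c("aquagram", class(out))
  out
}
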