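plsda_engine <- function(x, y01, n_components) {
  mixOmics::pls(x, matrix(y01, ncol = 1), ncomp = n_components,
                mode = "regression", scale = FALSE)
}

plsda_predict_response <- function(fit, x, n_components) {
  p <- stats::predict(fit, x)$predict
  as.numeric(p[, 1, n_components])
}

#' Round a continuous PLS-DA response to a class label
#'
#' Response encoding A = 0, E = 1; rounding at 0.5, half-up (a response of
#' exactly 0.5 is assigned class E).
#'
#' @param response Numeric predicted responses.
#' @return Character vector of class labels.
#' @export
plsda_decision <- function(response) ifelse(response >= 0.5, "E", "A")

#' PLS-DA classifier with leave-one-out cross-validation
#'
#' Partial least squares regression of the dummy-coded class response
#' (A = 0, E = 1) on the spectra; continuous predictions are rounded at 0.5.
#' The training set is scored by leave-one-out cross-validation (`n_train`
#' independent refits, each holding out one sample); the test set by the
#' model fitted on the full training set.
#'
#' @param train Training `spectra_set` (both classes present).
#' @param test Optional test `spectra_set`.
#' @param n_components Number of latent components (default 10).
#' @param loocv Run leave-one-out cross-validation on the training set.
#' @return An object of class `plsda_fit` with elements `train`, `loocv`,
#'   `test` (per-sample tibbles: `sample_id`, `truth`, `response`, `pred`),
#'   `misclassified` (ids per split) and the fitted engine.
#' @export
plsda_fit <- function(train, test = NULL, n_components = 10, loocv = TRUE) {
  y <- label_factor(train$meta$label)
  if (length(unique(train$meta$label)) < 2) {
    stop("plsda_fit: single-class training set", call. = FALSE)
  }
  if (n_components > min(n_samples(train) - 1, n_wavelengths(train))) {
    stop("plsda_fit: n_components too large for the training set", call. = FALSE)
  }
  x <- feature_matrix(train)
  y01 <- as.numeric(y) - 1
  fit <- plsda_engine(x, y01, n_components)

  score_set <- function(mod, data) {
    resp <- plsda_predict_response(mod, feature_matrix(data), n_components)
    tibble::tibble(
      sample_id = data$meta$sample_id,
      truth = data$meta$label,
      response = resp,
      pred = plsda_decision(resp)
    )
  }

  train_tbl <- score_set(fit, train)
  loocv_tbl <- NULL
  if (loocv) {
    resp <- vapply(seq_len(nrow(x)), function(i) {
      mod_i <- plsda_engine(x[-i, , drop = FALSE], y01[-i], n_components)
      plsda_predict_response(mod_i, x[i, , drop = FALSE], n_components)
    }, numeric(1))
    loocv_tbl <- tibble::tibble(
      sample_id = train$meta$sample_id,
      truth = train$meta$label,
      response = resp,
      pred = plsda_decision(resp)
    )
  }
  test_tbl <- if (!is.null(test)) score_set(fit, test) else NULL

  structure(
    list(
      engine = fit, n_components = n_components,
      train = train_tbl, loocv = loocv_tbl, test = test_tbl,
      misclassified = list(
        loocv = if (!is.null(loocv_tbl)) loocv_tbl$sample_id[loocv_tbl$pred != loocv_tbl$truth],
        test = if (!is.null(test_tbl)) test_tbl$sample_id[test_tbl$pred != test_tbl$truth]
      )
    ),
    class = "plsda_fit"
  )
}

#' @export
print.plsda_fit <- function(x, ...) {
  cat(sprintf("<plsda_fit> %d components\n", x$n_components))
  if (!is.null(x$loocv)) {
    cat(sprintf("  LOOCV misclassified: %d of %d\n",
                length(x$misclassified$loocv), nrow(x$loocv)))
  }
  if (!is.null(x$test)) {
    cat(sprintf("  test misclassified: %d of %d\n",
                length(x$misclassified$test), nrow(x$test)))
  }
  invisible(x)
}

#' @export
tidy.plsda_fit <- function(x, ...) {
  dplyr::bind_rows(
    if (!is.null(x$loocv)) dplyr::mutate(x$loocv, split = "loocv"),
    dplyr::mutate(x$train, split = "train"),
    if (!is.null(x$test)) dplyr::mutate(x$test, split = "test")
  )
}

#' @export
glance.plsda_fit <- function(x, ...) {
  acc <- function(tbl) if (is.null(tbl)) NA_real_ else mean(tbl$pred == tbl$truth)
  tibble::tibble(
    n_components = x$n_components,
    train_accuracy = acc(x$train),
    loocv_accuracy = acc(x$loocv),
    test_accuracy = acc(x$test)
  )
}
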