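#' Random forest configuration
#'
#' @param n_trees Trees for the final (importance-bearing) forest.
#' @param sweep Tree counts for the out-of-bag sweep, default
#'   `seq(50, 1000, by = 50)`; `NULL` disables the sweep.
#' @param mtry Variables tried per split; default `floor(sqrt(n_features))`.
#' @param seed RNG seed.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 500, sweep = seq(50, 1000, by = 50),
                      mtry = NULL, seed = 1) {
  if (n_trees < 1) stop("rf_config: n_trees must be >= 1", call. = FALSE)
  structure(list(n_trees = as.integer(n_trees), sweep = sweep, mtry = mtry,
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Random forest classifier with OOB sweep and importances
#'
#' Bootstrap-bagged decision trees. In sweep mode a forest is grown at each
#' tree count and its out-of-bag error (and test accuracy, when a test set is
#' given) recorded — the tree-count diagnostic curves. Feature importances
#' (mean decrease in accuracy from OOB permutation, and mean decrease in
#' Gini) come from the final forest.
#'
#' @param train Training `spectra_set`.
#' @param test Optional test `spectra_set` for the sweep's accuracy curve.
#' @param config An [rf_config()].
#' @return An object of class `rf_fit`: `forest` (randomForest), `oob_curve`
#'   tibble (`n_trees`, `oob_error`, `test_accuracy`), `importances` tibble
#'   (`wavelength`, `mean_decrease_accuracy`, `mean_decrease_gini`), `config`.
#' @export
rf_fit <- function(train, test = NULL, config = rf_config()) {
  x <- feature_matrix(train)
  y <- label_factor(train$meta$label)
  mtry <- config$mtry %||% max(1, floor(sqrt(ncol(x))))
  grow <- function(nt, seed, importance = FALSE) {
    withr::with_seed(seed, {
      randomForest::randomForest(x, y, ntree = nt, mtry = mtry,
                                 importance = importance)
    })
  }
  oob_curve <- NULL
  if (!is.null(config$sweep)) {
    oob_curve <- purrr::map_dfr(config$sweep, function(nt) {
      f <- grow(nt, config$seed + nt)
      acc <- if (!is.null(test)) {
        mean(stats::predict(f, feature_matrix(test)) == test$meta$label)
      } else {
        NA_real_
      }
      tibble::tibble(n_trees = nt, oob_error = unname(f$err.rate[nt, "OOB"]),
                     test_accuracy = acc)
    })
  }
  forest <- grow(config$n_trees, config$seed, importance = TRUE)
  imp <- randomForest::importance(forest)
  importances <- tibble::tibble(
    wavelength = train$wavelength,
    mean_decrease_accuracy = unname(imp[, "MeanDecreaseAccuracy"]),
    mean_decrease_gini = unname(imp[, "MeanDecreaseGini"])
  )
  structure(
    list(forest = forest, oob_curve = oob_curve, importances = importances,
         config = config, mtry = mtry),
    class = "rf_fit"
  )
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("<rf_fit> %d trees, mtry=%d, OOB error=%.4f\n",
              x$config$n_trees, x$mtry,
              unname(x$forest$err.rate[x$config$n_trees, "OOB"])))
  if (!is.null(x$oob_curve)) {
    cat(sprintf("  sweep: %d tree counts, max OOB error %.4f\n",
                nrow(x$oob_curve), max(x$oob_curve$oob_error)))
  }
  invisible(x)
}

#' @export
tidy.rf_fit <- function(x, ...) x$importances

#' @export
glance.rf_fit <- function(x, ...) {
  tibble::tibble(
    n_trees = x$config$n_trees, mtry = x$mtry,
    oob_error = unname(x$forest$err.rate[x$config$n_trees, "OOB"]),
    max_sweep_oob_error = if (is.null(x$oob_curve)) NA_real_ else max(x$oob_curve$oob_error)
  )
}

#' Predict with a fitted random forest
#'
#' @param fit An `rf_fit`.
#' @param data A `spectra_set`.
#' @return Tibble `sample_id`, `truth`, `pred`, `score` (fraction of tree
#'   votes for class E, usable as a ROC score).
#' @export
predict_rf <- function(fit, data) {
  x <- feature_matrix(data)
  prob <- stats::predict(fit$forest, x, type = "prob")
  tibble::tibble(
    sample_id = data$meta$sample_id,
    truth = data$meta$label,
    pred = as.character(stats::predict(fit$forest, x)),
    score = unname(prob[, "E"])
  )
}
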