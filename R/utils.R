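#' @importFrom rlang %||% .data
#' @importFrom Rcpp sourceCpp
#' @useDynLib nirha, .registration = TRUE
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# stratified fold assignment, deterministic given seed
stratified_folds <- function(labels, k, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# features matrix with stable column names (models such as PLS require them)
feature_matrix <- function(data) {
  x <- data$absorbance
  colnames(x) <- paste0("w", seq_len(ncol(x)))
  x
}

label_factor <- function(labels) factor(labels, levels = c("A", "E"))
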