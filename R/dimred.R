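new_embedding <- function(data, coords, method, kernel = NULL,
                          explained_variance = NULL, loadings = NULL,
                          params = list()) {
  k <- ncol(coords)
  coord_tbl <- tibble::as_tibble(coords, .name_repair = "minimal")
  names(coord_tbl) <- paste0("dim", seq_len(k))
  structure(
    list(
      coords = dplyr::bind_cols(data$meta, coord_tbl),
      method = method, kernel = kernel,
      explained_variance = explained_variance,
      loadings = loadings, params = params
    ),
    class = "spc_embedding"
  )
}

#' @export
print.spc_embedding <- function(x, ...) {
  cat(sprintf("<spc_embedding> method=%s%s, k=%d, n=%d\n", x$method,
              if (!is.null(x$kernel)) paste0(" (", x$kernel, ")") else "",
              sum(grepl("^dim", names(x$coords))), nrow(x$coords)))
  invisible(x)
}

#' @export
tidy.spc_embedding <- function(x, ...) x$coords

#' @export
glance.spc_embedding <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    kernel = x$kernel %||% NA_character_,
    k = sum(grepl("^dim", names(x$coords))),
    n = nrow(x$coords),
    explained_variance_total = if (is.null(x$explained_variance)) NA_real_ else sum(x$explained_variance),
    kl_divergence = x$params$kl %||% NA_real_
  )
}

flip_signs <- function(scores, basis) {
  # sign convention: the largest-magnitude loading of each component positive
  for (j in seq_len(ncol(scores))) {
    lead <- basis[which.max(abs(basis[, j])), j]
    if (lead < 0) {
      scores[, j] <- -scores[, j]
      basis[, j] <- -basis[, j]
    }
  }
  list(scores = scores, basis = basis)
}

#' Principal component analysis of a spectra set
#'
#' Column-mean-centered PCA (no scaling). Besides the scores and per-component
#' explained-variance fractions, returns correlation loadings: the Pearson
#' correlation between each of the first two scores and the original
#' absorbance at every wavelength.
#'
#' @param data A `spectra_set`.
#' @param k Number of components (`<= min(n_samples - 1, n_wavelengths)`).
#' @return An `spc_embedding` with `explained_variance` and `loadings`.
#' @export
spc_pca <- function(data, k = 2) {
  n <- n_samples(data)
  if (k > min(n - 1, n_wavelengths(data))) {
    stop("spc_pca: k exceeds min(n_samples - 1, n_wavelengths)", call. = FALSE)
  }
  pc <- stats::prcomp(data$absorbance, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  fl <- flip_signs(pc$x[, seq_len(k), drop = FALSE],
                   pc$rotation[, seq_len(k), drop = FALSE])
  n_load <- min(2, k)
  loadings <- tibble::tibble(wavelength = data$wavelength)
  for (j in seq_len(n_load)) {
    sc <- fl$scores[, j]
    loadings[[paste0("PC", j)]] <- as.vector(
      stats::cor(sc, data$absorbance)
    )
  }
  new_embedding(data, fl$scores, "pca",
                explained_variance = ev[seq_len(k)],
                loadings = loadings,
                params = list(total_components = length(ev)))
}

median_heuristic <- function(x) {
  d <- stats::dist(x)
  stats::median(d[d > 0])
}

#' Kernel principal component analysis
#'
#' Builds the kernel matrix (Gaussian, polynomial, sigmoid or Laplacian),
#' double-centers it in feature space, eigendecomposes it and returns the
#' top-`k` component scores. Sigmoid kernels are not positive semi-definite;
#' negative eigenvalues are clipped to zero with a warning. Gaussian and
#' Laplacian widths default to the median pairwise-distance heuristic,
#' polynomial degree to 3 with offset 1, sigmoid scale to `1/n_wavelengths`.
#'
#' @param data A `spectra_set`.
#' @param kernel One of `"gaussian"`, `"polynomial"`, `"sigmoid"`, `"laplacian"`.
#' @param k Number of components.
#' @param params Optional kernel parameters: `width` (gaussian/laplacian),
#'   `degree`, `scale`, `offset` (polynomial/sigmoid).
#' @return An `spc_embedding`.
#' @export
spc_kpca <- function(data, kernel = c("gaussian", "polynomial", "sigmoid", "laplacian"),
                     k = 2, params = list()) {
  kernel <- match.arg(kernel)
  x <- data$absorbance
  n <- nrow(x)
  if (k > n - 1) stop("spc_kpca: k exceeds n_samples - 1", call. = FALSE)
  kern <- switch(kernel,
    gaussian = {
      w <- params$width %||% median_heuristic(x)
      if (w <= 0) stop("spc_kpca: width must be > 0", call. = FALSE)
      params$width <- w
      kernlab::rbfdot(sigma = 1 / (2 * w^2))
    },
    laplacian = {
      w <- params$width %||% median_heuristic(x)
      if (w <= 0) stop("spc_kpca: width must be > 0", call. = FALSE)
      params$width <- w
      kernlab::laplacedot(sigma = 1 / w)
    },
    polynomial = {
      params$degree <- params$degree %||% 3
      if (params$degree < 1) stop("spc_kpca: degree must be >= 1", call. = FALSE)
      params$scale <- params$scale %||% 1
      params$offset <- params$offset %||% 1
      kernlab::polydot(degree = params$degree, scale = params$scale,
                       offset = params$offset)
    },
    sigmoid = {
      params$scale <- params$scale %||% 1 / ncol(x)
      params$offset <- params$offset %||% 0
      kernlab::tanhdot(scale = params$scale, offset = params$offset)
    }
  )
  km <- kernlab::kernelMatrix(kern, x)@.Data
  one <- matrix(1 / n, n, n)
  kc <- km - one %*% km - km %*% one + one %*% km %*% one
  eg <- eigen((kc + t(kc)) / 2, symmetric = TRUE)
  ev <- eg$values
  if (any(ev < -1e-8 * max(abs(ev)))) {
    warning("spc_kpca: kernel matrix not positive semi-definite; clipping negative eigenvalues")
  }
  ev <- pmax(ev, 0)
  vec <- eg$vectors[, seq_len(k), drop = FALSE]
  scores <- vec %*% diag(sqrt(ev[seq_len(k)]), k)
  fl <- flip_signs(scores, vec)
  new_embedding(data, fl$scores, "kpca", kernel = kernel, params = params)
}

#' t-SNE embedding of a spectra set
#'
#' Exact t-distributed stochastic neighbor embedding with seeded
#' reproducibility; the final Kullback-Leibler divergence is reported in
#' `params$kl`.
#'
#' @param data A `spectra_set`.
#' @param k Embedding dimension, 2 or 3.
#' @param perplexity Target perplexity, `< (n_samples - 1) / 3`.
#' @param seed RNG seed.
#' @param max_iter Gradient-descent iterations (default 500).
#' @return An `spc_embedding`.
#' @export
spc_tsne <- function(data, k = 2, perplexity = 10, seed = 1, max_iter = 500) {
  if (!k %in% c(2, 3)) stop("spc_tsne: k must be 2 or 3", call. = FALSE)
  res <- .tsne(data$absorbance, dims = k, perplexity = perplexity,
               seed = seed, max_iter = max_iter)
  new_embedding(data, res$y, "tsne",
                params = list(perplexity = perplexity, seed = seed,
                              max_iter = max_iter, kl = res$kl))
}
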