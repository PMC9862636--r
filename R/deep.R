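#' Architecture of the seven-layer 1D CNN
#'
#' Layer order: input, 1D convolution along the wavelength axis, ReLU,
#' max-pooling, fully connected, softmax, output. The fully connected stage
#' has a hidden width of `fc_width` (with a ReLU) followed by the 2-unit
#' output map.
#'
#' @param n_filters Convolution filters (default 8).
#' @param kernel_length Convolution kernel length in grid points (default 32).
#' @param pool_length Max-pooling window/stride (default 4, >= 2).
#' @param fc_width Hidden fully-connected width (default 32).
#' @return A list of class `cnn7_spec`.
#' @export
cnn7_spec <- function(n_filters = 8, kernel_length = 32, pool_length = 4,
                      fc_width = 32) {
  if (pool_length < 2) stop("cnn7_spec: pool_length must be >= 2", call. = FALSE)
  structure(list(n_filters = as.integer(n_filters),
                 kernel_length = as.integer(kernel_length),
                 pool_length = as.integer(pool_length),
                 fc_width = as.integer(fc_width)),
            class = "cnn7_spec")
}

#' Architecture of the LSTM spectral classifier
#'
#' The spectrum is consumed as an ordered sequence of `n_steps` chunks of
#' `n_features / n_steps` consecutive wavelength readings; a single LSTM
#' layer feeds a dropout-regularized fully-connected softmax head.
#'
#' @param hidden_units LSTM state size (default 64).
#' @param dropout Dropout probability on the final hidden state during
#'   training, in \[0, 1) (default 0.5).
#' @param n_steps Sequence length the spectrum is chunked into; must divide
#'   the feature count (default 4, i.e. 4 x 1037 = 4148: longer sequences
#'   let the recurrence accumulate inter-batch baseline drift and lose
#'   held-out-batch accuracy).
#' @param readout `"last"` (final hidden state feeds the head) or `"mean"`
#'   (temporal mean of the hidden states; exposed for experimentation --
#'   on batch-shifted spectra the last-state readout generalizes better).
#' @return A list of class `lstm_spec`.
#' @export
lstm_spec <- function(hidden_units = 64, dropout = 0.5, n_steps = 4,
                      readout = c("last", "mean")) {
  readout <- match.arg(readout)
  if (dropout < 0 || dropout >= 1) stop("lstm_spec: dropout must be in [0, 1)", call. = FALSE)
  structure(list(hidden_units = as.integer(hidden_units),
                 dropout = dropout, n_steps = as.integer(n_steps),
                 readout = readout),
            class = "lstm_spec")
}

#' Training configuration for the deep classifiers
#'
#' @param epochs Training epochs (>= 1, default 150).
#' @param batch_size Mini-batch size (default 16).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param optimizer Only `"adam"` is implemented (with decoupled weight
#'   decay).
#' @param weight_decay Decoupled L2 weight decay applied to weight matrices
#'   (not biases) at each update (default 1e-3).
#' @param validation_fraction Fraction of training samples held out as a
#'   stratified internal validation set (default 0.2).
#' @param seed RNG seed covering initialization, the validation split, batch
#'   shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 150, batch_size = 16, learning_rate = 1e-3,
                         optimizer = "adam", weight_decay = 1e-3,
                         validation_fraction = 0.2, seed = 1) {
  if (epochs < 1) stop("train_config: epochs must be >= 1", call. = FALSE)
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("train_config: validation_fraction must be in (0, 1)", call. = FALSE)
  }
  if (!identical(optimizer, "adam")) {
    stop("train_config: only the adam optimizer is implemented", call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 weight_decay = weight_decay,
                 validation_fraction = validation_fraction, seed = as.integer(seed)),
            class = "train_config")
}

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build the seven-layer 1D CNN
#'
#' @param spec A [cnn7_spec()].
#' @param n_features Spectrum length (must exceed `kernel_length`).
#' @param seed Initialization seed.
#' @return An object of class `cnn7_model` with seeded Glorot-uniform weights
#'   and zero biases.
#' @export
build_cnn7 <- function(spec, n_features, seed = 1) {
  if (spec$kernel_length >= n_features) {
    stop("build_cnn7: kernel_length must be < n_features", call. = FALSE)
  }
  p_conv <- n_features - spec$kernel_length + 1
  p_pool <- p_conv %/% spec$pool_length
  if (p_pool < 1) stop("build_cnn7: pooling leaves no positions", call. = FALSE)
  flat <- p_pool * spec$n_filters
  params <- withr::with_seed(seed, list(
    Wc = glorot(spec$kernel_length, spec$n_filters,
                spec$kernel_length, spec$n_filters),
    bc = numeric(spec$n_filters),
    W1 = glorot(flat, spec$fc_width, flat, spec$fc_width),
    b1 = numeric(spec$fc_width),
    W2 = glorot(spec$fc_width, 2, spec$fc_width, 2),
    b2 = numeric(2)
  ))
  structure(list(kind = "cnn7", spec = spec, n_features = as.integer(n_features),
                 p_conv = p_conv, p_pool = p_pool, params = params,
                 input_center = NULL, input_scale = NULL),
            class = c("cnn7_model", "deep_model"))
}

#' Parameter count of the seven-layer CNN
#'
#' Sum of the per-layer parameter formulas: convolution
#' `kernel_length * n_filters + n_filters`, hidden FC
#' `flat * fc_width + fc_width` with `flat = floor((n_features -
#' kernel_length + 1) / pool_length) * n_filters`, output map
#' `fc_width * 2 + 2`.
#'
#' @param spec A [cnn7_spec()].
#' @param n_features Spectrum length.
#' @return Integer parameter count.
#' @export
cnn7_n_params <- function(spec, n_features) {
  p_pool <- (n_features - spec$kernel_length + 1) %/% spec$pool_length
  flat <- p_pool * spec$n_filters
  spec$kernel_length * spec$n_filters + spec$n_filters +
    flat * spec$fc_width + spec$fc_width +
    spec$fc_width * 2 + 2
}

#' Build the LSTM spectral classifier
#'
#' @param spec An [lstm_spec()].
#' @param n_features Spectrum length; must be divisible by `spec$n_steps`.
#' @param seed Initialization seed.
#' @return An object of class `lstm_model`. The forget-gate bias is
#'   initialized to 1.
#' @export
build_lstm <- function(spec, n_features, seed = 1) {
  if (n_features %% spec$n_steps != 0) {
    stop(sprintf(
      "build_lstm: n_features (%d) must be divisible by n_steps (%d)",
      n_features, spec$n_steps), call. = FALSE)
  }
  d <- n_features %/% spec$n_steps
  h <- spec$hidden_units
  params <- withr::with_seed(seed, {
    b <- numeric(4 * h)
    b[(h + 1):(2 * h)] <- 1  # forget gate bias
    list(
      Wx = glorot(d, 4 * h, d, h),
      Wh = glorot(h, 4 * h, h, h),
      b = b,
      Wy = glorot(h, 2, h, 2),
      by = numeric(2)
    )
  })
  structure(list(kind = "lstm", spec = spec, n_features = as.integer(n_features),
                 d = d, params = params,
                 input_center = NULL, input_scale = NULL),
            class = c("lstm_model", "deep_model"))
}

# input-layer zero-center normalization, fitted on the training subset at
# the start of training; spectra share a large water background whose removal
# is what lets the small class signal drive the gradients
apply_input_norm <- function(model, x) {
  if (is.null(model$input_center)) return(x)
  sweep(x, 2, model$input_center) / model$input_scale
}

model_forward <- function(model, x) {
  x <- apply_input_norm(model, x)
  p <- model$params
  if (model$kind == "cnn7") {
    cnn_forward_cpp(x, p$Wc, p$bc, p$W1, p$b1, p$W2, p$b2,
                    model$spec$pool_length)
  } else {
    lstm_forward_cpp(x, model$spec$n_steps, model$d, p$Wx, p$Wh, p$b,
                     p$Wy, p$by, identical(model$spec$readout, "mean"))
  }
}

model_batch <- function(model, x, y, dropmask = NULL) {
  x <- apply_input_norm(model, x)
  p <- model$params
  if (model$kind == "cnn7") {
    r <- cnn_batch_cpp(x, y, p$Wc, p$bc, p$W1, p$b1, p$W2, p$b2,
                       model$spec$pool_length)
    r$grads <- list(Wc = r$gWc, bc = as.numeric(r$gbc),
                    W1 = r$gW1, b1 = as.numeric(r$gb1),
                    W2 = r$gW2, b2 = as.numeric(r$gb2))
  } else {
    r <- lstm_batch_cpp(x, y, model$spec$n_steps, model$d, p$Wx, p$Wh, p$b,
                        p$Wy, p$by, dropmask,
                        identical(model$spec$readout, "mean"))
    r$grads <- list(Wx = r$gWx, Wh = r$gWh, b = as.numeric(r$gb),
                    Wy = r$gWy, by = as.numeric(r$gby))
  }
  r
}

one_hot <- function(labels) {
  y <- label_factor(labels)
  cbind(A = as.numeric(y == "A"), E = as.numeric(y == "E"))
}

eval_loss_acc <- function(model, x, labels) {
  probs <- model_forward(model, x)
  y <- one_hot(labels)
  loss <- -mean(log(rowSums(probs * y) + 1e-12))
  acc <- mean(c("A", "E")[max.col(probs, ties.method = "first")] == labels)
  c(loss = loss, acc = acc)
}

#' Train a deep spectral classifier
#'
#' Minimizes the cross-entropy with Adam on mini-batches; a stratified
#' `validation_fraction` of the training samples is held out internally and
#' both train and validation loss/accuracy are recorded per epoch. Fully
#' reproducible for a fixed `config$seed` on a single-threaded BLAS.
#' Features are expected normalized to roughly \[0, 1\] upstream.
#'
#' @param model A [build_cnn7()] or [build_lstm()] model.
#' @param train Training `spectra_set` with binary labels.
#' @param config A [train_config()].
#' @return An object of class `deep_fit`: trained `model`, per-epoch
#'   `history` tibble (`epoch`, `train_loss`, `val_loss`, `train_acc`,
#'   `val_acc`), the config and the held-out validation sample ids.
#' @export
train_model <- function(model, train, config = train_config()) {
  stopifnot(inherits(model, "deep_model"))
  if (model$n_features != n_wavelengths(train)) {
    stop("train_model: model feature length does not match the data grid", call. = FALSE)
  }
  x_all <- unname(train$absorbance)
  labels <- train$meta$label
  h <- if (model$kind == "lstm") model$spec$hidden_units else NULL
  withr::with_seed(config$seed, {
    val_idx <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_val <- max(1, round(length(idx) * config$validation_fraction))
      val_idx <- c(val_idx, sample(idx, n_val))
    }
    fit_idx <- setdiff(seq_along(labels), val_idx)
    x_fit <- x_all[fit_idx, , drop = FALSE]
    if (is.null(model$input_center)) {
      model$input_center <- colMeans(x_fit)
      centered_sd <- stats::sd(sweep(x_fit, 2, model$input_center))
      model$input_scale <- max(centered_sd, 1e-12)
    }
    lab_fit <- labels[fit_idx]
    x_val <- x_all[val_idx, , drop = FALSE]
    lab_val <- labels[val_idx]

    adam <- list(m = purrr::map(model$params, ~ .x * 0),
                 v = purrr::map(model$params, ~ .x * 0), t = 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    history <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(length(fit_idx))
      starts <- seq(1, length(ord), by = config$batch_size)
      for (s in starts) {
        rows <- ord[s:min(s + config$batch_size - 1, length(ord))]
        xb <- x_fit[rows, , drop = FALSE]
        yb <- one_hot(lab_fit[rows])
        dropmask <- NULL
        if (model$kind == "lstm") {
          keep <- model$spec$dropout < 1
          dropmask <- matrix(
            (stats::runif(nrow(xb) * h) >= model$spec$dropout) /
              (1 - model$spec$dropout),
            nrow(xb), h)
        }
        res <- model_batch(model, xb, yb, dropmask)
        if (!is.finite(res$loss)) {
          stop(sprintf(
            "train_model: non-finite loss at epoch %d (exploding learning rate?)",
            epoch), call. = FALSE)
        }
        adam$t <- adam$t + 1
        for (nm in names(model$params)) {
          g <- res$grads[[nm]]
          adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * g
          adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * g^2
          mhat <- adam$m[[nm]] / (1 - b1^adam$t)
          vhat <- adam$v[[nm]] / (1 - b2^adam$t)
          decay <- if (is.matrix(model$params[[nm]])) config$weight_decay else 0
          model$params[[nm]] <- model$params[[nm]] -
            config$learning_rate * (mhat / (sqrt(vhat) + eps) +
                                    decay * model$params[[nm]])
        }
      }
      tr <- eval_loss_acc(model, x_fit, lab_fit)
      va <- eval_loss_acc(model, x_val, lab_val)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch,
        train_loss = unname(tr["loss"]), val_loss = unname(va["loss"]),
        train_acc = unname(tr["acc"]), val_acc = unname(va["acc"])
      )
    }
    structure(
      list(model = model, history = dplyr::bind_rows(history),
           config = config,
           validation_ids = train$meta$sample_id[val_idx]),
      class = "deep_fit"
    )
  })
}

#' @export
print.deep_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<deep_fit> %s, %d epochs; final train acc %.3f, val acc %.3f\n",
              x$model$kind, nrow(x$history), last$train_acc, last$val_acc))
  invisible(x)
}

#' @export
tidy.deep_fit <- function(x, ...) x$history

#' @export
glance.deep_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    kind = x$model$kind, epochs = nrow(x$history),
    train_loss = last$train_loss, val_loss = last$val_loss,
    train_acc = last$train_acc, val_acc = last$val_acc
  )
}

#' Evaluate a deep classifier on a spectra set
#'
#' Deterministic forward pass (dropout off); class is the arg-max
#' probability.
#'
#' @param model A `deep_fit`, `cnn7_model` or `lstm_model`.
#' @param data A `spectra_set` on the training grid.
#' @return Tibble `sample_id`, `truth`, `pred`, `prob_a`, `prob_e`, `score`
#'   (`prob_e`, usable for ROC).
#' @export
evaluate_deep <- function(model, data) {
  if (inherits(model, "deep_fit")) model <- model$model
  if (model$n_features != n_wavelengths(data)) {
    stop("evaluate_deep: feature-length mismatch with the model", call. = FALSE)
  }
  probs <- model_forward(model, unname(data$absorbance))
  tibble::tibble(
    sample_id = data$meta$sample_id,
    truth = data$meta$label,
    pred = c("A", "E")[max.col(probs, ties.method = "first")],
    prob_a = probs[, 1], prob_e = probs[, 2],
    score = probs[, 2]
  )
}
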