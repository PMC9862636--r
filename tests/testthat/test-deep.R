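# compact deep-learning fixtures: a 120-point grid in the separable regime
deep_sets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      # class bands widened so the coarse 120-point fixture grid resolves them
      d <- generate_lmwha_spectra(quick_config(
        n_points = 120, seed = 51, regime = "separable",
        class_delta_a = band_spec(1360, 20, 8e-4),
        class_delta_e = band_spec(1496, 20, 8e-4)
      ))
      sp <- split_by_batch(d, 1:8, 9)
      cache <<- preprocess_pipeline(sp$train, sp$test)
    }
    cache
  }
})

test_that("softmax probabilities are valid and zero input is class-symmetric", {
  m <- build_cnn7(cnn7_spec(n_filters = 4, kernel_length = 8, pool_length = 2,
                            fc_width = 8), 120, seed = 1)
  withr::with_seed(1, x <- matrix(runif(5 * 120), 5))
  probs <- nirha:::model_forward(m, x)
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-6)
  expect_true(all(probs >= 0))
  # zero input with zero biases: both classes exactly 0.5
  p0 <- nirha:::model_forward(m, matrix(0, 2, 120))
  expect_equal(as.numeric(p0), rep(0.5, 4))
})

test_that("CNN parameter count equals the layer arithmetic", {
  spec <- cnn7_spec(n_filters = 8, kernel_length = 32, pool_length = 4,
                    fc_width = 32)
  m <- build_cnn7(spec, 4148, seed = 1)
  counted <- sum(vapply(m$params, length, integer(1)))
  # conv: 32*8+8; fc: (1029*8)*32+32; out: 32*2+2
  expect_equal(cnn7_n_params(spec, 4148),
               32 * 8 + 8 + (1029 * 8) * 32 + 32 + 32 * 2 + 2)
  expect_equal(counted, cnn7_n_params(spec, 4148))
  expect_error(build_cnn7(cnn7_spec(kernel_length = 200), 120), "kernel_length")
  expect_error(build_lstm(lstm_spec(n_steps = 7), 120), "divisible")
})

test_that("analytic gradients match finite differences on a tiny model", {
  withr::with_seed(52, {
    x <- matrix(runif(3 * 24), 3)
    yl <- c("A", "E", "A")
  })
  y <- nirha:::one_hot(yl)
  for (kind in c("cnn7", "lstm")) {
    m <- if (kind == "cnn7") {
      build_cnn7(cnn7_spec(n_filters = 2, kernel_length = 5, pool_length = 2,
                           fc_width = 4), 24, seed = 3)
    } else {
      build_lstm(lstm_spec(hidden_units = 5, dropout = 0, n_steps = 4), 24,
                 seed = 3)
    }
    mask <- matrix(1, 3, if (kind == "lstm") 5 else 0)
    res <- nirha:::model_batch(m, x, y, mask)
    eps <- 1e-6
    for (nm in names(m$params)) {
      pick <- if (length(m$params[[nm]]) > 6) c(1, 3, 6) else 1
      for (i in pick) {
        up <- m; up$params[[nm]][i] <- up$params[[nm]][i] + eps
        dn <- m; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
        lu <- nirha:::model_batch(up, x, y, mask)$loss
        ld <- nirha:::model_batch(dn, x, y, mask)$loss
        expect_equal(res$grads[[nm]][i], (lu - ld) / (2 * eps),
                     tolerance = 1e-4)
      }
    }
  }
})

test_that("zero learning rate freezes the model and history", {
  pr <- deep_sets()
  m <- build_cnn7(cnn7_spec(n_filters = 2, kernel_length = 8, pool_length = 2,
                            fc_width = 4), 120, seed = 2)
  fit <- train_model(m, pr$train,
                     train_config(epochs = 4, learning_rate = 0, seed = 5))
  expect_equal(length(unique(fit$history$train_acc)), 1)
  expect_equal(length(unique(fit$history$train_loss)), 1)
  expect_equal(fit$model$params$Wc, m$params$Wc)
})

test_that("training histories are finite and improve over the first epoch", {
  pr <- deep_sets()
  for (s in 1:3) {
    m <- build_lstm(lstm_spec(hidden_units = 16, n_steps = 4), 120, seed = s)
    fit <- train_model(m, pr$train, train_config(epochs = 12, seed = s))
    expect_true(all(is.finite(fit$history$train_loss)))
    expect_lte(min(fit$history$train_loss), fit$history$train_loss[1])
  }
})

test_that("deep evaluation is deterministic, stateless and order-invariant", {
  pr <- deep_sets()
  m <- build_cnn7(cnn7_spec(n_filters = 4, kernel_length = 8, pool_length = 2,
                            fc_width = 8), 120, seed = 4)
  fit <- train_model(m, pr$train, train_config(epochs = 5, seed = 4))
  e1 <- evaluate_deep(fit, pr$test)
  e2 <- evaluate_deep(fit, pr$test)
  expect_identical(e1, e2)
  perm <- sample(seq_len(n_samples(pr$test)))
  e3 <- evaluate_deep(fit, subset_samples(pr$test, perm))
  expect_equal(e3$prob_e, e1$prob_e[perm], tolerance = 1e-12)
  expect_error(evaluate_deep(fit, spc_window(pr$test, 1300, 1600)),
               "feature-length")
})

test_that("final history entry agrees with re-evaluating the fit subset", {
  pr <- deep_sets()
  m <- build_cnn7(cnn7_spec(n_filters = 4, kernel_length = 8, pool_length = 2,
                            fc_width = 8), 120, seed = 6)
  fit <- train_model(m, pr$train, train_config(epochs = 20, seed = 6))
  fit_ids <- setdiff(pr$train$meta$sample_id, fit$validation_ids)
  sub <- subset_samples(pr$train,
                        match(fit_ids, pr$train$meta$sample_id))
  ev <- evaluate_deep(fit, sub)
  expect_equal(mean(ev$pred == ev$truth),
               fit$history$train_acc[nrow(fit$history)], tolerance = 1e-12)
})

test_that("both architectures solve the separable regime on the small grid", {
  pr <- deep_sets()
  hits <- 0
  for (s in 1:3) {
    fc <- train_model(
      build_cnn7(cnn7_spec(n_filters = 4, kernel_length = 8, pool_length = 2,
                           fc_width = 16), 120, seed = s),
      pr$train, train_config(epochs = 60, seed = s))
    fl <- train_model(
      build_lstm(lstm_spec(hidden_units = 32, n_steps = 4), 120, seed = s),
      pr$train, train_config(epochs = 60, seed = s))
    acc <- c(
      mean(with(evaluate_deep(fc, pr$test), pred == truth)),
      mean(with(evaluate_deep(fl, pr$test), pred == truth))
    )
    hits <- hits + all(acc == 1)
  }
  expect_gte(hits, 2)
})

test_that("label shuffling destroys held-out accuracy (leakage control)", {
  pr <- deep_sets()
  accs <- vapply(1:3, function(s) {
    shuffled <- pr$train
    withr::with_seed(100 + s, {
      shuffled$meta$label <- sample(shuffled$meta$label)
    })
    fit <- train_model(
      build_cnn7(cnn7_spec(n_filters = 4, kernel_length = 8, pool_length = 2,
                           fc_width = 16), 120, seed = s),
      shuffled, train_config(epochs = 30, seed = s))
    ev <- evaluate_deep(fit, pr$test)
    mean(ev$pred == ev$truth)
  }, numeric(1))
  # 30 held-out predictions in total: chance 0.5 +/- 3 binomial sd
  expect_lt(abs(mean(accs) - 0.5), 3 * sqrt(0.25 / 30))
})

test_that("a diverged model aborts training with a diagnostic", {
  pr <- deep_sets()
  m <- build_cnn7(cnn7_spec(n_filters = 2, kernel_length = 8, pool_length = 2,
                            fc_width = 4), 120, seed = 9)
  m$params$b2[1] <- NaN
  expect_error(train_model(m, pr$train, train_config(epochs = 2, seed = 9)),
               "non-finite loss")
})
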