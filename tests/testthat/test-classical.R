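sep_sets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      # class bands widened so the coarse 120-point fixture grid resolves them
      d <- generate_lmwha_spectra(quick_config(
        n_points = 120, seed = 31, regime = "separable",
        class_delta_a = band_spec(1360, 20, 8e-4),
        class_delta_e = band_spec(1496, 20, 8e-4)
      ))
      sp <- split_by_batch(d, 1:8, 9)
      cache <<- preprocess_pipeline(sp$train, sp$test)
    }
    cache
  }
})

test_that("PLS-DA rounds the continuous response at 0.5 toward class E", {
  expect_identical(plsda_decision(c(0.49, 0.51, 0.5, -0.2, 1.4)),
                   c("A", "E", "E", "A", "E"))
})

test_that("PLS-DA is perfect on cleanly separable data", {
  pr <- sep_sets()
  fit <- plsda_fit(pr$train, pr$test, n_components = 5)
  expect_length(fit$misclassified$loocv, 0)
  expect_length(fit$misclassified$test, 0)
  expect_equal(glance(fit)$loocv_accuracy, 1)
})

test_that("LOOCV equals an independent refit loop on a subsample", {
  pr <- sep_sets()
  idx <- which(pr$train$meta$batch <= 2)  # 20 samples
  small <- subset_samples(pr$train, idx)
  fit <- plsda_fit(small, n_components = 3)
  x <- small$absorbance
  colnames(x) <- paste0("w", seq_len(ncol(x)))
  y01 <- as.numeric(small$meta$label == "E")
  oracle <- vapply(seq_len(nrow(x)), function(i) {
    m <- mixOmics::pls(x[-i, ], matrix(y01[-i], ncol = 1), ncomp = 3,
                       mode = "regression", scale = FALSE)
    as.numeric(predict(m, x[i, , drop = FALSE])$predict[, 1, 3])
  }, numeric(1))
  expect_equal(fit$loocv$response, oracle, tolerance = 1e-8)
  expect_error(plsda_fit(subset_samples(small, which(small$meta$label == "A"))),
               "single-class")
})

test_that("SVC separates linear point clouds for any reasonable C", {
  withr::with_seed(32, {
    x <- rbind(matrix(rnorm(20, 0, 0.3), 10), matrix(rnorm(20, 3, 0.3), 10))
  })
  d <- spectra_set(x, c(1300, 1600), rep(c("A", "E"), each = 10), rep(1:2, 10))
  for (C in c(1, 10, 100)) {
    fit <- svc_fit(d, svc_config(C = C, gamma = 0.5, cv_folds = 2))
    pr <- predict_svc(fit, d)
    expect_equal(mean(pr$pred == pr$truth), 1)
  }
})

test_that("grid search evaluates exactly its grid and the best is the max", {
  pr <- sep_sets()
  small <- subset_samples(pr$train, which(pr$train$meta$batch <= 3))
  cfg <- svc_config(search = "gs", log2c = c(-2, 2), log2g = c(-6, -2),
                    grid_step = 2, cv_folds = 3, seed = 4)
  fit <- svc_fit(small, cfg)
  expect_equal(nrow(fit$trace), 9)
  expect_equal(fit$best$cv_accuracy, max(fit$trace$cv_accuracy))
  expect_setequal(unique(fit$trace$log2c), c(-2, 0, 2))
})

test_that("GA and PSO searches respect budgets, are seeded, and match the grid", {
  pr <- sep_sets()
  small <- subset_samples(pr$train, which(pr$train$meta$batch <= 3))
  gs <- svc_fit(small, svc_config(search = "gs", log2c = c(-4, 4),
                                  log2g = c(-8, 0), grid_step = 4,
                                  cv_folds = 3, seed = 1))
  ga_ctrl <- list(population = 8, generations = 5)
  pso_ctrl <- list(particles = 8, iterations = 5)
  for (s in 1:3) {
    ga <- svc_fit(small, svc_config(search = "ga", cv_folds = 3, seed = s,
                                    ga = ga_ctrl))
    pso <- svc_fit(small, svc_config(search = "pso", cv_folds = 3, seed = s,
                                     pso = pso_ctrl))
    expect_lte(nrow(ga$trace), 8 * 6)
    expect_lte(nrow(pso$trace), 8 * 6)
    expect_gte(ga$best$cv_accuracy, gs$best$cv_accuracy)
    expect_gte(pso$best$cv_accuracy, gs$best$cv_accuracy)
    ga2 <- svc_fit(small, svc_config(search = "ga", cv_folds = 3, seed = s,
                                     ga = ga_ctrl))
    expect_identical(ga$trace, ga2$trace)
  }
})

test_that("nu-SVC honors nu semantics across the default sweep", {
  pr <- sep_sets()
  sweep <- nusvc_sweep(pr$train, pr$test)
  expect_equal(nrow(sweep$results), 5)
  expect_equal(sweep$results$nu, seq(0.5, 0.9, by = 0.1))
  feasible <- sweep$results[sweep$results$feasible, ]
  # nu lower-bounds the support-vector fraction and upper-bounds train error
  expect_true(all(feasible$sv_fraction >= feasible$nu - 1e-8))
  expect_true(all(feasible$train_error_rate <= feasible$nu + 1e-8))
  expect_error(nusvc_sweep(pr$train, pr$test, nus = c(-1, 2)), "nu must be")
})

test_that("random forest sweep has 20 points and vanishing OOB error when separable", {
  pr <- sep_sets()
  cfg <- rf_config(n_trees = 300, seed = 2)
  fit <- rf_fit(pr$train, pr$test, cfg)
  expect_equal(fit$oob_curve$n_trees, seq(50, 1000, by = 50))
  expect_equal(nrow(fit$oob_curve), 20)
  expect_true(all(fit$oob_curve$oob_error >= 0 & fit$oob_curve$oob_error <= 1))
  expect_lt(fit$oob_curve$oob_error[nrow(fit$oob_curve)], 0.05)
  # the discriminative window carries the top importance
  top <- fit$importances$wavelength[which.max(fit$importances$mean_decrease_accuracy)]
  expect_true(top >= 1300 && top <= 1600)
})

test_that("random forest is seed-deterministic and a noise feature scores ~0", {
  pr <- sep_sets()
  small <- subset_samples(pr$train, which(pr$train$meta$batch <= 4))
  f1 <- rf_fit(small, config = rf_config(n_trees = 200, sweep = NULL, seed = 7))
  f2 <- rf_fit(small, config = rf_config(n_trees = 200, sweep = NULL, seed = 7))
  expect_identical(predict_rf(f1, pr$test)$pred, predict_rf(f2, pr$test)$pred)
  expect_equal(f1$importances$mean_decrease_accuracy,
               f2$importances$mean_decrease_accuracy)
  imp <- f1$importances
  # wavelengths far from every band and from the class signal are pure noise
  noise_region <- imp$wavelength > 2050
  expect_lt(max(abs(imp$mean_decrease_accuracy[noise_region])),
            3 * max(sd(imp$mean_decrease_accuracy[noise_region]), 1e-12) + 1e-9)
})
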