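poly_set <- function(coefs, wl = small_grid(60)) {
  rows <- t(vapply(seq_len(nrow(coefs)), function(i) {
    x <- (wl - mean(wl)) / 100
    drop(outer(x, 0:(ncol(coefs) - 1), `^`) %*% coefs[i, ])
  }, numeric(length(wl))))
  spectra_set(rows, wl, rep(c("A", "E"), length.out = nrow(coefs)),
              rep(1L, nrow(coefs)))
}

test_that("SG smoothing reproduces polynomials up to its order exactly", {
  d <- poly_set(rbind(c(2, 0, 0), c(1, 0.5, 0), c(0.3, -0.2, 0.7)))
  for (w in c(5, 11, 15)) {
    sm <- sg_smooth(d, window = w, polyorder = 2)
    expect_equal(sm$absorbance, d$absorbance, tolerance = 1e-9)
  }
})

test_that("SG interior output matches a sliding least-squares refit and reduces noise", {
  wl <- small_grid(200)
  withr::with_seed(5, {
    truth <- sin(2 * pi * (wl - 1300) / 150)
    noisy <- truth + rnorm(length(wl), 0, 0.05)
  })
  d <- spectra_set(matrix(noisy, 1), wl, "A", 1L)
  w <- 15
  p <- 3
  sm <- sg_smooth(d, window = w, polyorder = p)
  half <- (w - 1) / 2
  # oracle: explicit polynomial fit in every interior window
  interior <- (half + 1):(length(wl) - half)
  oracle <- vapply(interior, function(i) {
    idx <- (i - half):(i + half)
    fit <- lm(y ~ poly(x, p, raw = TRUE),
              data = data.frame(x = seq_along(idx) - half - 1, y = noisy[idx]))
    unname(predict(fit, data.frame(x = 0)))
  }, numeric(1))
  expect_equal(sm$absorbance[1, interior], oracle, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(sqrt(mean((sm$absorbance[1, ] - truth)^2)),
            sqrt(mean((noisy - truth)^2)))
  expect_error(sg_smooth(d, window = 10, polyorder = 2), "odd")
  expect_error(sg_smooth(d, window = 11, polyorder = 11), "polyorder")
})

test_that("MSC inverts affine distortions of the reference", {
  wl <- small_grid(80)
  ref <- 0.5 + 0.4 * exp(-(wl - 1450)^2 / (2 * 45^2))
  rows <- rbind(ref, 2 * ref + 3, 0.5 * ref - 1)
  d <- spectra_set(rows, wl, c("A", "A", "E"), c(1L, 1L, 1L))
  out <- msc(d, reference = ref)
  for (i in 1:3) {
    expect_equal(out$absorbance[i, ], ref, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  co <- attr(out, "msc_coefficients")
  expect_equal(co$a, c(1, 2, 0.5), tolerance = 1e-10)
  expect_equal(co$b, c(0, 3, -1), tolerance = 1e-10)
})

test_that("MSC coefficients match a longhand normal-equations solve", {
  wl <- small_grid(50)
  withr::with_seed(8, {
    ref <- runif(50)
    rows <- matrix(rnorm(6 * 50), 6)
  })
  d <- spectra_set(rows, wl, rep("A", 6), rep(1L, 6),
                   sprintf("r%d", 1:6))
  out <- msc(d, reference = ref)
  co <- attr(out, "msc_coefficients")
  for (i in 1:6) {
    # normal equations for y ~ a r + b, written out
    n <- length(ref)
    sxx <- sum(ref^2) - sum(ref)^2 / n
    sxy <- sum(ref * rows[i, ]) - sum(ref) * sum(rows[i, ]) / n
    a <- sxy / sxx
    b <- mean(rows[i, ]) - a * mean(ref)
    expect_equal(co$a[i], a, tolerance = 1e-8)
    expect_equal(co$b[i], b, tolerance = 1e-8)
  }
})

test_that("MSC is idempotent against a fixed reference", {
  d <- generate_lmwha_spectra(quick_config(n_points = 60, seed = 2))
  ref <- colMeans(d$absorbance)
  once <- msc(d, ref)
  twice <- msc(once, ref)
  expect_equal(twice$absorbance, once$absorbance, tolerance = 1e-10)
})

test_that("MSC removes the generator's multiplicative scatter", {
  cfg <- quick_config(n_points = 100, noise_sd = 0, batch_shift_sd = 0, seed = 4)
  d <- generate_lmwha_spectra(cfg)
  corrected <- msc(d)
  for (cl in c("A", "E")) {
    rows_pre <- d$absorbance[d$meta$label == cl, ]
    rows_post <- corrected$absorbance[corrected$meta$label == cl, ]
    var_pre <- mean(apply(rows_pre, 2, var))
    var_post <- mean(apply(rows_post, 2, var))
    expect_lt(var_post, 1e-6 * var_pre)
  }
})

test_that("global min-max normalization follows its closed form", {
  m <- matrix(c(0, 10, 5, 5), 2)
  out <- minmax_normalize(m)
  expect_equal(unclass(out)[, ], matrix(c(0, 1, 0.5, 0.5), 2),
               ignore_attr = TRUE)
  withr::with_seed(9, x <- matrix(rnorm(40), 5))
  nx <- minmax_normalize(x)
  expect_equal(min(nx), 0)
  expect_equal(max(nx), 1)
  # affine re-expansion recovers the input
  back <- nx * (attr(nx, "x_max") - attr(nx, "x_min")) + attr(nx, "x_min")
  expect_equal(unclass(back)[, ], x, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(minmax_normalize(matrix(3, 2, 2)), "constant")
})

test_that("pipeline fits on train only and composes the three stages", {
  d <- generate_lmwha_spectra(quick_config(n_points = 90, seed = 6))
  sp <- split_by_batch(d, 1:8, 9)
  cfg <- preprocess_config(sg_window = 9, sg_polyorder = 2)
  res <- preprocess_pipeline(sp$train, sp$test, cfg)

  # composition oracle: run the three stages by hand on the training set
  manual <- sg_smooth(sp$train, 9, 2)
  ref <- colMeans(manual$absorbance)
  manual <- msc(manual, ref)
  manual_n <- minmax_normalize(manual$absorbance)
  expect_equal(res$train$absorbance, unclass(manual_n)[, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(res$params$msc_reference, ref, ignore_attr = TRUE)

  # same data on both sides gives identical outputs
  res2 <- preprocess_pipeline(sp$train, sp$train, cfg)
  expect_equal(res2$test$absorbance, res2$train$absorbance)

  # train-fitted scalars: a localized spike survives MSC and normalizes
  # above 1 (the scalars are not re-fitted on the test set)
  hot <- sp$test
  hot$absorbance[, 40] <- hot$absorbance[, 40] + 5  # survives SG attenuation
  res3 <- preprocess_pipeline(sp$train, hot, cfg)
  expect_gt(max(res3$test$absorbance), 1)
  expect_equal(range(res3$train$absorbance), c(0, 1))

  bad <- spc_window(sp$test, 1000, 2000)
  expect_error(preprocess_pipeline(sp$train, bad, cfg), "grids differ")
})
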