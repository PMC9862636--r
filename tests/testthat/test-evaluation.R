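test_that("confusion counts follow their definition and a brute tally", {
  cm <- confusion(c("A", "A", "E", "E"), c("A", "A", "E", "E"), positive = "E")
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(2, 0, 0, 2))
  cm2 <- confusion(c("A", "A", "E", "E"), c("E", "E", "A", "A"), positive = "E")
  expect_equal(c(cm2$tp, cm2$fn, cm2$fp, cm2$tn), c(0, 2, 2, 0))

  withr::with_seed(41, {
    truth <- sample(c("A", "E"), 200, replace = TRUE)
    pred <- sample(c("A", "E"), 200, replace = TRUE)
  })
  cm3 <- confusion(truth, pred, positive = "E")
  tally <- c(tp = 0, fn = 0, fp = 0, tn = 0)
  for (i in 1:200) {
    key <- if (truth[i] == "E" && pred[i] == "E") "tp"
    else if (truth[i] == "E") "fn"
    else if (pred[i] == "E") "fp"
    else "tn"
    tally[key] <- tally[key] + 1
  }
  expect_equal(c(cm3$tp, cm3$fn, cm3$fp, cm3$tn), unname(tally))
  expect_equal(cm3$tp + cm3$fn, sum(truth == "E"))
  expect_error(confusion(c("A"), c("A", "E")), "lengths differ")
  expect_error(confusion(c("A", "E"), c("A", "X")), "unknown label")
})

test_that("metrics match hand-computable cases and flag undefined ones", {
  cm <- structure(list(tp = 5, fn = 1, fp = 0, tn = 4, positive = "E",
                       classes = c("A", "E")), class = "confusion_matrix")
  m <- cm_metrics(cm)
  expect_equal(m$accuracy, 90)
  expect_equal(m$precision, 100)
  expect_equal(m$specificity, 100)
  expect_equal(round(m$sensitivity, 1), 83.3)
  expect_equal(round(m$f1, 1), 90.9)

  perfect <- cm_metrics(confusion(c("A", "E"), c("A", "E")))
  expect_true(all(perfect[1, 1:5] == 100))

  # no predicted positives: precision undefined, never 0 or 100
  none_pred <- confusion(c("A", "E"), c("A", "A"))
  expect_true(is.na(cm_metrics(none_pred)$precision))
})

test_that("accuracy decomposes into the prevalence-weighted identity", {
  withr::with_seed(42, {
    for (i in 1:25) {
      counts <- rmultinom(1, 40, rep(0.25, 4))
      cm <- structure(list(tp = counts[1], fn = counts[2], fp = counts[3],
                           tn = counts[4], positive = "E",
                           classes = c("A", "E")), class = "confusion_matrix")
      m <- cm_metrics(cm)
      p <- cm$tp + cm$fn
      n <- cm$tn + cm$fp
      if (p > 0 && n > 0) {
        expect_equal(m$accuracy,
                     (m$sensitivity * p + m$specificity * n) / (p + n),
                     tolerance = 1e-9)
        if (!is.na(m$f1) && !is.na(m$precision) &&
            abs(m$precision - m$sensitivity) < 1e-12) {
          expect_equal(m$f1, m$precision, tolerance = 1e-9)
        }
      }
    }
  })
})

test_that("ROC endpoints, AUC extremes and the U-statistic equivalence hold", {
  truth <- rep(c("A", "E"), each = 5)
  perfect <- roc_auc(c(1:5, 6:10), truth)
  expect_equal(perfect$auc, 1)
  inverted <- roc_auc(c(6:10, 1:5), truth)
  expect_equal(inverted$auc, 0)
  expect_equal(perfect$roc$fpr[1], 0)
  expect_equal(perfect$roc$tpr[1], 0)
  expect_equal(perfect$roc$fpr[nrow(perfect$roc)], 1)
  expect_equal(perfect$roc$tpr[nrow(perfect$roc)], 1)
  expect_true(all(diff(perfect$roc$fpr) >= 0))
  expect_true(all(diff(perfect$roc$tpr) >= 0))

  withr::with_seed(43, {
    aucs <- numeric(60)
    for (i in seq_along(aucs)) {
      scores <- rnorm(40)
      truth <- rep(c("A", "E"), each = 20)
      r <- roc_auc(scores, truth)
      pos <- scores[truth == "E"]
      neg <- scores[truth == "A"]
      u <- (sum(outer(pos, neg, `>`)) + 0.5 * sum(outer(pos, neg, `==`))) /
        (length(pos) * length(neg))
      expect_equal(r$auc, u, tolerance = 1e-12)
      aucs[i] <- r$auc
    }
    expect_lt(abs(mean(aucs) - 0.5), 0.03)
  })
  expect_error(roc_auc(1:4, rep("E", 4)), "each class")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(44, {
    scores <- rnorm(30)
    truth <- sample(c("A", "E"), 30, replace = TRUE, prob = c(0.5, 0.5))
  })
  base <- roc_auc(scores, truth)$auc
  expect_equal(roc_auc(exp(scores), truth)$auc, base, tolerance = 1e-12)
  expect_equal(roc_auc(scores^3 + 2 * scores, truth)$auc, base,
               tolerance = 1e-12)
})

test_that("our ROC/AUC agrees with an established reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(45, {
    scores <- rnorm(50)
    truth <- sample(c("A", "E"), 50, replace = TRUE)
  })
  ours <- roc_auc(scores, truth)$auc
  ref <- pROC::auc(pROC::roc(response = truth, predictor = scores,
                             levels = c("A", "E"), direction = "<",
                             quiet = TRUE))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("fit_report rounds for display and round-trips through CSV", {
  withr::with_seed(46, {
    results <- list()
    for (model in c("svc", "gs_svc", "ga_svc", "pso_svc")) {
      for (split in c("train", "test")) {
        n <- if (split == "train") 80 else 10
        truth <- sample(c("A", "E"), n, replace = TRUE)
        scores <- rnorm(n) + (truth == "E")
        results[[length(results) + 1]] <- list(
          model = model, split = split, truth = truth,
          pred = ifelse(scores > 0.5, "E", "A"), scores = scores
        )
      }
    }
  })
  rep <- fit_report(results)
  expect_equal(nrow(rep), 8)
  expect_equal(names(rep), c("model", "split", "accuracy", "precision",
                             "specificity", "sensitivity", "f1", "auc"))
  for (i in seq_len(nrow(rep))) {
    r <- results[[i]]
    m <- cm_metrics(confusion(r$truth, r$pred))
    expect_equal(rep$accuracy[i], floor(m$accuracy * 10 + 0.5) / 10)
  }
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rep, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(rep))
})

test_that("reconstruct_confusion inverts printed metric rows uniquely", {
  hits <- reconstruct_confusion(10, accuracy = 90, precision = 100,
                                specificity = 100, sensitivity = 83.3,
                                f1 = 90.9)
  expect_equal(nrow(hits), 1)
  expect_equal(c(hits$tp, hits$fn, hits$fp, hits$tn), c(5, 1, 0, 4))
  none <- reconstruct_confusion(10, accuracy = 90, precision = 10,
                                specificity = 90, sensitivity = 90, f1 = 90)
  expect_equal(nrow(none), 0)
})
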