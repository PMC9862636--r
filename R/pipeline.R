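#' Full-run configuration
#'
#' Bundles the generator, preprocessing, split and model roster for
#' [run_full_comparison()]. The default roster is the study design's full
#' head-to-head: PLS-DA, plain/GS/GA/PSO-optimized RBF-SVC, the five-value
#' nu-SVC sweep, random forest, the seven-layer 1D CNN and the LSTM.
#'
#' @param generator A [generator_config()].
#' @param preprocess A [preprocess_config()].
#' @param train_batches,test_batches Batch split; defaults to all but the
#'   last batch vs the last batch.
#' @param models Character subset of `c("plsda", "svc", "gs_svc", "ga_svc",
#'   "pso_svc", "nusvc", "rf", "cnn7", "lstm")`.
#' @param svc Base [svc_config()] reused by the SVC variants (its `search`
#'   field is overridden per variant).
#' @param rf An [rf_config()].
#' @param cnn,lstm Architecture specs ([cnn7_spec()], [lstm_spec()]).
#' @param train A [train_config()] shared by both deep models.
#' @param plsda_components PLS-DA latent components.
#' @param output_dir Output directory.
#' @param seed Master seed, propagated to every stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       preprocess = preprocess_config(),
                       train_batches = NULL, test_batches = NULL,
                       models = c("plsda", "svc", "gs_svc", "ga_svc", "pso_svc",
                                  "nusvc", "rf", "cnn7", "lstm"),
                       svc = svc_config(),
                       rf = rf_config(),
                       cnn = cnn7_spec(), lstm = lstm_spec(),
                       train = train_config(),
                       plsda_components = 10,
                       output_dir = tempfile("nirha_run_"),
                       seed = 1) {
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(train_batches)) train_batches <- seq_len(generator$n_batches - 1)
  if (is.null(test_batches)) test_batches <- generator$n_batches
  structure(
    list(generator = generator, preprocess = preprocess,
         train_batches = train_batches, test_batches = test_batches,
         models = models, svc = svc, rf = rf, cnn = cnn, lstm = lstm,
         train = train, plsda_components = plsda_components,
         output_dir = output_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

run_stage <- function(name, log, expr) {
  log(sprintf("stage %s: start", name))
  res <- tryCatch(expr, error = function(e) {
    log(sprintf("stage %s: FAILED: %s", name, conditionMessage(e)))
    stop(sprintf("run_full_comparison: stage '%s' failed: %s",
                 name, conditionMessage(e)), call. = FALSE)
  })
  log(sprintf("stage %s: done", name))
  res
}

#' Run the end-to-end comparison
#'
#' Generates (or loads) the spectra, preprocesses with a train-only fit,
#' computes the per-class 2D correlation maps and the aquagram, a PCA
#' diagnostic, trains every configured model and writes a consolidated
#' per-model/per-split metrics report plus all intermediate artifacts (CSV),
#' a timestamped log and an md5 manifest under `config$output_dir`.
#'
#' @param config A [run_config()].
#' @param data Optional pre-made `spectra_set`; generated from
#'   `config$generator` when `NULL`.
#' @return Invisibly, a list with `report` (tibble) and `output_dir`.
#' @export
run_full_comparison <- function(config = run_config(), data = NULL) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "log.txt")
  log <- function(msg) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg),
        file = log_path, append = TRUE)
  }
  out <- function(...) file.path(config$output_dir, ...)

  gen <- config$generator
  gen$seed <- config$seed
  data <- run_stage("generate", log, {
    d <- data %||% generate_lmwha_spectra(gen)
    write_spectra_csv(d, out("spectra.csv"))
    cfg_echo <- config
    cfg_echo$generator$grid <- NULL  # grid echoed by its size, not 4148 values
    cfg_echo$generator_grid_points <- length(gen$grid)
    cfg_echo$output_dir <- NULL  # implicit; keeps the echo location-independent
    jsonlite::write_json(cfg_echo, out("config.json"), auto_unbox = TRUE,
                         force = TRUE, digits = NA)
    d
  })

  sets <- run_stage("split", log,
                    split_by_batch(data, config$train_batches, config$test_batches))
  prep <- run_stage("preprocess", log,
                    preprocess_pipeline(sets$train, sets$test, config$preprocess))

  run_stage("twodcos", log, {
    for (cl in c("A", "E")) {
      series <- subset_samples(prep$train, which(prep$train$meta$label == cl))
      corr <- compute_2dcos(series, 1300, 1600)
      write_2dcos_csv(corr, out(sprintf("twodcos_sync_%s.csv", cl)),
                      out(sprintf("twodcos_async_%s.csv", cl)))
    }
  })
  run_stage("aquagram", log, {
    aquagram_to_csv(aquagram(spc_window(prep$train, 1300, 1600)),
                    out("aquagram.csv"))
  })
  run_stage("dimred", log, {
    emb <- spc_pca(prep$train, k = 2)
    readr::write_csv(tidy(emb), out("pca_coords.csv"))
  })

  results <- list()
  add_result <- function(model, split, tbl) {
    results[[length(results) + 1]] <<- list(
      model = model, split = split,
      truth = tbl$truth, pred = tbl$pred, scores = tbl$score
    )
  }

  if ("plsda" %in% config$models) {
    run_stage("plsda", log, {
      fit <- plsda_fit(prep$train, prep$test,
                       n_components = config$plsda_components)
      loocv <- dplyr::mutate(fit$loocv, score = response)
      test <- dplyr::mutate(fit$test, score = response)
      add_result("plsda", "train", loocv)
      add_result("plsda", "test", test)
      readr::write_csv(tidy(fit), out("plsda_predictions.csv"))
    })
  }
  svc_variants <- intersect(config$models, c("svc", "gs_svc", "ga_svc", "pso_svc"))
  for (variant in svc_variants) {
    run_stage(variant, log, {
      cfg <- config$svc
      cfg$search <- c(svc = "none", gs_svc = "gs", ga_svc = "ga",
                      pso_svc = "pso")[[variant]]
      cfg$seed <- config$seed
      fit <- svc_fit(prep$train, cfg)
      add_result(variant, "train", predict_svc(fit, prep$train))
      add_result(variant, "test", predict_svc(fit, prep$test))
      readr::write_csv(fit$trace, out(sprintf("search_trace_%s.csv", variant)))
    })
  }
  if ("nusvc" %in% config$models) {
    run_stage("nusvc", log, {
      sweep <- nusvc_sweep(prep$train, prep$test)
      for (e in sweep$entries) {
        if (isTRUE(e$feasible)) {
          add_result(sprintf("nusvc_%.1f", e$nu), "train", e$train)
          add_result(sprintf("nusvc_%.1f", e$nu), "test", e$test)
        }
      }
      readr::write_csv(sweep$results, out("nusvc_sweep.csv"))
    })
  }
  if ("rf" %in% config$models) {
    run_stage("rf", log, {
      cfg <- config$rf
      cfg$seed <- config$seed
      fit <- rf_fit(prep$train, prep$test, cfg)
      add_result("rf", "train", predict_rf(fit, prep$train))
      add_result("rf", "test", predict_rf(fit, prep$test))
      if (!is.null(fit$oob_curve)) readr::write_csv(fit$oob_curve, out("rf_oob_curve.csv"))
      readr::write_csv(fit$importances, out("rf_importances.csv"))
    })
  }
  for (deep in intersect(config$models, c("cnn7", "lstm"))) {
    run_stage(deep, log, {
      tc <- config$train
      tc$seed <- config$seed
      model <- if (deep == "cnn7") {
        build_cnn7(config$cnn, n_wavelengths(prep$train), seed = config$seed)
      } else {
        build_lstm(config$lstm, n_wavelengths(prep$train), seed = config$seed)
      }
      fit <- train_model(model, prep$train, tc)
      add_result(deep, "train", evaluate_deep(fit, prep$train))
      add_result(deep, "test", evaluate_deep(fit, prep$test))
      readr::write_csv(fit$history, out(sprintf("history_%s.csv", deep)))
    })
  }

  report <- run_stage("report", log, {
    rep <- fit_report(results)
    readr::write_csv(rep, out("report.csv"))
    rep
  })

  run_stage("manifest", log, {
    files <- setdiff(list.files(config$output_dir),
                     c("manifest.csv", "log.txt"))
    hashes <- tools::md5sum(file.path(config$output_dir, files))
    readr::write_csv(tibble::tibble(file = files, md5 = unname(hashes)),
                     out("manifest.csv"))
  })
  invisible(list(report = report, output_dir = config$output_dir))
}
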