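#' Support vector classifier configuration
#'
#' RBF kernel convention `k(x, y) = exp(-g * ||x - y||^2)` with penalty `C`.
#' The hyperparameter search, when enabled, explores `(log2 C, log2 g)` over
#' `log2c`/`log2g` with cross-validated accuracy as fitness; grid search is
#' exhaustive, the genetic algorithm uses tournament selection, arithmetic
#' crossover and Gaussian mutation, and particle swarm optimization uses the
#' standard constricted update (inertia 0.729, c1 = c2 = 1.49445).
#'
#' @param C Penalty (> 0).
#' @param gamma RBF coefficient `g` (> 0); default `1 / n_features`.
#' @param search One of `"none"`, `"gs"`, `"ga"`, `"pso"`.
#' @param log2c,log2g Search ranges in log2 units.
#' @param grid_step Grid-search step in log2 units.
#' @param cv_folds Cross-validation folds for search fitness.
#' @param ga,pso Control lists (population/generations, particles/iterations,
#'   ...); sensible defaults are filled in.
#' @param seed RNG seed for folds and stochastic searches.
#' @return A list of class `svc_config`.
#' @export
svc_config <- function(C = 1, gamma = NULL,
                       search = c("none", "gs", "ga", "pso"),
                       log2c = c(-8, 8), log2g = c(-8, 8), grid_step = 1,
                       cv_folds = 5, ga = list(), pso = list(), seed = 1) {
  search <- match.arg(search)
  if (C <= 0) stop("svc_config: C must be > 0", call. = FALSE)
  if (!is.null(gamma) && gamma <= 0) stop("svc_config: gamma must be > 0", call. = FALSE)
  if (log2c[1] >= log2c[2] || log2g[1] >= log2g[2]) {
    stop("svc_config: search ranges must have lo < hi", call. = FALSE)
  }
  ga <- utils::modifyList(
    list(population = 20, generations = 50, p_cross = 0.8, p_mut = 0.2,
         mut_sd_frac = 0.1, tournament = 3, elite = 1), ga)
  pso <- utils::modifyList(
    list(particles = 20, iterations = 50, inertia = 0.729,
         c1 = 1.49445, c2 = 1.49445), pso)
  structure(
    list(C = C, gamma = gamma, search = search, log2c = log2c, log2g = log2g,
         grid_step = grid_step, cv_folds = as.integer(cv_folds),
         ga = ga, pso = pso, seed = as.integer(seed)),
    class = "svc_config"
  )
}

svc_cv_accuracy <- function(x, y, C, gamma, fold) {
  correct <- 0L
  for (f in sort(unique(fold))) {
    hold <- fold == f
    if (length(unique(y[!hold])) < 2) {
      stop("svc_fit: degenerate single-class cross-validation fold", call. = FALSE)
    }
    m <- e1071::svm(x[!hold, , drop = FALSE], y[!hold], type = "C-classification",
                    kernel = "radial", cost = C, gamma = gamma, scale = FALSE)
    correct <- correct + sum(stats::predict(m, x[hold, , drop = FALSE]) == y[hold])
  }
  correct / length(y)
}

search_trace_row <- function(method, iteration, log2c, log2g, acc) {
  tibble::tibble(method = method, iteration = iteration,
                 log2c = log2c, log2g = log2g,
                 C = 2^log2c, g = 2^log2g, cv_accuracy = acc)
}

svc_search_gs <- function(x, y, fold, cfg) {
  grid <- expand.grid(
    log2c = seq(cfg$log2c[1], cfg$log2c[2], by = cfg$grid_step),
    log2g = seq(cfg$log2g[1], cfg$log2g[2], by = cfg$grid_step)
  )
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    svc_cv_accuracy(x, y, 2^grid$log2c[i], 2^grid$log2g[i], fold)
  }, numeric(1))
  search_trace_row("gs", seq_len(nrow(grid)), grid$log2c, grid$log2g, acc)
}

svc_search_ga <- function(x, y, fold, cfg) {
  ga <- cfg$ga
  lo <- c(cfg$log2c[1], cfg$log2g[1])
  hi <- c(cfg$log2c[2], cfg$log2g[2])
  clamp <- function(v) pmin(pmax(v, lo), hi)
  pop <- matrix(stats::runif(ga$population * 2, lo, hi),
                ncol = 2, byrow = TRUE)
  evaluate <- function(p) {
    vapply(seq_len(nrow(p)), function(i) {
      svc_cv_accuracy(x, y, 2^p[i, 1], 2^p[i, 2], fold)
    }, numeric(1))
  }
  fit <- evaluate(pop)
  trace <- search_trace_row("ga", rep(0L, nrow(pop)), pop[, 1], pop[, 2], fit)
  for (gen in seq_len(ga$generations)) {
    new_pop <- matrix(0, ga$population, 2)
    ord <- order(fit, decreasing = TRUE)
    n_elite <- min(ga$elite, ga$population)
    new_pop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], , drop = FALSE]
    for (i in seq(n_elite + 1, ga$population)) {
      pick <- function() {
        cand <- sample.int(ga$population, ga$tournament)
        cand[which.max(fit[cand])]
      }
      p1 <- pop[pick(), ]
      p2 <- pop[pick(), ]
      child <- if (stats::runif(1) < ga$p_cross) {
        a <- stats::runif(2)
        a * p1 + (1 - a) * p2
      } else {
        p1
      }
      mut <- stats::runif(2) < ga$p_mut
      child[mut] <- child[mut] +
        stats::rnorm(sum(mut), 0, ga$mut_sd_frac * (hi - lo)[mut])
      new_pop[i, ] <- clamp(child)
    }
    pop <- new_pop
    fit <- evaluate(pop)
    trace <- dplyr::bind_rows(
      trace, search_trace_row("ga", rep(gen, nrow(pop)), pop[, 1], pop[, 2], fit)
    )
  }
  trace
}

svc_search_pso <- function(x, y, fold, cfg) {
  ps <- cfg$pso
  lo <- c(cfg$log2c[1], cfg$log2g[1])
  hi <- c(cfg$log2c[2], cfg$log2g[2])
  pos <- matrix(stats::runif(ps$particles * 2, lo, hi), ncol = 2, byrow = TRUE)
  vel <- matrix(stats::runif(ps$particles * 2, -(hi - lo), hi - lo) / 10,
                ncol = 2, byrow = TRUE)
  evaluate <- function(p) {
    vapply(seq_len(nrow(p)), function(i) {
      svc_cv_accuracy(x, y, 2^p[i, 1], 2^p[i, 2], fold)
    }, numeric(1))
  }
  fit <- evaluate(pos)
  pbest <- pos
  pbest_fit <- fit
  gbest <- pos[which.max(fit), ]
  gbest_fit <- max(fit)
  trace <- search_trace_row("pso", rep(0L, nrow(pos)), pos[, 1], pos[, 2], fit)
  for (it in seq_len(ps$iterations)) {
    r1 <- matrix(stats::runif(ps$particles * 2), ncol = 2)
    r2 <- matrix(stats::runif(ps$particles * 2), ncol = 2)
    vel <- ps$inertia * vel +
      ps$c1 * r1 * (pbest - pos) +
      ps$c2 * r2 * (matrix(gbest, ps$particles, 2, byrow = TRUE) - pos)
    pos <- pos + vel
    pos <- pmin(pmax(pos, matrix(lo, ps$particles, 2, byrow = TRUE)),
                matrix(hi, ps$particles, 2, byrow = TRUE))
    fit <- evaluate(pos)
    better <- fit > pbest_fit
    pbest[better, ] <- pos[better, , drop = FALSE]
    pbest_fit[better] <- fit[better]
    if (max(fit) > gbest_fit) {
      gbest_fit <- max(fit)
      gbest <- pos[which.max(fit), ]
    }
    trace <- dplyr::bind_rows(
      trace, search_trace_row("pso", rep(it, nrow(pos)), pos[, 1], pos[, 2], fit)
    )
  }
  trace
}

#' Fit an RBF support vector classifier, optionally with hyperparameter search
#'
#' With `search = "none"` the classifier is fitted at the configured `(C, g)`;
#' otherwise grid search, a genetic algorithm or particle swarm optimization
#' maximizes the `cv_folds`-fold cross-validated accuracy over
#' `(log2 C, log2 g)` and the classifier is refitted at the best point. All
#' searches are seeded and use the same fold assignment, and every evaluated
#' point is recorded in the search trace.
#'
#' @param train Training `spectra_set` (features already normalized).
#' @param config An [svc_config()].
#' @return An object of class `svc_fit`: fitted `e1071::svm` model, `trace`
#'   tibble (`method`, `iteration`, `C`, `g`, `cv_accuracy`), `best` row and
#'   the config.
#' @export
svc_fit <- function(train, config = svc_config()) {
  x <- feature_matrix(train)
  y <- label_factor(train$meta$label)
  gamma <- config$gamma %||% (1 / ncol(x))
  fold <- stratified_folds(y, config$cv_folds, config$seed)
  trace <- withr::with_seed(config$seed, {
    switch(config$search,
      none = search_trace_row("none", 1L, log2(config$C), log2(gamma),
                              svc_cv_accuracy(x, y, config$C, gamma, fold)),
      gs = svc_search_gs(x, y, fold, config),
      ga = svc_search_ga(x, y, fold, config),
      pso = svc_search_pso(x, y, fold, config)
    )
  })
  best <- trace[which.max(trace$cv_accuracy), ]
  C_fit <- if (config$search == "none") config$C else best$C
  g_fit <- if (config$search == "none") gamma else best$g
  model <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                      cost = C_fit, gamma = g_fit, scale = FALSE)
  structure(
    list(model = model, trace = trace, best = best,
         C = C_fit, gamma = g_fit, config = config),
    class = "svc_fit"
  )
}

#' @export
print.svc_fit <- function(x, ...) {
  cat(sprintf("<svc_fit> search=%s, C=%.4g, g=%.4g, best cv accuracy=%.3f (%d evaluations)\n",
              x$config$search, x$C, x$gamma, x$best$cv_accuracy, nrow(x$trace)))
  invisible(x)
}

#' @export
tidy.svc_fit <- function(x, ...) x$trace

#' @export
glance.svc_fit <- function(x, ...) {
  tibble::tibble(search = x$config$search, C = x$C, g = x$gamma,
                 cv_accuracy = x$best$cv_accuracy, n_evaluations = nrow(x$trace),
                 n_support_vectors = x$model$tot.nSV)
}

decision_score_e <- function(model, x) {
  dv <- attr(stats::predict(model, x, decision.values = TRUE), "decision.values")
  # e1071 orients the score toward the first class in the column name
  if (grepl("^E", colnames(dv)[1])) as.numeric(dv[, 1]) else -as.numeric(dv[, 1])
}

#' Predict with a fitted SVC
#'
#' @param fit An `svc_fit` (or the per-nu entry of [nusvc_sweep()]).
#' @param data A `spectra_set`.
#' @return Tibble `sample_id`, `truth`, `pred`, `score` (signed distance to
#'   the hyperplane, oriented so larger means class E).
#' @export
predict_svc <- function(fit, data) {
  model <- if (inherits(fit, "svc_fit")) fit$model else fit
  x <- feature_matrix(data)
  tibble::tibble(
    sample_id = data$meta$sample_id,
    truth = data$meta$label,
    pred = as.character(stats::predict(model, x)),
    score = decision_score_e(model, x)
  )
}

#' nu-SVC sweep with a degree-3 polynomial kernel
#'
#' Fits a nu-parameterized SVC at each requested nu (nu upper-bounds the
#' training-error fraction and lower-bounds the support-vector fraction).
#' Infeasible nu values are flagged, not raised.
#'
#' @param train,test `spectra_set`s.
#' @param nus Nu values in (0, 1] (default 0.5, 0.6, 0.7, 0.8, 0.9).
#' @param degree Polynomial degree (default 3).
#' @return An object of class `nusvc_sweep`: `results` tibble (`nu`,
#'   `feasible`, `train_accuracy`, `test_accuracy`, `sv_fraction`,
#'   `train_error_rate`) and per-nu `models` / prediction tibbles.
#' @export
nusvc_sweep <- function(train, test, nus = seq(0.5, 0.9, by = 0.1), degree = 3) {
  if (any(nus <= 0 | nus > 1)) stop("nusvc_sweep: nu must be in (0, 1]", call. = FALSE)
  x <- feature_matrix(train)
  y <- label_factor(train$meta$label)
  entries <- purrr::map(nus, function(nu) {
    model <- tryCatch(
      e1071::svm(x, y, type = "nu-classification", kernel = "polynomial",
                 degree = degree, nu = nu, scale = FALSE),
      error = function(e) e
    )
    if (inherits(model, "error")) {
      return(list(nu = nu, feasible = FALSE, message = conditionMessage(model)))
    }
    tr <- predict_svc(model, train)
    te <- predict_svc(model, test)
    list(nu = nu, feasible = TRUE, model = model, train = tr, test = te,
         sv_fraction = model$tot.nSV / nrow(x),
         train_error_rate = mean(tr$pred != tr$truth),
         train_accuracy = mean(tr$pred == tr$truth),
         test_accuracy = mean(te$pred == te$truth))
  })
  if (!any(purrr::map_lgl(entries, "feasible"))) {
    stop("nusvc_sweep: all nu values infeasible", call. = FALSE)
  }
  results <- purrr::map_dfr(entries, function(e) {
    tibble::tibble(
      nu = e$nu, feasible = e$feasible,
      train_accuracy = e$train_accuracy %||% NA_real_,
      test_accuracy = e$test_accuracy %||% NA_real_,
      sv_fraction = e$sv_fraction %||% NA_real_,
      train_error_rate = e$train_error_rate %||% NA_real_
    )
  })
  structure(list(results = results, entries = entries, degree = degree),
            class = "nusvc_sweep")
}

#' @export
print.nusvc_sweep <- function(x, ...) {
  cat(sprintf("<nusvc_sweep> polynomial degree %d, %d nu values\n",
              x$degree, nrow(x$results)))
  print(x$results)
  invisible(x)
}

#' @export
tidy.nusvc_sweep <- function(x, ...) x$results
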