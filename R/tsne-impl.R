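# Exact (non-Barnes-Hut) t-SNE. At the sample sizes of this package
# (n <= a few hundred) the O(n^2) gradient is trivial, so the classical
# algorithm is implemented directly: per-point precision calibrated to the
# target perplexity by bisection, symmetrized affinities, early exaggeration,
# momentum gradient descent with adaptive per-coordinate gains.

.tsne_perplexity_p <- function(d2, perplexity, tol = 1e-5, max_tries = 50) {
  n <- nrow(d2)
  p <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    beta_min <- -Inf
    beta_max <- Inf
    di <- d2[i, -i]
    for (tr in seq_len(max_tries)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < .Machine$double.xmin) sw <- .Machine$double.xmin
      h <- log(sw) + beta * sum(di * w) / sw
      diff <- h - log_u
      if (abs(diff) < tol) break
      if (diff > 0) {
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    p[i, -i] <- exp(-di * beta) / sum(exp(-di * beta))
  }
  p
}

.tsne <- function(x, dims = 2, perplexity = 10, seed = 1, max_iter = 500,
                  eta = 100, momentum = c(0.5, 0.8), exaggeration = 4,
                  exaggeration_iter = 100) {
  n <- nrow(x)
  if (perplexity >= (n - 1) / 3) {
    stop(sprintf("tsne: perplexity %g too large for n = %d (need < (n-1)/3)",
                 perplexity, n), call. = FALSE)
  }
  d2 <- as.matrix(stats::dist(x))^2
  p <- .tsne_perplexity_p(d2, perplexity)
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, .Machine$double.xmin)
  withr::with_seed(seed, {
    y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
    inc <- matrix(0, n, dims)
    gains <- matrix(1, n, dims)
    pe <- p * exaggeration
    for (iter in seq_len(max_iter)) {
      pp <- if (iter <= exaggeration_iter) pe else p
      num <- 1 / (1 + as.matrix(stats::dist(y))^2)
      diag(num) <- 0
      q <- num / sum(num)
      q <- pmax(q, .Machine$double.xmin)
      mult <- (pp - q) * num
      grad <- 4 * (diag(rowSums(mult)) - mult) %*% y
      mo <- if (iter <= 250) momentum[1] else momentum[2]
      gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      inc <- mo * inc - eta * gains * grad
      y <- y + inc
      y <- sweep(y, 2, colMeans(y))
    }
    num <- 1 / (1 + as.matrix(stats::dist(y))^2)
    diag(num) <- 0
    q <- pmax(num / sum(num), .Machine$double.xmin)
    kl <- sum(p * log(p / q))
    list(y = y, kl = kl)
  })
}
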