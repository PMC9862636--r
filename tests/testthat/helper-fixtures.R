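# shared fixtures, built in code at test time

# compact grid over the water first-overtone region
small_grid <- function(n = 120, lo = 1300, hi = 1600) seq(lo, hi, length.out = n)

# small, fast two-class generator configuration on a reduced grid
quick_config <- function(..., n_points = 160, seed = 1) {
  generator_config(
    grid = seq(900, 2100, length.out = n_points),
    seed = seed,
    ...
  )
}

# naive triple-loop 2D correlation maps, the independent oracle
naive_2dcos <- function(mat) {
  m <- nrow(mat)
  n <- ncol(mat)
  xd <- sweep(mat, 2, colMeans(mat))
  nh <- matrix(0, m, m)
  for (j in seq_len(m)) for (k in seq_len(m)) {
    if (j != k) nh[j, k] <- 1 / (pi * (k - j))
  }
  sync <- matrix(0, n, n)
  async <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    s <- 0
    for (j in seq_len(m)) s <- s + xd[j, a] * xd[j, b]
    sync[a, b] <- s / (m - 1)
    s <- 0
    for (j in seq_len(m)) for (k in seq_len(m)) {
      s <- s + xd[j, a] * nh[j, k] * xd[k, b]
    }
    async[a, b] <- s / (m - 1)
  }
  list(sync = sync, async = async)
}

# plain silhouette score (mean over samples), avoiding any clustering package
silhouette_score <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  n <- nrow(coords)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(unique(labels[!own]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# nearest-class-centroid classifier, the cheap linear reference model
centroid_accuracy <- function(train, test) {
  mu_a <- colMeans(train$absorbance[train$meta$label == "A", , drop = FALSE])
  mu_e <- colMeans(train$absorbance[train$meta$label == "E", , drop = FALSE])
  pred <- apply(test$absorbance, 1, function(x) {
    if (sum((x - mu_a)^2) <= sum((x - mu_e)^2)) "A" else "E"
  })
  mean(pred == test$meta$label)
}

toy_spectra <- function() {
  spectra_set(
    matrix(c(0.1, 0.2, 0.3, 0.4, 0.5,
             0.2, 0.3, 0.4, 0.5, 0.6,
             0.3, 0.4, 0.5, 0.6, 0.7), nrow = 3, byrow = TRUE),
    wavelengths = c(1300, 1350, 1400, 1450, 1500),
    labels = c("A", "A", "E"),
    batch = c(1L, 1L, 2L),
    sample_ids = c("s1", "s2", "s3")
  )
}
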