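# Brute-force oracles and small fixtures used across the suite.  The oracles
# are written independently of the package's implementations: clustering by
# exhaustive triple enumeration, shortest paths by Floyd-Warshall, local
# efficiency from all-pairs distances in every induced subgraph.

bf_clustering <- function(a) {
  n <- nrow(a)
  c_i <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    d <- length(nb)
    if (d < 2) next
    tri <- 0
    for (p in seq_len(d - 1)) {
      for (q in (p + 1):d) {
        if (a[nb[p], nb[q]] == 1) tri <- tri + 1
      }
    }
    c_i[i] <- 2 * tri / (d * (d - 1))
  }
  c_i
}

bf_distances <- function(a) {
  n <- nrow(a)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[a == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

bf_path_length <- function(a) {
  D <- bf_distances(a)
  diag(D) <- NA
  l_i <- apply(D, 1, function(r) {
    r <- r[!is.na(r) & is.finite(r)]
    if (length(r)) mean(r) else NA_real_
  })
  mean(l_i, na.rm = TRUE)
}

bf_local_efficiency <- function(a) {
  n <- nrow(a)
  e_i <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) next
    Ds <- bf_distances(a[nb, nb, drop = FALSE])
    inv <- 1 / Ds
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    e_i[i] <- sum(inv) / (length(nb) * (length(nb) - 1))
  }
  mean(e_i)
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  up <- upper.tri(a)
  a[up] <- as.integer(runif(sum(up)) < p)
  a + t(a)
}

# cosine trial with given phase, amplitude 1, plus white noise
tone_trial <- function(n, fs, f0, phase, noise_sd = 0, nch = 1) {
  tt <- (0:(n - 1)) / fs
  m <- matrix(0, nch, n)
  for (c_ in seq_len(nch))
    m[c_, ] <- cos(2 * pi * f0 * tt + phase) + rnorm(n, 0, noise_sd)
  m
}
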