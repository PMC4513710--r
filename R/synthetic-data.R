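# Synthetic coupled-oscillator EEG and reference graph generators.
#
# The trial generator produces band-limited sinusoidal carriers whose
# inter-channel phase locking is controlled by a von Mises jitter with
# concentration kappa, so the population phase-locking value has the closed
# form I1(kappa)/I0(kappa).  Reference graphs (ring lattice, rewired
# small-world lattice, Erdos-Renyi) have known metric values and serve as
# fixtures for the network measures.

#' Population phase-locking value of a von Mises phase jitter
#'
#' For a phase offset distributed von Mises with concentration `kappa`, the
#' expected resultant length (and hence the population PLV) is the Bessel
#' ratio `I1(kappa)/I0(kappa)`.
#'
#' @param kappa Non-negative concentration parameter.
#' @return PLV in `[0, 1)`; 1 in the degenerate limit `kappa >= 1e6`.
#' @export
vonmises_plv <- function(kappa) {
  stopifnot(is.numeric(kappa), all(is.finite(kappa)), all(kappa >= 0))
  out <- numeric(length(kappa))
  hi <- kappa >= 1e6
  out[hi] <- 1
  k <- kappa[!hi]
  # exponentially scaled ratio avoids overflow for large kappa
  out[!hi] <- ifelse(k == 0, 0,
                     besselI(k, 1, expon.scaled = TRUE) /
                       besselI(k, 0, expon.scaled = TRUE))
  out
}

#' Expected sample PLV of uncoupled channels (chance floor)
#'
#' The modulus of the mean of `n_trials` independent uniform unit phasors has
#' expectation `sqrt(pi) / (2 sqrt(n_trials))`.
#'
#' @param n_trials Number of trials entering the PLV average.
#' @export
plv_chance_floor <- function(n_trials) {
  stopifnot(n_trials >= 1)
  sqrt(pi) / (2 * sqrt(n_trials))
}

#' Draw von Mises variates (mean 0)
#'
#' Best-Fisher (1979) acceptance-rejection sampler.  `kappa >= 1e6` is treated
#' as the zero-jitter limit and returns zeros; `kappa = 0` returns uniform
#' angles on `(-pi, pi]`.
#'
#' @param n Number of draws.
#' @param kappa Concentration, finite and non-negative.
#' @export
rvonmises <- function(n, kappa) {
  stopifnot(length(kappa) == 1, is.finite(kappa), kappa >= 0)
  if (kappa >= 1e6) return(rep(0, n))
  if (kappa < 1e-12) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(max(min(f, 1), -1))
      i <- i + 1L
    }
  }
  out
}

# von Mises quantile function (mean 0), by numeric inversion of the CDF.
qvonmises <- function(p, kappa, n_grid = 4096L) {
  th <- seq(-pi, pi, length.out = n_grid)
  dens <- exp(kappa * (cos(th) - 1))
  cdf <- cumsum(dens)
  cdf <- (cdf - cdf[1]) / (cdf[n_grid] - cdf[1])
  stats::approx(cdf, th, xout = p, ties = "ordered")$y
}

#' Coupling specification for the trial generator
#'
#' @param pairs Data frame with columns `i`, `j` (1-based channel indices),
#'   `kappa` (von Mises concentration of the pair's phase offset) and
#'   `freq_hz` (carrier frequency).  Pairs must form a forest: ground-truth
#'   PLV between two channels joined by a path of couplings is the product of
#'   the Bessel ratios along the path, which is only well defined without
#'   cycles.
#' @param noise_sd Standard deviation of the additive white Gaussian noise, in
#'   signal units (carrier amplitude defaults to 1).
#' @param amplitude Carrier amplitude.
#' @param freq_hz Carrier frequency for channels not mentioned in `pairs`.
#' @export
coupling_spec <- function(pairs = NULL, noise_sd = 0.1, amplitude = 1,
                          freq_hz = 10) {
  if (is.null(pairs)) {
    pairs <- data.frame(i = integer(), j = integer(),
                        kappa = numeric(), freq_hz = numeric())
  }
  pairs <- as.data.frame(pairs)
  if (is.null(pairs$freq_hz)) pairs$freq_hz <- rep(freq_hz, nrow(pairs))
  req <- c("i", "j", "kappa", "freq_hz")
  if (!all(req %in% names(pairs)))
    stop("`pairs` needs columns i, j, kappa, freq_hz")
  if (nrow(pairs)) {
    if (any(pairs$i == pairs$j))
      stop("channel indices within a coupled pair must be distinct")
    if (any(!is.finite(pairs$kappa)) || any(pairs$kappa < 0))
      stop("kappa must be finite and non-negative")
  }
  structure(list(pairs = pairs, noise_sd = noise_sd, amplitude = amplitude,
                 freq_hz = freq_hz),
            class = "coupling_spec")
}

# union-find used to reject coupling cycles and to propagate path PLV
.forest_paths <- function(n_channels, pairs) {
  # adjacency list of the coupling graph; returns for every channel pair the
  # product of per-edge PLV along the unique path, or NA if not connected
  adj <- vector("list", n_channels)
  rho <- vonmises_plv(pairs$kappa)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    adj[[i]] <- rbind(adj[[i]], c(j, rho[r]))
    adj[[j]] <- rbind(adj[[j]], c(i, rho[r]))
  }
  out <- matrix(NA_real_, n_channels, n_channels)
  for (root in seq_len(n_channels)) {
    # BFS over the coupling forest accumulating products
    seen <- rep(FALSE, n_channels)
    seen[root] <- TRUE
    frontier <- root
    acc <- c(1)
    while (length(frontier)) {
      nf <- integer(); na_ <- numeric()
      for (q in seq_along(frontier)) {
        v <- frontier[q]
        nb <- adj[[v]]
        if (is.null(nb)) next
        for (e in seq_len(nrow(nb))) {
          w <- nb[e, 1]
          if (!seen[w]) {
            seen[w] <- TRUE
            out[root, w] <- acc[q] * nb[e, 2]
            nf <- c(nf, w); na_ <- c(na_, acc[q] * nb[e, 2])
          }
        }
      }
      frontier <- nf; acc <- na_
    }
  }
  out
}

#' Generate phase-locked multichannel oscillator trials
#'
#' Every channel carries a sinusoid plus white Gaussian noise.  Within a trial
#' each channel's carrier phase is constant; a coupled pair `(i, j)` shares
#' its phase up to an offset drawn from a von Mises distribution with the
#' pair's concentration `kappa`, so the population PLV of the pair is
#' `I1(kappa)/I0(kappa)`.  Channels not linked by any coupling get independent
#' uniform phases and their expected sample PLV is the chance floor
#' [plv_chance_floor()].
#'
#' With `jitter_sampling = "stratified"` (default) the `n_trials` offsets of a
#' coupled pair are the von Mises quantiles at midpoints `(k - 0.5)/n`, in
#' random order, so the realized trial ensemble embodies the nominal coupling
#' strength and downstream checks measure estimator error rather than von
#' Mises sampling noise; `"iid"` draws them independently.
#'
#' @param spec A [coupling_spec()].
#' @param n_channels Number of channels.
#' @param n_trials Number of trials (>= 1).
#' @param fs Sampling rate, Hz.
#' @param duration Trial duration, seconds; `duration * fs >= 64`.
#' @param seed Integer seed; identical seed and spec give identical output.
#' @param jitter_sampling `"stratified"` or `"iid"`.
#' @return A `synthetic_dataset`: list with `trials` (list of channels x time
#'   matrices), `fs`, `channel_labels`, `ground_truth_plv` (symmetric, unit
#'   diagonal), `seed`, `spec`.
#' @export
gen_phase_locked_trials <- function(spec, n_channels, n_trials, fs = 256,
                                    duration = 2, seed = 1,
                                    jitter_sampling = c("stratified", "iid")) {
  stopifnot(inherits(spec, "coupling_spec"), n_trials >= 1)
  jitter_sampling <- match.arg(jitter_sampling)
  n <- round(duration * fs)
  if (n < 64) stop("duration * fs must be at least 64 samples")
  pr <- spec$pairs
  if (nrow(pr)) {
    if (any(pr$i > n_channels | pr$j > n_channels | pr$i < 1 | pr$j < 1))
      stop("coupling pair channel index out of range")
    if (any(pr$freq_hz >= fs / 2))
      stop("carrier frequency at or above Nyquist (", fs / 2, " Hz) rejected")
    # forest check: a cycle would make path ground truth ill-defined
    parent <- seq_len(n_channels)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (r in seq_len(nrow(pr))) {
      a <- find(pr$i[r]); b <- find(pr$j[r])
      if (a == b) stop("coupling pairs must form a forest (no cycles)")
      parent[a] <- b
    }
  }
  if (spec$freq_hz >= fs / 2)
    stop("carrier frequency at or above Nyquist (", fs / 2, " Hz) rejected")
  set.seed(seed)
  tt <- (0:(n - 1)) / fs
  # channel carrier frequencies: pair frequency wins over the default
  freq <- rep(spec$freq_hz, n_channels)
  for (r in seq_len(nrow(pr))) freq[c(pr$i[r], pr$j[r])] <- pr$freq_hz[r]
  # per-trial phase offsets for each coupled pair
  offsets <- matrix(0, nrow(pr), n_trials)
  eff_pr <- pr
  for (r in seq_len(nrow(pr))) {
    k <- pr$kappa[r]
    if (k < 1e-12) {
      # kappa = 0 is no coupling: independent uniform phases (chance floor)
      offsets[r, ] <- NA
      eff_pr$kappa[r] <- 0
    } else if (jitter_sampling == "stratified" && k < 1e6) {
      q <- qvonmises((seq_len(n_trials) - 0.5) / n_trials, k)
      offsets[r, ] <- sample(q)
    } else {
      offsets[r, ] <- rvonmises(n_trials, k)
    }
  }
  # base phase per channel per trial: uniform; coupled channels overwritten by
  # propagation along the coupling forest below
  base_phi <- matrix(runif(n_channels * n_trials, -pi, pi),
                     n_channels, n_trials)
  coupled <- eff_pr[eff_pr$kappa > 0, , drop = FALSE]
  coupled_off <- offsets[eff_pr$kappa > 0, , drop = FALSE]
  phi <- base_phi
  if (nrow(coupled)) {
    for (k in seq_len(n_trials)) {
      # propagate phases along forest edges (each edge processed until fixed;
      # a forest needs at most n_edges sweeps)
      done <- rep(FALSE, nrow(coupled))
      rooted <- rep(FALSE, n_channels)
      # roots: keep base phase for the first endpoint seen in each tree
      for (sweep in seq_len(nrow(coupled))) {
        for (r in which(!done)) {
          i <- coupled$i[r]; j <- coupled$j[r]
          if (!rooted[i] && !rooted[j]) {
            rooted[i] <- TRUE
            phi[j, k] <- phi[i, k] + coupled_off[r, k]
            rooted[j] <- TRUE; done[r] <- TRUE
          } else if (rooted[i] && !rooted[j]) {
            phi[j, k] <- phi[i, k] + coupled_off[r, k]
            rooted[j] <- TRUE; done[r] <- TRUE
          } else if (rooted[j] && !rooted[i]) {
            phi[i, k] <- phi[j, k] - coupled_off[r, k]
            rooted[i] <- TRUE; done[r] <- TRUE
          }
        }
        if (all(done)) break
      }
    }
  }
  trials <- vector("list", n_trials)
  labels <- sprintf("ch%02d", seq_len(n_channels))
  for (k in seq_len(n_trials)) {
    sig <- matrix(0, n_channels, n)
    for (c_ in seq_len(n_channels)) {
      sig[c_, ] <- spec$amplitude * cos(2 * pi * freq[c_] * tt + phi[c_, k]) +
        rnorm(n, 0, spec$noise_sd)
    }
    rownames(sig) <- labels
    trials[[k]] <- sig
  }
  gt <- .forest_paths(n_channels, coupled)
  gt[is.na(gt)] <- plv_chance_floor(n_trials)
  gt <- (gt + t(gt)) / 2  # symmetric by construction; make it exact
  diag(gt) <- 1
  structure(list(trials = trials, fs = fs, channel_labels = labels,
                 ground_truth_plv = gt, seed = seed, spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic phase-locked dataset:", length(x$trials), "trials,",
      nrow(x$trials[[1]]), "channels x", ncol(x$trials[[1]]), "samples @",
      x$fs, "Hz (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Ring lattice adjacency matrix
#'
#' Node `i` is connected to its `k` nearest ring neighbours (`k/2` on each
#' side).  For `k > 2` the mean clustering coefficient has the closed form
#' `3(k - 2) / (4(k - 1))`.
#'
#' @param n Number of nodes.
#' @param k Even neighbour count, `k < n`.
#' @return Binary symmetric adjacency matrix with zero diagonal.
#' @export
gen_ring_lattice <- function(n, k) {
  if (k %% 2 != 0) stop("k must be even for a ring lattice")
  stopifnot(k < n, k >= 0)
  a <- matrix(0L, n, n)
  idx <- seq_len(n)
  for (d in seq_len(k / 2)) {
    j <- ((idx - 1 + d) %% n) + 1
    a[cbind(idx, j)] <- 1L
    a[cbind(j, idx)] <- 1L
  }
  a
}

#' Watts-Strogatz style rewired ring lattice
#'
#' Starts from [gen_ring_lattice()] and rewires each edge with probability `p`
#' to a uniformly chosen non-self, non-duplicate target, preserving the edge
#' count `n k / 2`.
#'
#' @param n,k As [gen_ring_lattice()].
#' @param p Rewiring probability in `[0, 1]`.
#' @param seed Integer seed.
#' @export
gen_ws_smallworld <- function(n, k, p, seed = 1) {
  stopifnot(p >= 0, p <= 1)
  a <- gen_ring_lattice(n, k)
  if (p == 0) return(a)
  set.seed(seed)
  for (d in seq_len(k / 2)) {
    for (i in seq_len(n)) {
      j <- ((i - 1 + d) %% n) + 1
      if (a[i, j] == 1L && runif(1) < p) {
        cand <- which(a[i, ] == 0L)
        cand <- cand[cand != i]
        if (length(cand)) {
          newj <- cand[sample.int(length(cand), 1)]
          a[i, j] <- a[j, i] <- 0L
          a[i, newj] <- a[newj, i] <- 1L
        }
      }
    }
  }
  a
}

#' Erdos-Renyi random graph adjacency matrix
#'
#' Each of the `n(n-1)/2` undirected pairs is connected independently with
#' probability `p`.
#'
#' @param n Number of nodes.
#' @param p Edge probability in `[0, 1]`.
#' @param seed Integer seed.
#' @export
gen_er_random <- function(n, p, seed = 1) {
  stopifnot(p >= 0, p <= 1)
  set.seed(seed)
  a <- matrix(0L, n, n)
  up <- upper.tri(a)
  a[up] <- as.integer(runif(sum(up)) < p)
  a + t(a)
}

#' Write / read an adjacency matrix as TSV
#'
#' @param a Adjacency matrix.
#' @param path File path.
#' @export
write_adjacency_tsv <- function(a, path) {
  utils::write.table(a, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_adjacency_tsv
#' @export
read_adjacency_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}
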