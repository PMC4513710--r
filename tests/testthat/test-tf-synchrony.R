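# Reduced-interference Rihaczek grids, phase differences, PLV, connectivity.

test_that("time marginal equals |s(t)|^2 on random and tonal signals", {
  set.seed(4)
  for (x in list(rnorm(128), tone_trial(128, 128, 16, 0.3)[1, ],
                 rnorm(100), tone_trial(200, 256, 40, 1, 0.5)[1, ])) {
    g <- rid_rihaczek(x, fs = 128)
    target <- Mod(analytic_signal(x))^2
    err <- sqrt(sum((tf_time_marginal(g) - target)^2) / sum(target^2))
    expect_lt(err, 1e-2)
  }
  expect_true(all(Mod(rid_rihaczek(rep(0, 64), 256)$values) == 0))
})

test_that("tonal energy concentrates at the carrier bin", {
  n <- 128
  x <- exp(2i * pi * 32 * (0:(n - 1)) / n)  # bin-32 complex exponential
  g <- rid_rihaczek(x, fs = n)
  m <- Mod(g$values[14:115, ])              # interior time points
  expect_gt(sum(m[, 31:35]) / sum(m), 0.9)  # within +-2 bins of bin 32
})

test_that("grid construction rejects bad inputs", {
  expect_error(rid_rihaczek(c(1, NA, 3, 4, 5, 6, 7, 8)), "non-finite")
  expect_error(rid_rihaczek(rnorm(4)), "8 samples")
  expect_error(rid_rihaczek(rnorm(64), params = rid_params(n_fft = 32)),
               "n_fft")
  expect_error(rid_params(sigma = 0))
})

test_that("phase difference: identity, antisymmetry, constant offset", {
  set.seed(6)
  x <- tone_trial(256, 256, 10, 0.7, 0.05)[1, ]
  y <- tone_trial(256, 256, 10, 0.7 - pi / 4, 0.05)[1, ]
  gx <- rid_rihaczek(x, 256)
  gy <- rid_rihaczek(y, 256)

  pd_self <- phase_difference(gx, gx)
  expect_true(all(abs(pd_self$values) < 1e-12, na.rm = TRUE))

  pd <- phase_difference(gx, gy)
  pd_rev <- phase_difference(gy, gx)
  ok <- !is.na(pd$values)
  expect_true(all(abs((pd$values[ok] + pd_rev$values[ok]) %% (2 * pi))
                  < 1e-9 |
                  abs((pd$values[ok] + pd_rev$values[ok]) %% (2 * pi)
                      - 2 * pi) < 1e-9))
  expect_true(all(pd$values > -pi & pd$values <= pi, na.rm = TRUE))

  # median phase at the carrier bin over interior times recovers the offset
  carrier_col <- which.min(abs(pd$freq_hz - 10))
  med <- median(pd$values[30:220, carrier_col], na.rm = TRUE)
  expect_lt(abs(med - pi / 4), 0.05)

  bad <- rid_rihaczek(rnorm(128), 256)
  expect_error(phase_difference(gx, bad), "axes")
})

test_that("PLV: degenerate cases and the uniform-phase chance floor", {
  set.seed(8)
  x <- rnorm(64)
  pd <- phase_difference(rid_rihaczek(x, 256), rid_rihaczek(rnorm(64), 256))
  one <- plv(list(pd))
  expect_true(all(abs(one$values - 1) < 1e-12, na.rm = TRUE))  # N = 1

  same <- plv(list(pd, pd, pd, pd))                      # identical trials
  expect_true(all(abs(same$values - 1) < 1e-12, na.rm = TRUE))
  expect_error(plv(list()), "empty")

  # i.i.d. uniform phase differences, N = 100: grid-mean PLV at the floor
  mk <- function() {
    structure(list(values = matrix(runif(1000, -pi, pi), 40, 25),
                   time_s = 1:40, freq_hz = 1:25, n_signal = 40),
              class = "phase_diff_grid")
  }
  pv <- plv(replicate(100, mk(), simplify = FALSE))
  expect_true(all(pv$values >= 0 & pv$values <= 1))
  expect_equal(pv$n_trials, 100)
  expect_lt(abs(mean(pv$values) - 0.0886), 0.01)
})

test_that("connectivity recovers strong von Mises coupling", {
  spec <- coupling_spec(data.frame(i = 1, j = 2, kappa = 8, freq_hz = 10))
  ds <- gen_phase_locked_trials(spec, 3, 30, fs = 256, duration = 1,
                                seed = 1)
  cm <- pairwise_connectivity(as_epoch_set(ds, band = "Alpha"))
  expect_equal(cm$weights, t(cm$weights))
  expect_true(all(diag(cm$weights) == 0))
  expect_true(all(cm$weights >= 0 & cm$weights <= 1))
  expect_lt(abs(cm$weights[1, 2] - vonmises_plv(8)), 0.05)
  # uncoupled pairs stay near the chance floor on average across seeds
  unc <- sapply(1:6, function(s) {
    d <- gen_phase_locked_trials(spec, 3, 30, fs = 256, duration = 1,
                                 seed = s)
    w <- pairwise_connectivity(as_epoch_set(d, band = "Alpha"))$weights
    mean(c(w[1, 3], w[2, 3]))
  })
  expect_lt(mean(unc), plv_chance_floor(30) + 0.05)
})

test_that("recovery is robust to the Choi-Williams sigma", {
  spec <- coupling_spec(data.frame(i = 1, j = 2, kappa = 8, freq_hz = 10))
  ds <- gen_phase_locked_trials(spec, 2, 30, fs = 256, duration = 1,
                                seed = 2)
  for (sg in c(0.005, 0.05)) {
    cm <- pairwise_connectivity(as_epoch_set(ds, band = "Alpha"),
                                rid_params(sigma = sg))
    expect_lt(abs(cm$weights[1, 2] - vonmises_plv(8)), 0.05)
  }
})

test_that("a constant phase offset on one channel leaves PLV unchanged", {
  spec <- coupling_spec(data.frame(i = 1, j = 2, kappa = 2, freq_hz = 10))
  ds <- gen_phase_locked_trials(spec, 2, 10, fs = 256, duration = 1,
                                seed = 4)
  w0 <- pairwise_connectivity(as_epoch_set(ds, band = "Alpha"))$weights[1, 2]
  ds$trials <- lapply(ds$trials, function(m) {
    m[2, ] <- Re(exp(1i * 1.1) * analytic_signal(m[2, ]))
    m
  })
  w1 <- pairwise_connectivity(as_epoch_set(ds, band = "Alpha"))$weights[1, 2]
  # the rotated channel is reconstructed through the analytic signal, which
  # is exact only up to DC/Nyquist leakage of the noise
  expect_equal(w1, w0, tolerance = 1e-4)
})

test_that("connectivity agrees with the explicit grid-level PLV route", {
  spec <- coupling_spec(data.frame(i = 1, j = 2, kappa = 4, freq_hz = 10))
  ds <- gen_phase_locked_trials(spec, 2, 5, fs = 256, duration = 0.5,
                                seed = 7)
  es <- as_epoch_set(ds, band = "Alpha")
  cm <- pairwise_connectivity(es, reduce = "mean")
  # independent route through the exported grid operations
  pds <- lapply(ds$trials, function(m) {
    phase_difference(rid_rihaczek(m[1, ], 256), rid_rihaczek(m[2, ], 256))
  })
  pv <- plv(pds)
  n <- 128
  margin <- floor(n * 0.1)
  bins <- which(pv$freq_hz >= 8 & pv$freq_hz <= 15)
  manual <- mean(pv$values[(margin + 1):(n - margin), bins], na.rm = TRUE)
  expect_equal(cm$weights[1, 2], manual, tolerance = 1e-10)
})

test_that("single-trial connectivity warns and a missing band errors", {
  spec <- coupling_spec(data.frame(i = 1, j = 2, kappa = 4, freq_hz = 10))
  ds <- gen_phase_locked_trials(spec, 2, 1, fs = 256, duration = 0.5,
                                seed = 9)
  expect_warning(pairwise_connectivity(as_epoch_set(ds, band = "Alpha")),
                 "single trial")
  es <- as_epoch_set(ds, band = "none", band_limits = c(300, 400))
  expect_error(suppressWarnings(pairwise_connectivity(es)), "no frequency")
})

test_that("connectivity matrices round-trip through TSV + JSON", {
  dir <- withr::local_tempdir()
  spec <- coupling_spec(data.frame(i = 1, j = 2, kappa = 4, freq_hz = 10))
  ds <- gen_phase_locked_trials(spec, 3, 4, fs = 256, duration = 0.5,
                                seed = 5)
  cm <- pairwise_connectivity(as_epoch_set(ds, band = "Alpha",
                                           condition = "chin_tuck",
                                           subject_id = "s07"))
  write_connectivity_tsv(cm, file.path(dir, "c.tsv"), file.path(dir, "c.json"))
  back <- read_connectivity_tsv(file.path(dir, "c.tsv"),
                                file.path(dir, "c.json"))
  expect_equal(back$weights, cm$weights, tolerance = 1e-12)
  expect_identical(back$condition, "chin_tuck")
  expect_identical(back$subject_id, "s07")
  expect_equal(back$n_trials, 4)
})
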