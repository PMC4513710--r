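# Signal conditioning: Fourier resampling, zero-phase elliptic filtering,
# canonical EEG band decomposition and epoch extraction.

#' Multichannel EEG recording container
#'
#' @param samples Channels x time numeric matrix (microvolts).
#' @param fs Sampling rate, Hz.
#' @param channel_labels Character vector, one label per channel.
#' @param reference_label Optional label of the reference electrode.
#' @param band Optional band tag (set by [band_decompose()]).
#' @export
recording <- function(samples, fs, channel_labels = NULL,
                      reference_label = NULL, band = NULL) {
  samples <- as.matrix(samples)
  if (is.null(channel_labels)) {
    channel_labels <- rownames(samples)
    if (is.null(channel_labels))
      channel_labels <- sprintf("ch%02d", seq_len(nrow(samples)))
  }
  stopifnot(fs > 0, length(channel_labels) == nrow(samples))
  if (!all(is.finite(samples))) stop("recording contains non-finite values")
  rownames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs,
                 channel_labels = channel_labels,
                 reference_label = reference_label, band = band),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("EEG recording:", nrow(x$samples), "channels x", ncol(x$samples),
      "samples @", x$fs, "Hz",
      if (!is.null(x$band)) paste0("[", x$band, " band]") else "", "\n")
  invisible(x)
}

#' Drop channels from a recording (e.g. the reference electrode)
#'
#' @param rec A [recording()].
#' @param labels Channel labels to remove.
#' @export
drop_channels <- function(rec, labels) {
  keep <- !(rec$channel_labels %in% labels)
  recording(rec$samples[keep, , drop = FALSE], rec$fs,
            rec$channel_labels[keep], rec$reference_label, rec$band)
}

#' Read / write a recording as CSV matrix plus JSON sidecar
#'
#' The CSV holds the channels x time matrix (no header); the sidecar is a
#' JSON object `{"fs": .., "channels": [..], "reference": ..}`.
#'
#' @param csv_path,json_path File paths.
#' @export
read_recording_csv <- function(csv_path, json_path) {
  m <- as.matrix(utils::read.csv(csv_path, header = FALSE))
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  recording(m, fs = meta$fs, channel_labels = meta$channels,
            reference_label = meta$reference)
}

#' @rdname read_recording_csv
#' @param rec A [recording()].
#' @export
write_recording_csv <- function(rec, csv_path, json_path) {
  utils::write.table(rec$samples, csv_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, channels = rec$channel_labels,
                            reference = rec$reference_label),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(rec)
}

#' Read swallow-segment annotations
#'
#' CSV with header `onset_s,offset_s,condition,subject_id`; onsets must
#' precede offsets and be non-negative.
#'
#' @param path CSV path.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("onset_s", "offset_s", "condition", "subject_id")
  if (!all(req %in% names(ann)))
    stop("annotations need columns ", paste(req, collapse = ", "))
  if (any(ann$onset_s < 0) || any(ann$onset_s >= ann$offset_s))
    stop("annotations must satisfy 0 <= onset < offset")
  ann
}

# ---- filtering internals ----------------------------------------------------

# order-4 elliptic design with 0.5 dB passband ripple, 40 dB stopband; checks
# pole radii and, for band-pass, falls back to a high-pass + low-pass cascade
# when the direct design is unstable (narrow bands at low normalized edges)
.design_ellip <- function(fs, low = NULL, high = NULL, type, order = 4,
                          rp = 0.5, rs = 40) {
  nyq <- fs / 2
  stable <- function(flt) max(Mod(polyroot(rev(flt$a)))) < 1
  if (type == "pass") {
    flt <- tryCatch(signal::ellip(order, rp, rs, c(low, high) / nyq, "pass"),
                    error = function(e) NULL)
    if (!is.null(flt) && stable(flt)) return(list(flt))
    hp <- signal::ellip(order, rp, rs, low / nyq, "high")
    lp <- signal::ellip(order, rp, rs, high / nyq, "low")
    if (!stable(hp) || !stable(lp))
      stop("unstable elliptic filter design for band ", low, "-", high, " Hz")
    return(list(hp, lp))
  }
  if (type == "stop") {
    flt <- signal::ellip(order, rp, rs, c(low, high) / nyq, "stop")
    if (!stable(flt))
      stop("unstable elliptic band-stop design for ", low, "-", high, " Hz")
    return(list(flt))
  }
  stop("unknown filter type")
}

# complex frequency response of one filter at radian frequencies w
.filter_h <- function(flt, w) {
  ew <- exp(-1i * outer(w, seq_along(flt$b) - 1))
  num <- drop(ew %*% flt$b)
  ew <- exp(-1i * outer(w, seq_along(flt$a) - 1))
  num / drop(ew %*% flt$a)
}

# zero-phase application of a filter cascade to each row: the squared
# magnitude response |H(w)|^2 (the exact transfer function of
# forward-backward filtering) is applied on the Fourier grid, which avoids
# the long edge transients of time-domain filtfilt for near-DC elliptic
# poles and is exactly time-reversal symmetric
.filtfilt_rows <- function(m, cascade) {
  n <- ncol(m)
  w <- 2 * pi * (0:(n - 1)) / n
  gain <- rep(1, n)
  for (flt in cascade) gain <- gain * Mod(.filter_h(flt, w))^2
  t(apply(m, 1, function(x) {
    Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
  }))
}

# squared magnitude response (two passes) of a cascade at frequencies f_hz
.realized_response_db <- function(cascade, f_hz, fs) {
  h <- rep(1 + 0i, length(f_hz))
  for (flt in cascade) {
    h <- h * .filter_h(flt, 2 * pi * f_hz / fs)
  }
  40 * log10(Mod(h))  # 2x20: forward-backward doubles the attenuation
}

#' Realized zero-phase frequency response of the package's elliptic designs
#'
#' Returns the gain in dB (forward-backward application, i.e. the squared
#' magnitude response) of the filter used by [bandpass_broad()],
#' [notch_powerline()] or a [band_decompose()] band, measured at `f_hz`.
#'
#' @param f_hz Frequencies at which to evaluate, Hz.
#' @param fs Sampling rate, Hz.
#' @param low,high Band edges, Hz.
#' @param type `"pass"` or `"stop"`.
#' @param order,rp,rs Elliptic design parameters.
#' @export
filter_response_db <- function(f_hz, fs, low, high, type = "pass",
                               order = 4, rp = 0.5, rs = 40) {
  cascade <- .design_ellip(fs, low, high, type, order, rp, rs)
  .realized_response_db(cascade, f_hz, fs)
}

#' Resample a recording to a lower rate (Fourier method)
#'
#' Resamples each channel on the Fourier grid (ideal anti-alias low-pass
#' before decimation); the output has `round(n * target_fs / fs)` samples.
#' Upsampling is rejected.
#'
#' @param rec A [recording()].
#' @param target_fs Target sampling rate, Hz (default 256).
#' @export
resample_to <- function(rec, target_fs = 256) {
  if (target_fs > rec$fs) stop("upsampling rejected: target_fs > fs")
  if (target_fs == rec$fs) return(rec)
  n <- ncol(rec$samples)
  m <- round(n * target_fs / rec$fs)
  out <- t(apply(rec$samples, 1, .fourier_resample, m = m))
  recording(out, target_fs, rec$channel_labels, rec$reference_label, rec$band)
}

.fourier_resample <- function(x, m) {
  n <- length(x)
  X <- stats::fft(x)
  Y <- complex(m)
  half <- min(ceiling(m / 2), ceiling(n / 2))
  Y[1:half] <- X[1:half]
  if (half > 1) Y[m - (1:(half - 1)) + 1] <- X[n - (1:(half - 1)) + 1]
  if (m %% 2 == 0 && m / 2 + 1 <= n) {
    # split energy at the new Nyquist bin to keep the output real
    Y[m / 2 + 1] <- (X[m / 2 + 1] + X[n - m / 2 + 1]) / 2
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Broad elliptic band-pass (0.1-100 Hz), zero phase
#'
#' Order-4 elliptic IIR design with 0.5 dB passband ripple and 40 dB
#' stopband attenuation.  The filter is applied zero phase: the exact
#' squared-magnitude response of forward-backward filtering is applied on
#' the Fourier grid, avoiding the edge transients of the slowly decaying
#' near-DC poles.
#'
#' @param rec A [recording()].
#' @param low,high Band edges, Hz; `high` must be below Nyquist.
#' @param order,rp,rs Elliptic design parameters.
#' @export
bandpass_broad <- function(rec, low = 0.1, high = 100, order = 4, rp = 0.5,
                           rs = 40) {
  if (high >= rec$fs / 2) stop("high edge must be below Nyquist")
  cascade <- .design_ellip(rec$fs, low, high, "pass", order, rp, rs)
  recording(.filtfilt_rows(rec$samples, cascade), rec$fs,
            rec$channel_labels, rec$reference_label, rec$band)
}

#' Elliptic power-line notch (58-62 Hz), zero phase
#'
#' @inheritParams bandpass_broad
#' @param stop_low,stop_high Stop-band edges, Hz.
#' @export
notch_powerline <- function(rec, stop_low = 58, stop_high = 62, order = 4,
                            rp = 0.5, rs = 40) {
  if (stop_high >= rec$fs / 2) stop("stop band must be inside Nyquist")
  cascade <- .design_ellip(rec$fs, stop_low, stop_high, "stop", order, rp, rs)
  recording(.filtfilt_rows(rec$samples, cascade), rec$fs,
            rec$channel_labels, rec$reference_label, rec$band)
}

#' Canonical EEG band definitions
#'
#' Delta 0.1-4, Theta 4-7, Alpha 8-15, Beta 16-31, Gamma 32-100 Hz.  The
#' Delta lower edge and Gamma upper edge are the broadband filter's limits.
#'
#' @return Data frame with columns `band`, `low_hz`, `high_hz`.
#' @export
eeg_bands <- function() {
  data.frame(band = c("Delta", "Theta", "Alpha", "Beta", "Gamma"),
             low_hz = c(0.1, 4, 8, 16, 32),
             high_hz = c(4, 7, 15, 31, 100),
             stringsAsFactors = FALSE)
}

#' Decompose a recording into the five canonical EEG bands
#'
#' Each band is an order-4 elliptic band-pass of the input, applied zero
#' phase.
#'
#' @param rec A [recording()] sampled at 256 Hz (other rates allowed if all
#'   band edges stay below Nyquist).
#' @param bands Band definition data frame as [eeg_bands()].
#' @return Named list of band-tagged [recording()] objects.
#' @export
band_decompose <- function(rec, bands = eeg_bands()) {
  out <- vector("list", nrow(bands))
  names(out) <- bands$band
  for (r in seq_len(nrow(bands))) {
    cascade <- .design_ellip(rec$fs, bands$low_hz[r], bands$high_hz[r], "pass")
    out[[r]] <- recording(.filtfilt_rows(rec$samples, cascade), rec$fs,
                          rec$channel_labels, rec$reference_label,
                          band = bands$band[r])
  }
  out
}

#' Band-filtered per-trial epoch container
#'
#' @param trials List of channels x time matrices of identical shape.
#' @param fs Sampling rate, Hz.
#' @param band Band name (one of [eeg_bands()] or `"broadband"`).
#' @param condition Condition label.
#' @param subject_id Subject identifier.
#' @param channel_labels Channel labels.
#' @param band_limits Numeric `c(low, high)` Hz used for in-band frequency
#'   selection; defaults to the canonical limits of `band`.
#' @export
epoch_set <- function(trials, fs, band = "broadband", condition = "neutral",
                      subject_id = "s01", channel_labels = NULL,
                      band_limits = NULL) {
  stopifnot(length(trials) >= 1)
  dims <- vapply(trials, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all trials must have identical shape")
  if (is.null(channel_labels)) {
    channel_labels <- rownames(trials[[1]])
    if (is.null(channel_labels))
      channel_labels <- sprintf("ch%02d", seq_len(dims[1, 1]))
  }
  if (is.null(band_limits)) {
    bd <- eeg_bands()
    band_limits <- if (band %in% bd$band) {
      unlist(bd[bd$band == band, c("low_hz", "high_hz")], use.names = FALSE)
    } else c(0, fs / 2)
  }
  structure(list(trials = trials, fs = fs, band = band,
                 condition = condition, subject_id = subject_id,
                 channel_labels = channel_labels,
                 band_limits = band_limits),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("Epoch set:", length(x$trials), "trials,",
      nrow(x$trials[[1]]), "channels x", ncol(x$trials[[1]]), "samples @",
      x$fs, "Hz |", x$band, "band |", x$subject_id, "/", x$condition, "\n")
  invisible(x)
}

#' Convert a synthetic dataset to an epoch set
#'
#' @param dataset A `synthetic_dataset` from [gen_phase_locked_trials()].
#' @inheritParams epoch_set
#' @export
as_epoch_set <- function(dataset, band = "broadband", condition = "neutral",
                         subject_id = "s01", band_limits = NULL) {
  epoch_set(dataset$trials, dataset$fs, band, condition, subject_id,
            dataset$channel_labels, band_limits)
}

#' Extract fixed-length epochs around annotated swallows
#'
#' One equal-length window per annotation, centred on the annotation
#' midpoint.  Windows that would exceed the recording bounds are dropped with
#' a warning.  Epochs are grouped by (subject, condition).
#'
#' @param rec A [recording()] (typically band-filtered).
#' @param annotations Data frame as [read_annotations()].
#' @param epoch_length_s Window length in seconds (default 2).
#' @return List of [epoch_set()] objects, one per (subject, condition) with
#'   at least one surviving trial.
#' @export
epoch_extract <- function(rec, annotations, epoch_length_s = 2) {
  n <- ncol(rec$samples)
  w <- round(epoch_length_s * rec$fs)
  half <- w / 2
  centre <- round((annotations$onset_s + annotations$offset_s) / 2 * rec$fs)
  start <- centre - floor(half) + 1
  end <- start + w - 1
  ok <- start >= 1 & end <= n
  if (any(!ok))
    warning(sum(!ok), " epoch(s) dropped: window exceeds recording bounds")
  ann <- annotations[ok, , drop = FALSE]
  start <- start[ok]
  groups <- split(seq_len(nrow(ann)),
                  interaction(ann$subject_id, ann$condition, drop = TRUE))
  out <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    trials <- lapply(idx, function(r) {
      rec$samples[, start[r]:(start[r] + w - 1), drop = FALSE]
    })
    out[[g]] <- epoch_set(trials, rec$fs,
                          band = if (is.null(rec$band)) "broadband" else rec$band,
                          condition = ann$condition[idx[1]],
                          subject_id = ann$subject_id[idx[1]],
                          channel_labels = rec$channel_labels)
  }
  out
}

#' Reject epochs whose peak amplitude exceeds a threshold
#'
#' Simple artifact hook: removes trials whose absolute peak exceeds
#' `threshold` (same units as the recording).  Off unless called.
#'
#' @param epochs An [epoch_set()].
#' @param threshold Peak-amplitude threshold.
#' @export
reject_epochs_by_amplitude <- function(epochs, threshold) {
  keep <- vapply(epochs$trials, function(m) max(abs(m)) <= threshold,
                 logical(1))
  if (!any(keep)) stop("all trials rejected by amplitude threshold")
  if (any(!keep))
    warning(sum(!keep), " trial(s) rejected by amplitude threshold")
  epochs$trials <- epochs$trials[keep]
  epochs
}
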