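#' Downsample a recording
#'
#' Raw recordings are reduced to `target_fs` (200 Hz by default) before any
#' further processing. Integer ratios (1000 -> 200) are anti-alias filtered
#' (8th-order Butterworth low-pass at 80% of the target Nyquist, applied
#' forward-backward) and decimated; non-integer ratios (500 -> 200) are
#' resampled in the Fourier domain (exact for band-limited signals). Event
#' indices are rescaled by the rate ratio and rounded to the nearest
#' sample.
#'
#' @param rec An `eeg_recording`.
#' @param target_fs Target sampling rate, Hz.
#' @return The downsampled `eeg_recording`.
#' @export
downsample <- function(rec, target_fs = 200) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs)
    stop("target_fs (", target_fs, ") exceeds the recording rate (", rec$fs, ")")
  if (target_fs == rec$fs) return(rec)
  ratio <- rec$fs / target_fs
  x <- rec$signal
  if (abs(ratio - round(ratio)) < 1e-9) {
    q <- as.integer(round(ratio))
    bf <- signal::butter(8, 0.8 / ratio, type = "low")
    y <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
    y <- y[, seq(1, ncol(y), by = q), drop = FALSE]
  } else {
    nt <- floor(ncol(x) * target_fs / rec$fs)
    y <- t(apply(x, 1, resample_fft, n_out = nt))
  }
  events <- rec$events
  if (nrow(events)) {
    events$sample <- pmax(1L, pmin(ncol(y),
      as.integer(round((events$sample - 1L) * target_fs / rec$fs)) + 1L))
  }
  eeg_recording(y, target_fs, rec$labels, events, rec$subject_id, rec$hand,
                rec$cohort)
}

# Fourier-domain resampling to n_out samples: truncates the spectrum at
# the new Nyquist frequency and inverse-transforms, which is exact for
# band-limited content.
resample_fft <- function(x, n_out) {
  n <- length(x)
  X <- stats::fft(x)
  Y <- complex(real = numeric(n_out), imaginary = numeric(n_out))
  half <- min(floor(n_out / 2), floor(n / 2))
  Y[1] <- X[1]
  if (half >= 1) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[n_out - (1:half) + 1] <- X[n - (1:half) + 1]
  }
  if (n_out %% 2 == 0 && half == n_out / 2)
    Y[half + 1] <- Re(Y[half + 1])  # keep the Nyquist bin real
  Re(stats::fft(Y, inverse = TRUE)) * n_out / (n * n_out)
}

#' Common average reference
#'
#' Subtracts the across-channel mean potential from every channel at each
#' sample, so the channel mean of the output is zero everywhere. Requires
#' at least two channels.
#'
#' @param rec An `eeg_recording`.
#' @return The re-referenced `eeg_recording`.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$signal) < 2)
    stop("common average reference needs at least 2 channels")
  y <- sweep(rec$signal, 2, colMeans(rec$signal))
  eeg_recording(y, rec$fs, rec$labels, rec$events, rec$subject_id, rec$hand,
                rec$cohort)
}

#' Zero-phase Butterworth band-pass
#'
#' 3rd-order Butterworth band-pass (1-55 Hz by default) applied forward and
#' backward (`signal::filtfilt`), so the net phase response is zero and the
#' effective magnitude response is the squared one-pass response.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band edges, Hz; `high` must be below Nyquist.
#' @param order Filter order of the one-pass prototype.
#' @return The filtered `eeg_recording`.
#' @export
bandpass <- function(rec, low = 1, high = 55, order = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(0 < low && low < high)) stop("need 0 < low < high")
  if (high >= nyq)
    stop("high edge (", high, " Hz) must be below Nyquist (", nyq, " Hz)")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  y <- t(apply(rec$signal, 1, function(ch) signal::filtfilt(bf, ch)))
  eeg_recording(y, rec$fs, rec$labels, rec$events, rec$subject_id, rec$hand,
                rec$cohort)
}

#' Cut a recording into event-locked epochs
#'
#' Healthy data are segmented (-0.5, 0.5) s around key presses; stroke data
#' (-0.5, 1.0) s around cues. Trials whose window would leave the recording
#' are dropped with a warning.
#'
#' @param rec An `eeg_recording`.
#' @param cohort Protocol selecting window and event type; defaults to the
#'   recording's cohort.
#' @param window Optional explicit `(t_start, t_end)` in seconds overriding
#'   the cohort default.
#' @return An object of class `epoch_array`: `data` (trials x channels x
#'   samples), `fs`, `window`, `labels`.
#' @export
epoch_recording <- function(rec, cohort = rec$cohort, window = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(window))
    window <- if (cohort == "healthy") c(-0.5, 0.5) else c(-0.5, 1.0)
  type <- if (cohort == "healthy") "keypress" else "cue"
  ev <- rec$events[rec$events$type == type, , drop = FALSE]
  if (nrow(ev) == 0) stop("no '", type, "' events to epoch around")
  nsamp <- round((window[2] - window[1]) * rec$fs)
  rel0 <- round(window[1] * rec$fs)
  starts <- ev$sample + rel0
  ok <- starts >= 1 & (starts + nsamp - 1) <= ncol(rec$signal)
  if (any(!ok))
    warning(sum(!ok), " trial(s) dropped: epoch window outside the recording")
  starts <- starts[ok]
  if (length(starts) == 0) stop("no usable trials after windowing")
  data <- array(NA_real_, c(length(starts), nrow(rec$signal), nsamp))
  for (i in seq_along(starts))
    data[i, , ] <- rec$signal[, starts[i]:(starts[i] + nsamp - 1)]
  structure(list(data = data, fs = rec$fs, window = window,
                 labels = rec$labels),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_array> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$fs, " Hz, window [", x$window[1], ", ", x$window[2],
      "] s\n", sep = "")
  invisible(x)
}

#' Gamma-band power spectral densities of an epoch array
#'
#' Per trial and channel, the magnitude-squared FFT of the epoch
#' (rectangular window, zero-padded to the next multiple of `fs /
#' resolution` samples so bins fall on exact multiples of `resolution` Hz),
#' restricted to the requested band. The default 30-50 Hz band at 1 Hz
#' resolution yields 21 bins.
#'
#' @param ep An `epoch_array`.
#' @param band `c(low, high)` in Hz, endpoints inclusive.
#' @param resolution Frequency resolution, Hz.
#' @return A `model_input` with `level = "Input_5"`, `width_kind = "psd"`
#'   and `freq_bins`.
#' @export
compute_psd <- function(ep, band = c(30, 50), resolution = 1) {
  stopifnot(inherits(ep, "epoch_array"))
  if (band[2] > ep$fs / 2) stop("band exceeds Nyquist (", ep$fs / 2, " Hz)")
  d <- dim(ep$data)
  if (d[3] / ep$fs < 1 / resolution)
    stop("epoch shorter than 1/resolution seconds")
  block <- ep$fs / resolution
  nfft <- as.integer(ceiling(d[3] / block) * block)
  bins <- seq(band[1], band[2], by = resolution)
  idx <- as.integer(round(bins * nfft / ep$fs)) + 1L
  if (any(abs(bins * nfft / ep$fs - (idx - 1L)) > 1e-6))
    stop("requested bins not representable at this resolution")
  out <- array(NA_real_, c(d[1], d[2], length(bins)))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    x <- c(ep$data[i, j, ], numeric(nfft - d[3]))
    out[i, j, ] <- Mod(stats::fft(x))[idx]^2
  }
  structure(list(level = "Input_5", tensor = out, width_kind = "psd",
                 freq_bins = bins, labels = ep$labels,
                 stages = c("epoch", "psd")),
            class = "model_input")
}

#' @export
print.model_input <- function(x, ...) {
  d <- dim(x$tensor)
  cat("<model_input> ", x$level, " (", x$width_kind, "): ", d[1],
      " trials x ", d[2], " channels x ", d[3], " ",
      if (x$width_kind == "psd") "bins" else "samples",
      "; stages: ", paste(x$stages, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Build one of the five model inputs from a raw recording
#'
#' Applies the preprocessing ladder cumulatively:
#' * `Input_1` - downsampled raw data, epoched (channel x time)
#' * `Input_2` - + common average reference
#' * `Input_3` - + 1-55 Hz zero-phase Butterworth band-pass
#' * `Input_4` - + ICA artifact removal
#' * `Input_5` - + gamma-band (30-50 Hz) PSDs (channel x PSD)
#'
#' The common average reference and ICA operate on the full montage; the
#' channel-set restriction is applied after epoching.
#'
#' @param rec A raw `eeg_recording`.
#' @param level Integer 1-5 or `"Input_1"` .. `"Input_5"`.
#' @param channel_set Optional `channel_set` restricting the channels.
#' @param cohort Protocol for epoching; defaults to the recording's cohort.
#' @param target_fs Rate for the initial downsampling.
#' @param ica_args List of extra arguments for [remove_artifact_components()].
#' @return A `model_input`.
#' @export
build_input <- function(rec, level, channel_set = NULL, cohort = rec$cohort,
                        target_fs = 200, ica_args = list()) {
  if (is.character(level)) level <- as.integer(sub("Input_", "", level))
  stopifnot(level %in% 1:5)
  stages <- character()
  r <- downsample(rec, target_fs); stages <- c(stages, "downsample")
  if (level >= 2) { r <- common_average_reference(r); stages <- c(stages, "car") }
  if (level >= 3) { r <- bandpass(r); stages <- c(stages, "bandpass") }
  if (level >= 4) {
    r <- do.call(remove_artifact_components, c(list(r), ica_args))
    stages <- c(stages, "ica")
  }
  ep <- epoch_recording(r, cohort); stages <- c(stages, "epoch")
  if (!is.null(channel_set)) {
    keep <- match(channel_set$labels, ep$labels)
    if (anyNA(keep)) stop("channel set labels missing from the recording")
    ep$data <- ep$data[, keep, , drop = FALSE]
    ep$labels <- channel_set$labels
    stages <- c(stages, paste0("channels:", channel_set$set_id))
  }
  if (level == 5) {
    out <- compute_psd(ep)
    out$stages <- c(stages, "psd")
    return(out)
  }
  structure(list(level = paste0("Input_", level), tensor = ep$data,
                 width_kind = "time", freq_bins = NULL, labels = ep$labels,
                 stages = stages),
            class = "model_input")
}
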