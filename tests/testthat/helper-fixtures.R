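# Shared fixtures, all generated in code.

# A recording holding pure sinusoids (one per channel) plus optional events.
sine_recording <- function(freqs, fs = 1000, dur = 10, amp = 10,
                           events = NULL, cohort = "healthy") {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- t(sapply(freqs, function(f) amp * sin(2 * pi * f * t)))
  labels <- paste0("ch", seq_along(freqs))
  ev <- if (is.null(events)) data.frame(sample = integer(), type = character())
  else data.frame(sample = events,
                  type = if (cohort == "healthy") "keypress" else "cue")
  eeg_recording(x, fs, labels, ev, cohort = cohort)
}

# FFT amplitude of a sinusoid component.
fft_peak_amp <- function(x, fs, freq) {
  n <- length(x)
  sp <- abs(stats::fft(x))[1:(n %/% 2)] * 2 / n
  freqs <- (seq_len(n %/% 2) - 1) * fs / n
  sp[which.min(abs(freqs - freq))]
}

# Small stroke-cohort synthetic subject (cheap: 29 channels, few trials).
small_subject <- function(n_trials = 4, seed = 7, cohort = "stroke",
                          snr = 5, hands = "right", ...) {
  cfg <- synth_config(cohort, n_trials = n_trials, snr = snr, seed = seed, ...)
  montage <- load_montage(if (cohort == "healthy") "healthy63" else "stroke29")
  set.seed(seed)
  generate_subject(montage, cfg, "s01", hands = hands)
}

# Compact CNN profile for fast tests.
tiny_config <- function(max_epochs = 5, patience = 5, seed = 1,
                        conv_blocks = list(c(1, 4)), dense_sizes = c(8, 3)) {
  model_config(conv_blocks = conv_blocks, dense_sizes = dense_sizes,
               max_epochs = max_epochs, patience = patience, seed = seed)
}

# Exact two-sided Wilcoxon signed-rank p-value by enumerating all 2^n sign
# assignments of the ranked absolute differences (independent oracle).
signed_rank_p_enum <- function(d) {
  n <- length(d)
  stopifnot(n <= 14, all(d != 0))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  min(1, 2 * min(p_low, p_high))
}
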