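test_that("downsampling decimates, rescales events, and preserves tones", {
  rec <- sine_recording(10, fs = 1000, dur = 10,
                        events = c(1001L, 5001L))
  d <- downsample(rec, 200)
  expect_equal(ncol(d$signal), 2000)
  expect_equal(d$fs, 200)
  expect_equal(d$events$sample, c(201L, 1001L))
  expect_equal(fft_peak_amp(d$signal[1, ], 200, 10), 10, tolerance = 0.01)

  # polyphase path for the non-integer 500 -> 200 ratio
  rec5 <- sine_recording(10, fs = 500, dur = 10)
  d5 <- downsample(rec5, 200)
  expect_equal(ncol(d5$signal), 2000)
  expect_equal(fft_peak_amp(d5$signal[1, ], 200, 10), 10, tolerance = 0.01)

  expect_error(downsample(rec5, 2000), "exceeds")
  expect_identical(downsample(rec5, 500), rec5)
})

test_that("common average reference zeroes the channel mean", {
  rec <- eeg_recording(rbind(rep(1, 5), rep(3, 5)), 100, c("a", "b"))
  out <- common_average_reference(rec)
  expect_equal(unname(out$signal), rbind(rep(-1, 5), rep(1, 5)))

  set.seed(1)
  r <- eeg_recording(matrix(rnorm(8 * 100), 8, 100), 100, paste0("c", 1:8))
  car1 <- common_average_reference(r)
  expect_lt(max(abs(colSums(car1$signal))), 1e-9 * max(abs(r$signal)))
  # idempotence
  expect_equal(common_average_reference(car1)$signal, car1$signal,
               tolerance = 1e-12)
  expect_error(common_average_reference(
    eeg_recording(matrix(0, 1, 10), 100, "a")), "2 channels")
})

test_that("band-pass is zero-phase with the squared Butterworth response", {
  fs <- 200
  # DC is in the stopband
  dc <- eeg_recording(matrix(5, 1, 2000), fs, "a")
  expect_lt(abs(mean(bandpass(dc)$signal)), 0.05)

  # 28 Hz passband tone: gain matches the squared analog prototype
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 28 * t)
  rec <- eeg_recording(rbind(x), fs, "a")
  y <- bandpass(rec)$signal[1, ]
  core <- 801:3200  # trim filter edge transients
  gain <- sqrt(mean(y[core]^2) / mean(x[core]^2))
  # analog band-pass prototype |H| at f, squared by bidirectional filtering
  H <- function(f, low = 1, high = 55, n = 3) {
    w <- 2 * pi * f; w0 <- 2 * pi * sqrt(low * high); B <- 2 * pi * (high - low)
    1 / sqrt(1 + ((w^2 - w0^2) / (B * w))^(2 * n))
  }
  expect_equal(gain, H(28)^2, tolerance = 0.02)

  # zero-phase: cross-correlation with the input peaks at lag 0
  x40 <- sin(2 * pi * 40 * t)
  y40 <- bandpass(eeg_recording(rbind(x40), fs, "a"))$signal[1, ]
  cc <- stats::ccf(y40[core], x40[core], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # time-reversal identity of zero-phase filtering (away from the edge
  # transients of the finite forward/backward passes; the 1 Hz high-pass
  # corner has a long impulse response)
  set.seed(3)
  z <- rnorm(6000)
  f1 <- bandpass(eeg_recording(rbind(z), fs, "a"))$signal[1, ]
  f2 <- rev(bandpass(eeg_recording(rbind(rev(z)), fs, "a"))$signal[1, ])
  mid <- 1001:5000
  expect_equal(f1[mid], f2[mid], tolerance = 1e-6)

  expect_error(bandpass(rec, high = 120), "Nyquist")
  expect_error(bandpass(rec, low = 60, high = 50), "low < high")
})

test_that("epoching follows the cohort windows and drops bad trials", {
  fs <- 200
  rec <- sine_recording(5, fs = fs, dur = 20, events = c(300L, 1000L, 2000L))
  ep <- epoch_recording(rec, "healthy")
  expect_equal(dim(ep$data), c(3, 1, 200))
  expect_equal(ep$window, c(-0.5, 0.5))

  recs <- sine_recording(5, fs = fs, dur = 20, events = c(300L, 1000L),
                         cohort = "stroke")
  eps <- epoch_recording(recs, "stroke")
  expect_equal(dim(eps$data), c(2, 1, 300))

  # event 50 samples from the start cannot host a -0.5 s margin
  rec_bad <- sine_recording(5, fs = fs, dur = 20, events = c(50L, 1000L))
  expect_warning(ep2 <- epoch_recording(rec_bad, "healthy"), "dropped")
  expect_equal(dim(ep2$data)[1], 1)

  rec_none <- sine_recording(5, fs = fs, dur = 2, events = 60L)
  expect_error(suppressWarnings(epoch_recording(rec_none, "healthy")),
               "no usable trials")
  # epochs carry the data at the right offsets
  expect_equal(ep$data[2, 1, ], rec$signal[1, 900:1099])
})

test_that("gamma PSDs use exact 1 Hz bins and satisfy Parseval", {
  fs <- 200
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  ep <- structure(list(
    data = array(rep(sin(2 * pi * 40 * t), each = 2), c(2, 1, fs)),
    fs = fs, window = c(-0.5, 0.5), labels = "a"), class = "epoch_array")
  psd <- compute_psd(ep)
  expect_equal(dim(psd$tensor)[3], 21)
  expect_equal(psd$freq_bins, 30:50)
  expect_equal(psd$freq_bins[which.max(psd$tensor[1, 1, ])], 40)

  # quadratic amplitude scaling
  ep2 <- ep; ep2$data <- 2 * ep$data
  expect_equal(compute_psd(ep2)$tensor, 4 * psd$tensor, tolerance = 1e-12)

  # Parseval on the full zero-padded spectrum, and band values match a
  # direct FFT oracle (1.5 s stroke epoch -> padded to 2 s)
  set.seed(2)
  x <- rnorm(300)
  eps <- structure(list(data = array(x, c(1, 1, 300)), fs = fs,
                        window = c(-0.5, 1), labels = "a"),
                   class = "epoch_array")
  nfft <- 400
  spec <- stats::fft(c(x, numeric(nfft - 300)))
  expect_equal(sum(Mod(spec)^2) / nfft, sum(x^2), tolerance = 1e-6)
  oracle <- Mod(spec)[30 * nfft / fs + 1 + 0:20 * nfft / fs / 1]^2
  expect_equal(as.numeric(compute_psd(eps)$tensor[1, 1, ]), oracle,
               tolerance = 1e-9)

  expect_error(compute_psd(ep, band = c(90, 120)), "Nyquist")
})

test_that("the input ladder composes stages cumulatively", {
  s <- small_subject(n_trials = 3, seed = 21, cohort = "stroke")
  rec <- s$recording_right
  m <- load_montage("stroke29")

  i1 <- build_input(rec, 1)
  expect_equal(dim(i1$tensor), c(3, 29, 300))
  expect_equal(i1$level, "Input_1")
  expect_equal(i1$width_kind, "time")
  expect_equal(i1$stages, c("downsample", "epoch"))

  # level 2 equals level 1 with the per-sample channel mean removed
  i2 <- build_input(rec, 2)
  mean_removed <- sweep(i1$tensor, c(1, 3), apply(i1$tensor, c(1, 3), mean))
  expect_equal(i2$tensor, mean_removed, tolerance = 1e-9)

  # level 3 equals epoching the explicitly composed stage chain
  i3 <- build_input(rec, 3)
  manual <- epoch_recording(bandpass(common_average_reference(
    downsample(rec, 200))), "stroke")
  expect_equal(i3$tensor, manual$data, tolerance = 1e-9)

  # level 4 adds seeded ICA; level 5 turns the same chain into PSDs
  set.seed(99); i4 <- build_input(rec, 4)
  set.seed(99); cleaned <- remove_artifact_components(bandpass(
    common_average_reference(downsample(rec, 200))))
  expect_equal(i4$tensor, epoch_recording(cleaned, "stroke")$data,
               tolerance = 1e-9)
  set.seed(99); i5 <- build_input(rec, 5)
  expect_equal(dim(i5$tensor), c(3, 29, 21))
  expect_equal(i5$width_kind, "psd")
  ep4 <- structure(list(data = i4$tensor, fs = 200, window = c(-0.5, 1),
                        labels = i4$labels), class = "epoch_array")
  expect_equal(i5$tensor, compute_psd(ep4)$tensor, tolerance = 1e-9)

  # channel-set restriction applies after epoching, in montage order
  cs <- select_channel_set(m, "Set3", "right")
  i1r <- build_input(rec, 1, cs)
  expect_equal(dim(i1r$tensor), c(3, 5, 300))
  expect_equal(i1r$labels, cs$labels)
  expect_equal(i1r$tensor[, , ], i1$tensor[, match(cs$labels, i1$labels), ])
})
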