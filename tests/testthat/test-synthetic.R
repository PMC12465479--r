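test_that("spatial weights follow the Gaussian scalp kernel", {
  m <- load_montage("healthy63")
  w <- spatial_weights(m$positions["C3", ], m, spatial_sigma = 20)
  expect_equal(unname(w["C3"]), 1)
  expect_true(all(w <= 1))
  expect_equal(names(which.max(w)), "C3")

  # closed form on a two-electrode stub 20 mm apart
  stub <- structure(list(
    name = "stub", labels = c("A", "B"),
    positions = rbind(A = c(0, 0, 0), B = c(20, 0, 0)),
    head_radius = 90), class = "electrode_montage")
  w2 <- spatial_weights(c(0, 0, 0), stub, spatial_sigma = 20)
  expect_equal(unname(w2["B"]), exp(-0.5), tolerance = 1e-12)

  # flat-kernel limit
  w3 <- spatial_weights(m$positions["C3", ], m, spatial_sigma = 1e6)
  expect_true(all(w3 > 0.999))
})

test_that("hotspot sampling is seeded and contralateral with calibrated offset", {
  m <- load_montage("healthy63")
  cfg <- synth_config("healthy")
  set.seed(11); h1 <- sample_hotspot(m, "right", cfg)
  set.seed(11); h2 <- sample_hotspot(m, "right", cfg)
  expect_identical(h1, h2)
  expect_equal(h1$hemisphere, "left")  # right hand -> left hemisphere
  expect_equal(h1$source, "synthetic_truth")

  # degenerate configuration lands exactly on C3
  cfg0 <- synth_config("healthy", hotspot_offset_mean = 0, hotspot_jitter_sd = 0)
  set.seed(1); h0 <- sample_hotspot(m, "right", cfg0)
  expect_equal(c(h0$x, h0$y, h0$z), unname(m$positions["C3", ]),
               tolerance = 1e-9)

  # sampled hotspots stay on the scalp sphere
  set.seed(2)
  ctr <- c(0, 0, -m$head_radius)
  for (i in 1:50) {
    h <- sample_hotspot(m, if (i %% 2) "left" else "right", cfg)
    expect_equal(sqrt(sum((c(h$x, h$y, h$z) - ctr)^2)), m$head_radius,
                 tolerance = 1e-9)
  }
})

test_that("mean hotspot offset from C3/C4 matches the cohort calibration", {
  expect_equal(calibrate_hotspot_offset(synth_config("healthy"), 4000, seed = 3),
               24.31, tolerance = 0.03)
  expect_equal(calibrate_hotspot_offset(synth_config("stroke"), 4000, seed = 3),
               34.96, tolerance = 0.03)
})

test_that("generated recordings follow the cohort protocol", {
  s <- small_subject(n_trials = 4, seed = 7, cohort = "stroke")
  rec <- s$recording_right
  expect_equal(rec$fs, 500)
  expect_equal(nrow(rec$events), 4)
  expect_true(all(rec$events$type == "cue"))
  expect_equal(nrow(rec$signal), 29)
  expect_equal(s$truth_right$hemisphere, "left")
  expect_null(s$recording_left)

  sh <- small_subject(n_trials = 2, seed = 8, cohort = "healthy")
  expect_equal(sh$recording_right$fs, 1000)
  expect_true(all(sh$recording_right$events$type == "keypress"))
  expect_equal(nrow(sh$recording_right$signal), 63)

  # montage/cohort mismatch
  cfg <- synth_config("stroke", n_trials = 2)
  expect_error(generate_subject(load_montage("healthy63"), cfg), "cohort")
})

test_that("cohort generation is deterministic and writes consistent files", {
  cfg <- synth_config("stroke", n_subjects = 2, n_trials = 2, seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(cfg, dir = d1, hands = c("left", "right"))
  generate_cohort(cfg, dir = d2, hands = c("left", "right"))
  csv1 <- readBin(file.path(d1, "hotspots.csv"), raw(), 1e5)
  expect_identical(csv1, readBin(file.path(d2, "hotspots.csv"), raw(), 1e5))
  expect_identical(readBin(file.path(d1, "s02_left.edf"), raw(), 1e7),
                   readBin(file.path(d2, "s02_left.edf"), raw(), 1e7))

  tab <- read_hotspot_table(file.path(d1, "hotspots.csv"))
  expect_equal(nrow(tab), 4)  # 2 subjects x 2 hands
  expect_length(list.files(d1, pattern = "\\.edf$"), 4)
  # truths contralateral to the recorded hand
  expect_true(all(tab$hemisphere[tab$hand == "right"] == "left"))
  expect_true(all(tab$hemisphere[tab$hand == "left"] == "right"))

  # collision protection
  expect_error(generate_cohort(cfg, dir = d1), "overwrite")
  # a written recording round-trips through the EDF reader
  r <- read_recording(file.path(d1, "s01_right.edf"))
  expect_equal(nrow(r$events), 2)
  expect_equal(r$subject_id, "s01")
})

test_that("burst power tracks the planted hotspot and the snr setting", {
  gamma_power_by_channel <- function(s) {
    inp <- build_input(s$recording_right, 1)
    ep <- structure(list(data = inp$tensor, fs = 200, window = c(-0.5, 1),
                         labels = inp$labels), class = "epoch_array")
    psd <- compute_psd(ep)
    apply(psd$tensor, 2, mean)
  }
  m <- load_montage("stroke29")
  s <- small_subject(n_trials = 4, seed = 13, cohort = "stroke", snr = 8)
  pw <- gamma_power_by_channel(s)
  truth <- c(s$truth_right$x, s$truth_right$y, s$truth_right$z)
  d <- sqrt(rowSums(sweep(m$positions, 2, truth)^2))
  # event-locked gamma is strongest at the electrode nearest the hotspot
  expect_equal(s$recording_right$labels[which.max(pw)],
               names(which.min(d)))

  # snr monotonicity at the best channel, same seed
  best <- which.max(pw)
  pows <- vapply(c(0, 2, 8), function(snr_) {
    s2 <- small_subject(n_trials = 4, seed = 13, cohort = "stroke", snr = snr_)
    gamma_power_by_channel(s2)[best]
  }, numeric(1))
  expect_true(all(diff(pows) > 0))

  # snr = 0 plants no event-locked gamma: epoch power comparable to
  # a no-burst recording's overall level (ratio near 1)
  s0 <- small_subject(n_trials = 4, seed = 13, cohort = "stroke", snr = 0)
  pw0 <- gamma_power_by_channel(s0)
  expect_lt(max(pw0) / stats::median(pw0), 3)
})
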