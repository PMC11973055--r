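test_that("preprocess_config validates its arguments", {
  expect_error(preprocess_config(band = c(0, 40)), "band")
  expect_error(preprocess_config(band = c(40, 1)), "band")
  expect_error(preprocess_config(target_fs = 64), "band")
  expect_error(preprocess_config(filter_order = 0), "filter_order")
})

test_that("resampling yields the exact rounded output length", {
  rec <- generate_recording(default_profiles()$control, duration = 3,
                            n_channels = 2, seed = 21)  # 200 Hz, 600 samples
  out <- resample_to_target(rec, 256)
  expect_equal(ncol(out$data), round(600 * 256 / 200))
  expect_equal(out$fs, 256)
  # a non-integer ratio: 777 samples at 200 -> 256 Hz must give round(), not floor()
  x <- sin(2 * pi * 7 * (0:776) / 200)
  expect_length(adeeg:::resample_fourier(x, round(777 * 256 / 200)), 995)
  # already at target: unchanged object
  rec2 <- generate_recording(default_profiles()$ad, duration = 2,
                             n_channels = 1, seed = 3)  # 256 Hz
  expect_identical(resample_to_target(rec2, 256), rec2)
})

test_that("Fourier resampling reproduces a band-limited tone exactly", {
  # 7 Hz tone, 2 s at 200 Hz (integer periods -> periodic, band-limited)
  t200 <- (0:399) / 200
  x <- sin(2 * pi * 7 * t200)
  up <- adeeg:::resample_fourier(x, 512)
  t256 <- (0:511) / 256
  expect_equal(up, sin(2 * pi * 7 * t256), tolerance = 1e-9)
  # and the round trip returns the original signal
  back <- adeeg:::resample_fourier(up, 400)
  expect_equal(back, x, tolerance = 1e-9)
})

test_that("resampling preserves the magnitude spectrum (fidelity > 0.99)", {
  rec <- generate_recording(default_profiles()$control, duration = 10,
                            n_channels = 4, seed = 33)  # 200 Hz
  out <- resample_to_target(rec, 256)
  cors <- check_resampling_fidelity(rec, out)
  expect_length(cors, 4)
  expect_true(all(cors > 0.99))
  # a deliberately broken "resampled" recording triggers the diagnostic
  bad <- out
  set.seed(1)
  bad$data <- matrix(rnorm(length(out$data)), nrow = nrow(out$data))
  expect_message(check_resampling_fidelity(rec, bad), class = "adeeg_diagnostic")
})

test_that("RMS normalization gives unit RMS on every channel", {
  rec <- generate_recording(default_profiles()$ad, duration = 4,
                            n_channels = 3, seed = 8)
  out <- rms_normalize(rec)
  expect_equal(sqrt(rowMeans(out$data^2)), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  flat <- rec
  flat$data[2, ] <- 0
  expect_error(rms_normalize(flat), "zero-RMS")
})

test_that("mean removal centers every channel at exactly zero", {
  rec <- generate_recording(default_profiles()$control, duration = 4,
                            n_channels = 3, seed = 8)
  rec$data <- rec$data + 5  # a gross offset
  out <- remove_mean(rec)
  expect_equal(rowMeans(out$data), rep(0, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the band-pass keeps in-band tones and rejects out-of-band tones", {
  t <- (0:(16 * 256 - 1)) / 256
  data <- rbind(sin(2 * pi * 10 * t),   # passband
                sin(2 * pi * 60 * t),   # above 40 Hz
                sin(2 * pi * 0.2 * t))  # below 1 Hz
  rec <- eeg_recording(data, fs = 256)
  out <- bandpass_filter(rec)
  mid <- 513:(16 * 256 - 512)  # interior, away from filtfilt edge transients
  rms <- sqrt(rowMeans(out$data[, mid]^2))
  expect_gt(rms[1], 0.65)   # ~ sqrt(1/2), attenuated little
  expect_lt(rms[2], 0.01)
  expect_lt(rms[3], 0.01)
  # upper edge must stay below Nyquist
  lowfs <- eeg_recording(data[, 1:300], fs = 64)
  expect_error(bandpass_filter(lowfs), "Nyquist")
})

test_that("preprocess_recording chains the stages and records fidelity", {
  rec <- generate_recording(default_profiles()$control, duration = 6,
                            n_channels = 3, seed = 77)  # 200 Hz
  out <- preprocess_recording(rec)
  expect_equal(out$fs, 256)
  expect_equal(ncol(out$data), round(ncol(rec$data) * 256 / 200))
  fid <- attr(out, "resample_fidelity")
  expect_length(fid, 3)
  expect_true(all(fid > 0.99))
  # deterministic
  out2 <- preprocess_recording(rec)
  expect_equal(out$data, out2$data, tolerance = 1e-15)
  # no resampling -> no fidelity attribute
  rec256 <- generate_recording(default_profiles()$ad, duration = 4,
                               n_channels = 2, seed = 5)
  expect_null(attr(preprocess_recording(rec256), "resample_fidelity"))
})
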