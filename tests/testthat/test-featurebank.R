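test_that("windowing produces the documented window count and placement", {
  x <- seq_len(10 * 256) / 256
  ws <- window_signal(x, 256)
  expect_length(ws$windows, 10)
  expect_true(all(lengths(ws$windows) == 256))
  expect_equal(ws$starts, 256 * (0:9))  # 0-based start samples
  expect_equal(ws$times, 0:9)
  expect_equal(ws$windows[[2]], x[257:512])
  # 50% overlap: hop 128, (2560 - 256) / 128 + 1 = 19 windows
  ws2 <- window_signal(x, 256, windowing_config(overlap_fraction = 0.5))
  expect_length(ws2$windows, 19)
  expect_error(window_signal(x[1:5], 256), "window")
  expect_error(windowing_config(overlap_fraction = 1), "overlap")
})

test_that("the feature bank has exactly 43 named metrics in fixed order", {
  fn <- feature_names()
  expect_length(fn, 43)
  expect_false(anyDuplicated(fn) > 0)
  w <- sin(2 * pi * 9 * (0:255) / 256) + rnorm(256, sd = 0.3)
  f <- adeeg:::window_features(w, 256, feature_params())
  expect_identical(names(f), fn)
  expect_true(all(is.finite(f)))
})

test_that("entropies, fractal dimensions and quantiles match brute-force oracles", {
  suite <- oracle_window_suite()
  expect_gte(nrow(suite), 50)
  for (metric in c("sampen", "apen", "perm", "petrosian", "higuchi",
                   "p25", "p50", "p75", "alpha")) {
    expect_equal(suite[[paste0(metric, "_pkg")]],
                 suite[[paste0(metric, "_ref")]],
                 tolerance = 1e-12, label = metric)
  }
})

test_that("closed-form feature values are reproduced", {
  fs <- 256
  t <- (0:(fs - 1)) / fs
  sine <- sin(2 * pi * 4 * t)  # 4 full periods, hits +/-1 exactly
  st <- basic_stat_features(sine)
  expect_equal(st[["crest_factor"]], sqrt(2), tolerance = 1e-12)
  expect_equal(st[["rms"]], sqrt(1 / 2), tolerance = 1e-12)
  expect_equal(st[["mean"]], 0, tolerance = 1e-12)

  # Katz fractal dimension of a straight line is exactly 1
  line <- seq(0, 5, length.out = 120)
  expect_equal(unname(fractal_complexity_features(line, fs)[["katz_fd"]]), 1,
               tolerance = 1e-12)

  # the five band powers partition the total power exactly
  set.seed(99)
  for (i in 1:5) {
    w <- rnorm(256)
    p <- psd_features(w, fs)
    expect_equal(p[["delta_power"]] + p[["theta_power"]] + p[["alpha_power"]] +
                   p[["beta_power"]] + p[["gamma_power"]],
                 p[["total_power"]], tolerance = 1e-12)
  }

  # Hjorth mobility of a sinusoid is 2 sin(pi f / fs) (discrete differences)
  sine8 <- sin(2 * pi * 8 * (0:(2 * fs - 1)) / fs)
  mob <- fractal_complexity_features(sine8, fs)[["hjorth_mobility"]]
  expect_equal(unname(mob), 2 * sin(pi * 8 / fs), tolerance = 1e-2)

  # a 5 Hz cosine crosses zero 10 times per second
  cw <- cos(2 * pi * 5 * t)
  expect_equal(unname(fractal_complexity_features(cw, fs)[["zero_crossings"]]), 10)

  # a pure in-band tone peaks at its own frequency
  fr <- frequency_features(sin(2 * pi * 12 * t), fs)
  expect_equal(fr[["peak_frequency"]], 12)
  expect_equal(fr[["median_frequency"]], 12)
})

test_that("feature invariances hold under amplitude scaling", {
  set.seed(5)
  w <- sin(2 * pi * 6 * (0:255) / 256) + rnorm(256, sd = 0.4)
  params <- feature_params()
  f1 <- adeeg:::window_features(w, 256, params)
  f3 <- adeeg:::window_features(3 * w, 256, params)
  invariant <- c("permutation_entropy", "spectral_entropy", "svd_entropy",
                 "approximate_entropy", "sample_entropy", "crest_factor",
                 "skewness", "kurtosis", "r1", "r2", "r3", "mean_frequency",
                 "median_frequency", "peak_frequency", "zero_crossings",
                 "katz_fd", "higuchi_fd", "dfa_alpha", "petrosian_fd",
                 "hjorth_mobility", "hjorth_complexity")
  expect_equal(f1[invariant], f3[invariant], tolerance = 1e-9)
  # and plain statistics scale linearly / quadratically as they must
  expect_equal(f3[["std"]], 3 * f1[["std"]], tolerance = 1e-12)
  expect_equal(f3[["variance"]], 9 * f1[["variance"]], tolerance = 1e-12)
  expect_equal(f3[["total_power"]], 9 * f1[["total_power"]], tolerance = 1e-12)
})

test_that("DFA of white noise is close to the theoretical 0.5", {
  set.seed(12)
  alphas <- replicate(30, adeeg:::dfa_alpha(rnorm(512)))
  expect_lt(abs(mean(alphas) - 0.5), 0.1)
})

test_that("degenerate windows produce defined values with a diagnostic", {
  const <- rep(2, 256)
  expect_message(e <- entropy_features(const, 256), class = "adeeg_diagnostic")
  expect_equal(unname(e), rep(0, 6))
  st <- basic_stat_features(const)
  expect_equal(st[["crest_factor"]], 0)
  expect_equal(st[["skewness"]], 0)
  expect_equal(st[["kurtosis"]], 0)
  expect_message(fr <- fractal_complexity_features(const, 256),
                 class = "adeeg_diagnostic")
  expect_equal(unname(fr[c("higuchi_fd", "hjorth_mobility", "hjorth_complexity")]),
               rep(0, 3))
})

test_that("the feature cube has the documented shape and is deterministic", {
  pp <- small_preprocessed()
  cube <- suppressMessages(compute_feature_cube(pp))
  expect_s3_class(cube, "feature_cube")
  expect_equal(dim(cube$values), c(3, 10, 43))
  expect_identical(dimnames(cube$values)[[3]], feature_names())
  expect_identical(dimnames(cube$values)[[1]], pp$channel_names)
  expect_true(all(is.finite(cube$values)))
  cube2 <- suppressMessages(compute_feature_cube(pp))
  expect_identical(cube$values, cube2$values)
})

test_that("feature cubes round-trip through the long CSV format", {
  pp <- small_preprocessed()
  cube <- suppressMessages(compute_feature_cube(pp))
  path <- tempfile(fileext = ".csv")
  write_feature_cube_csv(cube, path)
  back <- read_feature_cube_csv(path)
  expect_equal(back$subject_id, cube$subject_id)
  expect_equal(back$group, cube$group)
  expect_equal(back$channel_names, cube$channel_names)
  expect_equal(back$values, cube$values, tolerance = 1e-12, ignore_attr = TRUE)
  unlink(path)
})
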