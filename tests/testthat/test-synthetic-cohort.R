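test_that("recording generation is deterministic and validated", {
  prof <- default_profiles()$ad
  r1 <- generate_recording(prof, duration = 4, n_channels = 3, seed = 9)
  r2 <- generate_recording(prof, duration = 4, n_channels = 3, seed = 9)
  expect_identical(r1$data, r2$data)
  r3 <- generate_recording(prof, duration = 4, n_channels = 3, seed = 10)
  expect_false(identical(r1$data, r3$data))
  expect_equal(dim(r1$data), c(3, 4 * prof$sampling_rate))
  expect_true(all(is.finite(r1$data)))
  expect_error(generate_recording(prof, duration = 1), "duration")
  expect_error(generate_recording(prof, duration = 4, n_channels = 0), "n_channels")
})

test_that("profile invariants are enforced", {
  expect_error(group_profile("x", c(0, 0, 0, 0, 0), 256), "band_weights")
  expect_error(group_profile("x", c(1, 1, 1, 1, -1), 256), "band_weights")
  expect_error(group_profile("x", c(1, 1, 1, 1, 1), 60), "sampling_rate")
})

test_that("a single-band profile concentrates its power in that band", {
  prof <- group_profile("alpha_only", c(delta = 0, theta = 0, alpha = 1,
                                        beta = 0, gamma = 0),
                        sampling_rate = 256, snr = Inf)
  rec <- generate_recording(prof, duration = 8, n_channels = 1, seed = 5)
  x <- rec$data[1, ]
  alpha <- oracle_band_power(x, 256, 8, 13)
  total <- oracle_band_power(x, 256, 1, 40, include_upper = TRUE)
  expect_gt(alpha / total, 0.9)
  # the feature bank sees the same dominance; a single 1-s window has only
  # 1 Hz resolution, so leakage into neighboring bins lowers the ratio
  f <- psd_features(x[1:256], 256)
  expect_gt(f[["alpha_power"]] / f[["total_power"]], 0.6)
  expect_gt(f[["alpha_power"]],
            max(f[["delta_power"]], f[["theta_power"]],
                f[["beta_power"]], f[["gamma_power"]]))
})

test_that("AD-like profiles have higher theta/alpha power than control-like", {
  profs <- default_profiles()
  ratios <- vapply(1:20, function(s) {
    ad <- generate_recording(profs$ad, duration = 4, n_channels = 1, seed = s)
    co <- generate_recording(profs$control, duration = 4, n_channels = 1, seed = s)
    th_ad <- oracle_band_power(ad$data[1, ], ad$fs, 4, 8)
    al_ad <- oracle_band_power(ad$data[1, ], ad$fs, 8, 13)
    th_co <- oracle_band_power(co$data[1, ], co$fs, 4, 8)
    al_co <- oracle_band_power(co$data[1, ], co$fs, 8, 13)
    (th_ad / al_ad) - (th_co / al_co)
  }, 0)
  # theta/alpha ratio strictly greater for the AD-like profile, every seed
  expect_true(all(ratios > 0))
})

test_that("cohort generation respects counts, rates, ids and determinism", {
  spec <- cohort_spec(n_per_group = 7, duration = 2, n_channels = 4, seed = 3)
  recs <- generate_cohort(spec)
  expect_length(recs, 21)
  groups <- vapply(recs, `[[`, "", "group")
  expect_equal(unname(table(groups)[c("control", "mci", "ad")]),
               rep(7L, 3), ignore_attr = TRUE)
  fs <- vapply(recs, function(r) r$fs, 0)
  expect_true(all(fs[groups == "control"] == 200))
  expect_true(all(fs[groups %in% c("mci", "ad")] == 256))
  expect_false(anyDuplicated(vapply(recs, `[[`, "", "subject_id")) > 0)
  recs2 <- generate_cohort(spec)
  expect_identical(lapply(recs, `[[`, "data"), lapply(recs2, `[[`, "data"))
})

test_that("recording CSV round-trips through the writer/reader", {
  rec <- generate_recording(default_profiles()$control, duration = 2,
                            n_channels = 2, seed = 1, subject_id = "rt_01")
  path <- tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$group, rec$group)
  expect_equal(back$subject_id, rec$subject_id)
  expect_equal(back$channel_names, rec$channel_names)
  expect_equal(back$data, rec$data, tolerance = 1e-12, ignore_attr = TRUE)
  unlink(path)
})
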