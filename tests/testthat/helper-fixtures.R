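# Shared fixtures, built lazily and cached for the whole test run.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a small preprocessed patient-like recording for feature-level tests
small_preprocessed <- function() {
  fixture("small_pp", function() {
    rec <- generate_recording(default_profiles()$ad, duration = 10,
                              n_channels = 3, seed = 101)
    suppressMessages(preprocess_recording(rec))
  })
}

# small hand-built compressed vectors for dataset/classifier tests:
# two groups separated by `sep` on every column
fake_vectors <- function(n_per = 7, p = 24, sep = 3, seed = 1,
                         groups = c("g0", "g1")) {
  set.seed(seed)
  cols <- paste0("c", seq_len(p))
  mk <- function(id, group, mu) {
    structure(list(subject_id = id, group = group,
                   values = rnorm(p, mean = mu),
                   column_names = cols),
              class = "compressed_vector")
  }
  c(lapply(seq_len(n_per), function(i) mk(paste0("a", i), groups[1], 0)),
    lapply(seq_len(n_per), function(i) mk(paste0("b", i), groups[2], sep)))
}

# >= 50 random short windows plus genuine preprocessed EEG windows, with
# package features and brute-force oracle values computed side by side
oracle_window_suite <- function() {
  fixture("oracle_suite", function() {
    params <- feature_params()
    wins <- list()
    set.seed(314)
    for (i in 1:52) {  # random short windows, varied length and character
      n <- sample(60:160, 1)
      f0 <- runif(1, 2, 30)
      wins[[i]] <- sin(2 * pi * f0 * (0:(n - 1)) / 256) * runif(1, 0.5, 3) +
        rnorm(n, sd = runif(1, 0.1, 1.5))
    }
    pp <- small_preprocessed()
    for (ch in 1:3) {  # a few genuine preprocessed EEG windows
      ws <- window_signal(pp$data[ch, ], pp$fs)
      wins[[length(wins) + 1]] <- ws$windows[[1]]
      wins[[length(wins) + 1]] <- ws$windows[[5]]
    }
    rows <- lapply(wins, function(w) {
      f <- suppressMessages(adeeg:::window_features(w, 256, params))
      r <- params$entropy_tolerance_r * adeeg:::pop_sd(w)
      data.frame(
        n = length(w),
        sampen_pkg = f[["sample_entropy"]], sampen_ref = oracle_sampen(w, 2, r),
        apen_pkg = f[["approximate_entropy"]], apen_ref = oracle_apen(w, 2, r),
        perm_pkg = f[["permutation_entropy"]], perm_ref = oracle_perm_entropy(w, 3, 1),
        petrosian_pkg = f[["petrosian_fd"]], petrosian_ref = oracle_petrosian(w),
        higuchi_pkg = f[["higuchi_fd"]], higuchi_ref = oracle_higuchi(w, 10),
        p25_pkg = f[["p25"]], p25_ref = oracle_quantile7(w, 0.25),
        p50_pkg = f[["p50"]], p50_ref = oracle_quantile7(w, 0.50),
        p75_pkg = f[["p75"]], p75_ref = oracle_quantile7(w, 0.75),
        alpha_pkg = f[["alpha_power"]], alpha_ref = oracle_band_power(w, 256, 8, 13)
      )
    })
    do.call(rbind, rows)
  })
}

# the full study-scale cohort: 7 control-like + 7 AD-like subjects, 19
# channels, 60-s recordings -> normalized 14 x 8170 pairwise matrix
study_pair <- function() {
  fixture("study_pair", function() {
    profs <- default_profiles()[c("control", "ad")]
    spec <- cohort_spec(n_per_group = 7, duration = 60, n_channels = 19,
                        seed = 42, profiles = profs)
    t0 <- Sys.time()
    recs <- generate_cohort(spec)
    vectors <- suppressMessages(lapply(recs, function(r) {
      compress_cube(compute_feature_cube(preprocess_recording(r)))
    }))
    elapsed <- as.numeric(Sys.time() - t0, units = "secs")
    ds <- suppressMessages(minmax_normalize(build_pairwise(vectors, "control", "ad")))
    list(vectors = vectors, dataset = ds, elapsed_build = elapsed)
  })
}
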