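test_that("stratified folds are disjoint, exhaustive and balanced", {
  ds <- minmax_normalize(build_pairwise(fake_vectors(), "g0", "g1"))
  folds <- make_folds(ds, cv_config(n_folds = 7, shuffle_seed = 3))
  expect_length(folds, 7)
  tests <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:14)          # exhaustive, disjoint
  for (k in 1:7) {
    expect_equal(sort(ds$y[tests[[k]]]), c(0L, 1L))  # one subject per class
    expect_equal(sort(c(folds[[k]]$train, folds[[k]]$test)), 1:14)
  }
  # deterministic given the seed, different across seeds
  folds2 <- make_folds(ds, cv_config(n_folds = 7, shuffle_seed = 3))
  expect_identical(folds, folds2)
  expect_error(make_folds(ds, cv_config(n_folds = 8)), "class size")
})

test_that("confusion metrics follow the report formulas exactly", {
  m <- confusion_metrics(tp = 3, tn = 4, fp = 1, fn = 2)
  expect_identical(m[["accuracy"]], 7 / 10)
  expect_identical(m[["recall"]], 3 / 5)
  expect_identical(m[["precision"]], 3 / 4)
  expect_identical(m[["f1"]], 2 * (3 / 4) * (3 / 5) / (3 / 4 + 3 / 5))
  expect_identical(m[["specificity"]], 4 / 5)
  # zero denominators are reported as 0, not NaN
  z <- confusion_metrics(tp = 0, tn = 5, fp = 0, fn = 5)
  expect_identical(z[["recall"]], 0)
  expect_identical(z[["precision"]], 0)
  expect_identical(z[["f1"]], 0)
  expect_identical(confusion_metrics(0, 0, 0, 0)[["accuracy"]], 0)
})

test_that("pooled AUC behaves correctly on canonical score patterns", {
  y <- c(0, 0, 0, 1, 1, 1)
  expect_equal(adeeg:::pooled_auc(y, c(1, 2, 3, 4, 5, 6)), 1)
  expect_equal(adeeg:::pooled_auc(y, c(6, 5, 4, 3, 2, 1)), 0)
  expect_equal(adeeg:::pooled_auc(y, c(1, 4, 2, 3, 5, 6)), 8 / 9)
  # rank-based: invariant under any strictly monotone transform
  s <- c(0.1, 0.9, 0.3, 0.5, 0.8, 0.95)
  expect_equal(adeeg:::pooled_auc(y, s), adeeg:::pooled_auc(y, exp(4 * s)))
  # constant scores fall back to 0.5 with a diagnostic
  expect_message(a <- adeeg:::pooled_auc(y, rep(1, 6)),
                 class = "adeeg_diagnostic")
  expect_equal(a, 0.5)
})

test_that("the roster is fixed and run_cv validates its classifier name", {
  expect_length(classifier_roster(), 15)
  expect_false(anyDuplicated(classifier_roster()) > 0)
  ds <- minmax_normalize(build_pairwise(fake_vectors(), "g0", "g1"))
  expect_error(run_cv(ds, "perceptron"), "arg")
})

test_that("every classifier separates a well-separated pair", {
  ds <- minmax_normalize(build_pairwise(fake_vectors(sep = 4, seed = 2),
                                        "g0", "g1"))
  for (clf in c("adaboost", "decision_tree", "knn", "lda",
                "logistic_regression", "gaussian_nb", "svm", "sgd", "mlp")) {
    res <- suppressMessages(run_cv(ds, clf))
    expect_null(res$error)
    expect_gte(res$metrics[["accuracy"]], 0.9)
    expect_gte(res$metrics[["auc"]], 0.9)
  }
})

test_that("run_cv pools predictions into a complete confusion matrix", {
  ds <- minmax_normalize(build_pairwise(fake_vectors(seed = 4), "g0", "g1"))
  res <- suppressMessages(run_cv(ds, "knn"))
  expect_equal(sum(res$confusion), length(ds$y))
  expect_true(all(!is.na(res$predictions)))
  expect_equal(res$pair, c("g0", "g1"))
  m <- confusion_metrics(res$confusion[["tp"]], res$confusion[["tn"]],
                         res$confusion[["fp"]], res$confusion[["fn"]])
  expect_equal(unname(res$metrics[names(m)]), unname(m))
  # deterministic under a fixed configuration, also for stochastic learners
  r1 <- suppressMessages(run_cv(ds, "bagging"))
  r2 <- suppressMessages(run_cv(ds, "bagging"))
  expect_identical(r1$metrics, r2$metrics)
})

test_that("fold-internal normalization is available and leak-free", {
  ds <- build_pairwise(fake_vectors(seed = 6), "g0", "g1")  # un-normalized
  res <- suppressMessages(run_cv(ds, "lda", normalize_within_folds = TRUE))
  expect_null(res$error)
  expect_gte(res$metrics[["accuracy"]], 0.9)
})

test_that("run_all reports one row per pair and classifier and picks a best", {
  ds <- minmax_normalize(build_pairwise(fake_vectors(seed = 8), "g0", "g1"))
  roster <- c("knn", "lda", "decision_tree")
  rep_ <- suppressMessages(run_all(list(ds), roster = roster))
  expect_s3_class(rep_, "classification_report")
  expect_equal(nrow(rep_$table), 3)
  expect_identical(rep_$table$classifier, roster)
  expect_true(all(rep_$table$pair == "g0_vs_g1"))
  expect_true(rep_$best$classifier %in% roster)
  expect_equal(rep_$best$accuracy, max(rep_$table$accuracy))
  path <- tempfile(fileext = ".csv")
  write_report_csv(rep_, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$accuracy, rep_$table$accuracy, tolerance = 1e-12)
  unlink(path)
})

test_that("the end-to-end pipeline wrapper composes all stages", {
  profs <- default_profiles()[c("control", "ad")]
  spec <- cohort_spec(n_per_group = 2, duration = 4, n_channels = 2, seed = 15,
                      profiles = profs)
  recs <- generate_cohort(spec)
  out <- suppressMessages(run_pipeline(recs, cv = cv_config(n_folds = 2),
                                       roster = c("knn", "lda")))
  expect_length(out$vectors, 4)
  expect_length(out$datasets, 1)
  expect_equal(dim(out$datasets[[1]]$X), c(4, 2 * 43 * 10))
  expect_equal(nrow(out$report$table), 2)
})
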