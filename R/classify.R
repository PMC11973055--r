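#' The canonical 15-classifier roster
#'
#' The fixed roster of classifiers used for pairwise discrimination, with
#' frozen hyperparameters (library defaults where a single-library default
#' exists; the support-vector machine uses an RBF kernel with
#' `gamma = 1/n_features`, the "auto" width). Stochastic learners draw their
#' seeds from the cross-validation seed.
#'
#' @return Character vector of the 15 canonical classifier names.
#' @export
classifier_roster <- function() {
  c("adaboost", "bagging", "decision_tree", "extra_trees", "gaussian_nb",
    "gaussian_process", "gradient_boosting", "knn", "lda",
    "logistic_regression", "logistic_regression_cv", "mlp", "random_forest",
    "sgd", "svm")
}

# ---- individual fit/predict wrappers -------------------------------------
# Each returns list(pred = integer 0/1 vector, score = numeric vector where
# larger means "more class 1", or NULL when no continuous score exists).

fit_predict <- function(name, Xtr, ytr, Xte, seed) {
  set.seed(seed)
  switch(name,
    adaboost = fp_adaboost(Xtr, ytr, Xte),
    bagging = fp_bagging(Xtr, ytr, Xte),
    decision_tree = fp_tree(Xtr, ytr, Xte),
    extra_trees = fp_extra_trees(Xtr, ytr, Xte, seed),
    gaussian_nb = fp_gaussian_nb(Xtr, ytr, Xte),
    gaussian_process = fp_gaussian_process(Xtr, ytr, Xte),
    gradient_boosting = fp_xgboost(Xtr, ytr, Xte, seed),
    knn = fp_knn(Xtr, ytr, Xte),
    lda = fp_lda(Xtr, ytr, Xte),
    logistic_regression = fp_logreg(Xtr, ytr, Xte),
    logistic_regression_cv = fp_logreg_cv(Xtr, ytr, Xte, seed),
    mlp = fp_mlp(Xtr, ytr, Xte),
    random_forest = fp_random_forest(Xtr, ytr, Xte),
    sgd = fp_sgd(Xtr, ytr, Xte),
    svm = fp_svm(Xtr, ytr, Xte),
    stop("unknown classifier: ", name)
  )
}

score_to_pred <- function(score, cut = 0.5) as.integer(score > cut)

# compiled greedy CART (gini, sample weights); formula-based tree engines
# cannot digest 8170-column design matrices
cart <- function(Xtr, ytr, Xte, w = rep(1 / nrow(Xtr), nrow(Xtr)),
                 max_depth = 25L) {
  .cart_fit_predict(Xtr, as.integer(ytr), w, Xte, as.integer(max_depth))
}

# discrete AdaBoost (SAMME) over depth-1 trees, 50 rounds
fp_adaboost <- function(Xtr, ytr, Xte, rounds = 50) {
  n <- nrow(Xtr)
  w <- rep(1 / n, n)
  yy <- ifelse(ytr == 1, 1, -1)
  F_te <- numeric(nrow(Xte))
  for (t in seq_len(rounds)) {
    fit <- cart(Xtr, ytr, Xte, w = w, max_depth = 1L)
    htr <- ifelse(fit$train_p1 > 0.5, 1, -1)
    hte <- ifelse(fit$test_p1 > 0.5, 1, -1)
    err <- sum(w[htr != yy])
    if (err <= 0) {  # perfect stump: take it with a large finite weight
      F_te <- F_te + 10 * hte
      break
    }
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    w <- w * exp(-alpha * yy * htr)
    w <- w / sum(w)
    F_te <- F_te + alpha * hte
  }
  list(pred = as.integer(F_te > 0), score = F_te)
}

# bootstrap-aggregated fully grown trees, 10 rounds
fp_bagging <- function(Xtr, ytr, Xte, rounds = 10) {
  p1 <- rowMeans(vapply(seq_len(rounds), function(b) {
    idx <- sample.int(nrow(Xtr), replace = TRUE)
    while (length(unique(ytr[idx])) < 2) idx <- sample.int(nrow(Xtr), replace = TRUE)
    cart(Xtr[idx, , drop = FALSE], ytr[idx], Xte)$test_p1
  }, numeric(nrow(Xte))))
  list(pred = score_to_pred(p1), score = p1)
}

fp_tree <- function(Xtr, ytr, Xte) {
  p1 <- cart(Xtr, ytr, Xte)$test_p1
  list(pred = score_to_pred(p1), score = p1)
}

fp_extra_trees <- function(Xtr, ytr, Xte, seed) {
  fit <- ranger::ranger(x = Xtr, y = factor(ytr, levels = c(0, 1)),
                        num.trees = 100,
                        mtry = max(1, floor(sqrt(ncol(Xtr)))),
                        splitrule = "extratrees", num.random.splits = 1,
                        replace = FALSE, sample.fraction = 1,
                        probability = TRUE, seed = seed, num.threads = 1)
  p1 <- predict(fit, Xte, num.threads = 1)$predictions[, "1"]
  list(pred = score_to_pred(p1), score = p1)
}

fp_gaussian_nb <- function(Xtr, ytr, Xte) {
  fit <- e1071::naiveBayes(Xtr, factor(ytr, levels = c(0, 1)))
  # guard zero within-class standard deviations
  fit$tables <- lapply(fit$tables, function(tb) {
    tb[, 2][tb[, 2] == 0 | !is.finite(tb[, 2])] <- 1e-9
    tb
  })
  p <- predict(fit, Xte, type = "raw")
  p1 <- p[, "1"]
  list(pred = score_to_pred(p1), score = p1)
}

fp_gaussian_process <- function(Xtr, ytr, Xte) {
  # capture.output: kernlab cat()s its automatic sigma estimation note
  junk <- utils::capture.output(
    fit <- suppressWarnings(
      kernlab::gausspr(Xtr, factor(ytr, levels = c(0, 1)), kernel = "rbfdot",
                       type = "classification", prob.model = TRUE)
    )
  )
  p <- kernlab::predict(fit, Xte, type = "probabilities")
  p1 <- p[, "1"]
  list(pred = score_to_pred(p1), score = p1)
}

fp_xgboost <- function(Xtr, ytr, Xte, seed) {
  dtr <- xgboost::xgb.DMatrix(Xtr, label = ytr)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
                  nthread = 1, seed = seed),
    data = dtr, nrounds = 100, verbose = 0
  )
  p1 <- predict(fit, xgboost::xgb.DMatrix(Xte))
  list(pred = score_to_pred(p1), score = p1)
}

fp_knn <- function(Xtr, ytr, Xte, k = 5) {
  k <- min(k, nrow(Xtr))
  pr <- class::knn(Xtr, Xte, factor(ytr, levels = c(0, 1)), k = k, prob = TRUE)
  pwin <- attr(pr, "prob")
  p1 <- ifelse(pr == "1", pwin, 1 - pwin)
  list(pred = as.integer(pr == "1"), score = p1)
}

# LDA after projection onto the training data's principal subspace
# (well-defined at p >> n; equivalent to an SVD-based solver)
fp_lda <- function(Xtr, ytr, Xte) {
  mu <- colMeans(Xtr)
  Xc <- sweep(Xtr, 2, mu)
  sv <- svd(Xc, nu = 0)
  keep <- sv$d > max(sv$d) * 1e-8
  V <- sv$v[, keep, drop = FALSE]
  fit <- suppressWarnings(MASS::lda(Xc %*% V, grouping = factor(ytr, levels = c(0, 1))))
  pr <- predict(fit, sweep(Xte, 2, mu) %*% V)
  p1 <- pr$posterior[, "1"]
  list(pred = as.integer(pr$class == "1"), score = p1)
}

# ridge-penalized logistic regression at a fixed penalty (1/n)
fp_logreg <- function(Xtr, ytr, Xte) {
  # suppressWarnings: glmnet warns about tiny per-class counts by design here
  fit <- suppressWarnings(
    glmnet::glmnet(Xtr, factor(ytr, levels = c(0, 1)), family = "binomial",
                   alpha = 0, lambda = 1 / nrow(Xtr), standardize = FALSE)
  )
  p1 <- as.numeric(predict(fit, Xte, type = "response"))
  list(pred = score_to_pred(p1), score = p1)
}

# ridge logistic regression with the penalty chosen by inner cross-validation
fp_logreg_cv <- function(Xtr, ytr, Xte, seed) {
  set.seed(seed)
  foldid <- as.integer((rank(ytr, ties.method = "first") + sample.int(3, 1)) %% 3) + 1L
  fit <- suppressWarnings(
    glmnet::cv.glmnet(Xtr, factor(ytr, levels = c(0, 1)), family = "binomial",
                      alpha = 0, nfolds = 3, foldid = foldid,
                      standardize = FALSE)
  )
  p1 <- as.numeric(predict(fit, Xte, type = "response", s = "lambda.min"))
  list(pred = score_to_pred(p1), score = p1)
}

# single-hidden-layer ReLU perceptron trained full-batch with Adam on
# cross-entropy (L2 penalty 1e-4, 200 iterations; quasi-Newton trainers
# need memory quadratic in the weight count, prohibitive at p = 8170)
fp_mlp <- function(Xtr, ytr, Xte, hidden = 100, maxit = 200,
                   lr = 1e-3, alpha = 1e-4) {
  n <- nrow(Xtr); p <- ncol(Xtr)
  y <- matrix(ytr, ncol = 1)
  W1 <- matrix(rnorm(p * hidden, sd = sqrt(2 / (p + hidden))), p, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(rnorm(hidden, sd = sqrt(2 / (hidden + 1))), hidden, 1)
  b2 <- 0
  pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  mom <- lapply(pars, function(q) q * 0)
  vel <- lapply(pars, function(q) q * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (it in seq_len(maxit)) {
    A <- sweep(Xtr %*% pars$W1, 2, pars$b1, "+")
    H <- pmax(A, 0)
    z <- H %*% pars$W2 + pars$b2
    pr <- 1 / (1 + exp(-z))
    g <- (pr - y) / n
    gH <- g %*% t(pars$W2)
    gH[A <= 0] <- 0
    grad <- list(W1 = crossprod(Xtr, gH) + alpha * pars$W1,
                 b1 = colSums(gH),
                 W2 = crossprod(H, g) + alpha * pars$W2,
                 b2 = sum(g))
    for (nm in names(pars)) {
      mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grad[[nm]]
      vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grad[[nm]]^2
      mhat <- mom[[nm]] / (1 - beta1^it)
      vhat <- vel[[nm]] / (1 - beta2^it)
      pars[[nm]] <- pars[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  Hte <- pmax(sweep(Xte %*% pars$W1, 2, pars$b1, "+"), 0)
  p1 <- as.numeric(1 / (1 + exp(-(Hte %*% pars$W2 + pars$b2))))
  list(pred = score_to_pred(p1), score = p1)
}

fp_random_forest <- function(Xtr, ytr, Xte) {
  fit <- randomForest::randomForest(Xtr, factor(ytr, levels = c(0, 1)),
                                    ntree = 500)
  p1 <- predict(fit, Xte, type = "prob")[, "1"]
  list(pred = score_to_pred(p1), score = p1)
}

# linear hinge-loss learner trained by stochastic (sub)gradient descent
# (Pegasos-style schedule, L2 penalty 1e-4)
fp_sgd <- function(Xtr, ytr, Xte, lambda = 1e-4, epochs = 100) {
  n <- nrow(Xtr)
  yy <- ifelse(ytr == 1, 1, -1)
  wv <- numeric(ncol(Xtr)); b <- 0
  t <- 0
  for (ep in seq_len(epochs)) {
    for (i in sample.int(n)) {
      t <- t + 1
      eta <- 1 / (lambda * (t + 1 / lambda))
      margin <- yy[i] * (sum(wv * Xtr[i, ]) + b)
      wv <- (1 - eta * lambda) * wv
      if (margin < 1) {
        wv <- wv + eta * yy[i] * Xtr[i, ]
        b <- b + eta * yy[i]
      }
    }
  }
  s <- as.numeric(Xte %*% wv + b)
  list(pred = as.integer(s > 0), score = s)
}

# RBF support-vector machine with the "auto" kernel width (gamma = 1/p)
fp_svm <- function(Xtr, ytr, Xte) {
  fit <- e1071::svm(Xtr, factor(ytr, levels = c(0, 1)), kernel = "radial",
                    gamma = 1 / ncol(Xtr), cost = 1, scale = FALSE)
  pr <- predict(fit, Xte, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # orient the decision value so larger favors class "1"
  s <- if (startsWith(colnames(dv)[1], "1")) dv[, 1] else -dv[, 1]
  list(pred = as.integer(pr == "1"), score = as.numeric(s))
}

# ---- cross-validation ----------------------------------------------------

#' Cross-validation configuration
#'
#' @param n_folds Number of folds (default 7, matching the number of
#'   recordings per class in the balanced design).
#' @param stratified Stratify folds by class (default `TRUE`).
#' @param shuffle_seed Integer seed for the fold assignment and for all
#'   stochastic classifiers.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(n_folds = 7, stratified = TRUE, shuffle_seed = 1) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  structure(list(n_folds = as.integer(n_folds), stratified = isTRUE(stratified),
                 shuffle_seed = as.integer(shuffle_seed)),
            class = "cv_config")
}

#' Build stratified cross-validation folds
#'
#' Each class's indices are shuffled with the configured seed and dealt
#' round-robin across folds, so with 7 + 7 subjects and 7 folds every test
#' fold holds exactly one subject per class. Folds are disjoint and cover
#' all subjects.
#'
#' @param ds A [build_pairwise()] dataset.
#' @param cfg A [cv_config()].
#' @return List of `list(train, test)` index pairs.
#' @export
make_folds <- function(ds, cfg = cv_config()) {
  stopifnot(inherits(ds, "pairwise_dataset"))
  y <- ds$y
  counts <- table(y)
  if (cfg$n_folds > min(counts)) {
    stop("n_folds (", cfg$n_folds, ") exceeds the smallest class size (",
         min(counts), ")")
  }
  set.seed(cfg$shuffle_seed)
  assign <- integer(length(y))
  if (cfg$stratified) {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      assign[idx] <- rep_len(seq_len(cfg$n_folds), length(idx))
    }
  } else {
    idx <- sample(seq_along(y))
    assign[idx] <- rep_len(seq_len(cfg$n_folds), length(idx))
  }
  lapply(seq_len(cfg$n_folds), function(k) {
    list(train = which(assign != k), test = which(assign == k))
  })
}

#' Classification metrics from confusion counts
#'
#' The standard report formulas: accuracy `(TP+TN)/(TP+TN+FP+FN)`, recall
#' `TP/(TP+FN)`, precision `TP/(TP+FP)`, F1 (harmonic mean of precision and
#' recall; 0 when precision + recall = 0) and specificity `TN/(TN+FP)`.
#' Undefined ratios (zero denominators) are reported as 0.
#'
#' @param tp,tn,fp,fn Pooled confusion counts.
#' @return Named numeric vector with `accuracy`, `recall`, `precision`,
#'   `f1`, `specificity`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  div <- function(a, b) if (b == 0) 0 else a / b
  acc <- div(tp + tn, tp + tn + fp + fn)
  rec <- div(tp, tp + fn)
  prec <- div(tp, tp + fp)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  spec <- div(tn, tn + fp)
  c(accuracy = acc, recall = rec, precision = prec, f1 = f1,
    specificity = spec)
}

pooled_auc <- function(y, score) {
  if (is.null(score) || length(unique(score)) < 2 || any(!is.finite(score))) {
    adeeg_diag("no usable continuous score: AUC set to 0.5")
    return(0.5)
  }
  r <- pROC::roc(response = y, predictor = score, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Cross-validate one classifier on one pairwise dataset
#'
#' Fits the named classifier on each fold's training rows and predicts its
#' test rows; predictions and continuous scores are pooled across folds into
#' a single confusion matrix from which accuracy, recall, precision, F1,
#' specificity and (rank-based) AUC are computed. Class 1 (the second,
#' more-affected group of the pair) is the positive class.
#'
#' @param ds A (normalized) [pairwise_dataset][build_pairwise()].
#' @param classifier One of [classifier_roster()].
#' @param cfg A [cv_config()].
#' @param normalize_within_folds If `TRUE`, min-max extrema are estimated on
#'   each training fold only and applied to its test rows (no leakage);
#'   default `FALSE`, matching whole-matrix normalization done upstream.
#' @return List with `pair`, `classifier`, `metrics` (incl. `auc`),
#'   `confusion` (tp/tn/fp/fn), `predictions`, `scores` and `folds`; or an
#'   entry with an `error` field if the classifier failed on any fold.
#' @export
run_cv <- function(ds, classifier, cfg = cv_config(),
                   normalize_within_folds = FALSE) {
  stopifnot(inherits(ds, "pairwise_dataset"))
  classifier <- match.arg(classifier, classifier_roster())
  folds <- make_folds(ds, cfg)
  pred <- rep(NA_integer_, length(ds$y))
  score <- rep(NA_real_, length(ds$y))
  # generic column names: several backends take formula/data.frame routes
  # that cannot digest the "channel|feature|statistic" labels
  Xall <- ds$X
  colnames(Xall) <- paste0("V", seq_len(ncol(Xall)))
  for (k in seq_along(folds)) {
    tr <- folds[[k]]$train; te <- folds[[k]]$test
    Xtr <- Xall[tr, , drop = FALSE]; Xte <- Xall[te, , drop = FALSE]
    if (normalize_within_folds) {
      lo <- apply(Xtr, 2, min); rng <- apply(Xtr, 2, max) - lo
      rng[rng == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, lo), 2, rng, "/")
      Xte <- pmin(pmax(sweep(sweep(Xte, 2, lo), 2, rng, "/"), 0), 1)
    }
    res <- tryCatch(
      fit_predict(classifier, Xtr, ds$y[tr], Xte,
                  seed = derive_seed(cfg$shuffle_seed, k,
                                     match(classifier, classifier_roster()))),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      return(list(pair = ds$pair, classifier = classifier,
                  error = conditionMessage(res)))
    }
    pred[te] <- res$pred
    if (!is.null(res$score)) score[te] <- res$score
  }
  tp <- sum(pred == 1 & ds$y == 1); tn <- sum(pred == 0 & ds$y == 0)
  fp <- sum(pred == 1 & ds$y == 0); fn <- sum(pred == 0 & ds$y == 1)
  m <- confusion_metrics(tp, tn, fp, fn)
  auc <- if (all(is.na(score))) {
    adeeg_diag("classifier ", classifier, " exposes no continuous score: AUC = 0.5")
    0.5
  } else pooled_auc(ds$y, score)
  list(pair = ds$pair, classifier = classifier,
       metrics = c(m, auc = auc),
       confusion = c(tp = tp, tn = tn, fp = fp, fn = fn),
       predictions = pred, scores = score, folds = folds)
}

#' Run the full classifier roster over pairwise datasets
#'
#' @param datasets List of (normalized) pairwise datasets.
#' @param roster Character vector of classifier names
#'   (default [classifier_roster()]).
#' @param cfg A [cv_config()].
#' @param normalize_within_folds Passed to [run_cv()].
#' @return An object of class `classification_report`: list with `results`
#'   (one [run_cv()] entry per pair x classifier), `table` (a data.frame
#'   with pair, classifier, the six metrics and confusion counts) and
#'   `best` (best classifier per pair by accuracy, ties broken by AUC then
#'   roster order).
#' @export
run_all <- function(datasets, roster = classifier_roster(), cfg = cv_config(),
                    normalize_within_folds = FALSE) {
  if (!length(roster)) stop("empty classifier roster")
  results <- list()
  rows <- list()
  for (ds in datasets) {
    pair_lab <- paste(ds$pair, collapse = "_vs_")
    for (clf in roster) {
      r <- run_cv(ds, clf, cfg, normalize_within_folds)
      results[[paste(pair_lab, clf, sep = ".")]] <- r
      if (is.null(r$error)) {
        rows[[length(rows) + 1]] <- data.frame(
          pair = pair_lab, classifier = clf,
          accuracy = r$metrics[["accuracy"]], recall = r$metrics[["recall"]],
          precision = r$metrics[["precision"]], f1 = r$metrics[["f1"]],
          auc = r$metrics[["auc"]], specificity = r$metrics[["specificity"]],
          tp = r$confusion[["tp"]], tn = r$confusion[["tn"]],
          fp = r$confusion[["fp"]], fn = r$confusion[["fn"]])
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          pair = pair_lab, classifier = clf, accuracy = NA_real_,
          recall = NA_real_, precision = NA_real_, f1 = NA_real_,
          auc = NA_real_, specificity = NA_real_,
          tp = NA_integer_, tn = NA_integer_, fp = NA_integer_,
          fn = NA_integer_)
      }
    }
  }
  tab <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(split(tab, tab$pair), function(d) {
    d <- d[!is.na(d$accuracy), , drop = FALSE]
    if (!nrow(d)) return(NULL)
    d[order(-d$accuracy, -d$auc, match(d$classifier, roster))[1],
      c("pair", "classifier", "accuracy", "auc")]
  }))
  rownames(tab) <- NULL
  structure(list(results = results, table = tab, best = best),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report>\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' Write a classification report as CSV
#'
#' @param report A [run_all()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
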