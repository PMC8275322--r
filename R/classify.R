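#' Seeded stratified train/test split
#'
#' Holds out a class-stratified test set: within each class the samples are
#' shuffled under a seed and `round(n_class * test_fraction)` of them go to
#' the test set, so the class ratio is preserved to within one sample.
#' Deterministic given the label order, fraction and seed.
#'
#' @param labels binary 0/1 vector.
#' @param test_fraction fraction held out (default 0.30).
#' @param seed integer seed.
#' @return A `rawms_split`: list with integer `train_idx`, `test_idx`,
#'   `seed`, `test_fraction`.
#' @export
stratified_split <- function(labels, test_fraction = 0.30, seed = 1L) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (n < 4 || length(unique(labels)) < 2) {
    rawms_stop("rawms_split_error", "need both classes and at least 4 samples")
  }
  if (min(table(labels)) < 2) {
    rawms_stop("rawms_split_error", "each class needs at least 2 members")
  }
  test_idx <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    n_test <- round(length(idx) * test_fraction)
    shuffled <- with_seed(derive_seed(seed, sprintf("split_class_%d", cl)),
                          sample(idx))
    test_idx <- c(test_idx, shuffled[seq_len(n_test)])
  }
  if (length(test_idx) == 0) {
    rawms_stop("rawms_split_error", "test_fraction %g yields an empty test set",
               test_fraction)
  }
  if (length(test_idx) == n) {
    rawms_stop("rawms_split_error", "test_fraction %g leaves no training samples",
               test_fraction)
  }
  test_idx <- sort(test_idx)
  structure(
    list(train_idx = setdiff(seq_len(n), test_idx), test_idx = test_idx,
         seed = as.integer(seed), test_fraction = test_fraction),
    class = "rawms_split"
  )
}

#' Fit a per-feature min-max scaler on training rows
#'
#' Maps each column to `[0, 1]` via `(x - min) / (max - min)` with the
#' statistics learned on the training rows only. A column constant on the
#' training set maps to 0 everywhere — including any test value. Test
#' values outside the training range are NOT clipped and may leave `[0, 1]`.
#'
#' @param train numeric matrix of training rows.
#' @return A `rawms_scaler`.
#' @export
fit_minmax <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) < 2) {
    rawms_stop("rawms_validation_error", "scaler needs at least 2 training rows")
  }
  mins <- apply(train, 2, min)
  maxs <- apply(train, 2, max)
  structure(list(min = mins, range = maxs - mins), class = "rawms_scaler")
}

#' Apply a fitted min-max scaler
#'
#' @param scaler a [fit_minmax()] result.
#' @param values numeric matrix with the same columns as the training data.
#' @return The scaled matrix.
#' @export
apply_scaler <- function(scaler, values) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(scaler$min))
  constant <- scaler$range == 0
  rng <- ifelse(constant, 1, scaler$range)
  out <- sweep(sweep(values, 2, scaler$min, "-"), 2, rng, "/")
  if (any(constant)) out[, constant] <- 0
  out
}

#' Hyperparameter grid for a classifier
#'
#' The shallow grids searched during tuning, in declared order (ties in CV
#' AUC are broken toward the first listed point): logistic regression
#' C in \{0.1, 1, 10, 100\}; SVC the same C values crossed with linear,
#' polynomial and RBF kernels; random forests and gradient boosted trees
#' 100 or 500 trees. `C` is inverse regularization strength.
#'
#' @param classifier one of `"logreg"`, `"svc"`, `"random_forest"`,
#'   `"gradient_boosted_trees"`.
#' @return A data.frame with one row per grid point.
#' @export
hyper_grid <- function(classifier = c("logreg", "svc", "random_forest",
                                      "gradient_boosted_trees")) {
  classifier <- match.arg(classifier)
  switch(classifier,
    logreg = data.frame(C = c(0.1, 1, 10, 100)),
    svc = data.frame(C = rep(c(0.1, 1, 10, 100), each = 3),
                     kernel = rep(c("linear", "poly", "rbf"), 4),
                     stringsAsFactors = FALSE),
    random_forest = data.frame(n_estimators = c(100, 500)),
    gradient_boosted_trees = data.frame(n_estimators = c(100, 500))
  )
}

# Fit one classifier at one grid point; returns a predictor giving, for new
# rows, a continuous ranking score and a class-1 probability. Scores are
# margins for logreg/svc and probabilities for the tree ensembles.
fit_classifier <- function(classifier, params, x, y, seed) {
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- nrow(x)
  if (classifier == "logreg") {
    # ridge-penalized logistic regression; lambda = 1/(n*C) maps the inverse
    # regularization strength C onto glmnet's per-sample penalty scale
    lam <- 1 / (n * params$C)
    fit <- withCallingHandlers(
      glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                     alpha = 0, lambda = lam, standardize = FALSE),
      warning = function(w) {
        # expected on small CV folds; harmless for a fixed-lambda ridge fit
        if (grepl("fewer than 8\\s+observations", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    function(newx) {
      eta <- as.numeric(predict(fit, as.matrix(newx), type = "link"))
      list(score = eta, prob = stats::plogis(eta))
    }
  } else if (classifier == "svc") {
    yf <- factor(y, levels = c(0, 1))
    fit <- with_seed(seed, e1071::svm(
      x, yf, cost = params$C, kernel = params$kernel,
      probability = TRUE, scale = FALSE
    ))
    # decision-value sign depends on which class e1071 saw first; orient on
    # the training data so larger means class 1
    dv_tr <- as.numeric(attr(predict(fit, x, decision.values = TRUE),
                             "decision.values"))
    r_tr <- rank(dv_tr)
    n1 <- sum(y == 1L); n0 <- sum(y == 0L)
    auc_tr <- (sum(r_tr[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    flip <- if (auc_tr >= 0.5) 1 else -1
    function(newx) {
      pr <- predict(fit, as.matrix(newx), decision.values = TRUE,
                    probability = TRUE)
      dv <- as.numeric(attr(pr, "decision.values")) * flip
      pb <- attr(pr, "probabilities")[, "1"]
      list(score = dv, prob = as.numeric(pb))
    }
  } else if (classifier == "random_forest") {
    df <- data.frame(x)
    df$.y <- factor(y, levels = c(0, 1))
    fit <- ranger::ranger(.y ~ ., data = df, num.trees = params$n_estimators,
                          probability = TRUE, seed = seed, num.threads = 1)
    function(newx) {
      p <- predict(fit, data.frame(as.matrix(newx)),
                   num.threads = 1)$predictions[, "1"]
      list(score = as.numeric(p), prob = as.numeric(p))
    }
  } else if (classifier == "gradient_boosted_trees") {
    dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", nthread = 1,
                    seed = seed %% 2147483647),
      data = dtrain, nrounds = params$n_estimators, verbose = 0
    )
    function(newx) {
      p <- predict(fit, xgboost::xgb.DMatrix(as.matrix(newx), nthread = 1))
      list(score = as.numeric(p), prob = as.numeric(p))
    }
  } else {
    rawms_stop("rawms_validation_error", "unknown classifier '%s'", classifier)
  }
}

#' Classification metric suite
#'
#' AUC is the Mann-Whitney statistic on the ranking scores (ties count one
#' half), equivalently the probability that a random positive outscores a
#' random negative. Brier score and log loss are computed from the
#' probabilities (log loss with a 1e-15 probability floor); accuracy, F1,
#' recall, precision and specificity threshold the probability at 0.5; and
#' Youden's J is maximized over all ROC thresholds of the score,
#' `max(TPR - FPR)`.
#'
#' @param scores continuous ranking scores, larger = more class-1.
#' @param probabilities class-1 probabilities in `[0, 1]`.
#' @param labels binary 0/1 labels.
#' @return A `rawms_metric_set` list: `auc`, `brier`, `log_loss`,
#'   `accuracy`, `f1`, `youden`, `recall`, `precision`, `specificity`.
#' @export
#' @examples
#' compute_metrics(c(.9, .3, .5, .1), c(.9, .3, .5, .1), c(1, 1, 0, 0))$auc
compute_metrics <- function(scores, probabilities, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            length(probabilities) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    rawms_stop("rawms_metric_error", "AUC undefined: only one class present")
  }
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  p <- pmin(pmax(probabilities, 1e-15), 1 - 1e-15)
  brier <- mean((probabilities - labels)^2)
  log_loss <- -mean(labels * log(p) + (1 - labels) * log(1 - p))

  pred <- as.integer(probabilities >= 0.5)
  tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  accuracy <- (tp + tn) / length(labels)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  specificity <- tn / (tn + fp)
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0

  # Youden's J over all score thresholds: walk the ROC curve
  ord <- order(scores, decreasing = TRUE)
  tpr <- cumsum(labels[ord] == 1L) / n1
  fpr <- cumsum(labels[ord] == 0L) / n0
  # only evaluate at distinct-score boundaries
  keep <- c(diff(scores[ord]) != 0, TRUE)
  youden <- max(0, (tpr - fpr)[keep])

  structure(
    list(auc = auc, brier = brier, log_loss = log_loss, accuracy = accuracy,
         f1 = f1, youden = youden, recall = recall, precision = precision,
         specificity = specificity),
    class = "rawms_metric_set"
  )
}

# stratified fold assignment: within each class, shuffle then deal
# round-robin, so every fold's class ratio is within one sample of the cohort
stratified_folds <- function(labels, k, seed) {
  labels <- as.integer(labels)
  if (min(table(labels)) < k) {
    rawms_stop("rawms_cv_error",
               "smallest class has fewer members (%d) than folds (%d); reduce folds",
               min(table(labels)), k)
  }
  folds <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    shuffled <- with_seed(derive_seed(seed, sprintf("folds_class_%d", cl)),
                          sample(idx))
    folds[shuffled] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Grid search by repeated stratified cross-validation
#'
#' For every grid point, runs `repeats` repetitions of stratified `folds`-
#' fold cross-validation (each repetition's fold assignment is drawn from a
#' seed derived from the master seed and the repetition index), scores each
#' held-out fold by AUC, and selects the grid point with the best mean AUC
#' over all `folds * repeats` fold scores. Ties go to the first grid row.
#'
#' @param x training matrix (already scaled).
#' @param y binary training labels.
#' @param classifier classifier name, see [hyper_grid()].
#' @param grid optional data.frame overriding the default grid.
#' @param folds,repeats CV shape (defaults 6 and 2).
#' @param seed master seed for fold assignment and stochastic learners.
#' @return List: `best_params` (one-row data.frame), `cv_auc` (best mean),
#'   `cv_table` (mean AUC per grid point).
#' @export
grid_search <- function(x, y, classifier, grid = NULL, folds = 6L,
                        repeats = 2L, seed = 1L) {
  if (is.null(grid)) grid <- hyper_grid(classifier)
  x <- as.matrix(x)
  y <- as.integer(y)
  fold_sets <- lapply(seq_len(repeats), function(r) {
    stratified_folds(y, folds, derive_seed(seed, sprintf("cv_repeat_%d", r)))
  })
  mean_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    aucs <- numeric(0)
    for (r in seq_len(repeats)) {
      fs <- fold_sets[[r]]
      for (f in seq_len(folds)) {
        tr <- fs != f
        fit_seed <- derive_seed(seed, sprintf("fit_g%d_r%d_f%d", g, r, f))
        model <- fit_classifier(classifier, grid[g, , drop = FALSE],
                                x[tr, , drop = FALSE], y[tr], fit_seed)
        pr <- model(x[!tr, , drop = FALSE])
        aucs <- c(aucs, compute_metrics(pr$score, pr$prob, y[!tr])$auc)
      }
    }
    mean_auc[g] <- mean(aucs)
  }
  best <- which.max(mean_auc)  # first maximum wins
  list(best_params = grid[best, , drop = FALSE],
       cv_auc = mean_auc[best],
       cv_table = cbind(grid, mean_cv_auc = mean_auc))
}

#' Run the full evaluation protocol on one feature matrix
#'
#' The end-to-end protocol for one configuration: constant-feature removal,
#' seeded stratified 70/30 split, per-feature `[0, 1]` scaling fit on the
#' training rows and reapplied to the test rows, grid search by repeated
#' stratified cross-validation selecting on mean AUC, refit of the winning
#' hyperparameters on the full training set, and the metric suite on the
#' held-out test set. Fully deterministic given the master seed.
#'
#' @param fm a `rawms_feature_matrix`.
#' @param classifier classifier name, see [hyper_grid()].
#' @param seed master seed.
#' @param test_fraction held-out fraction (default 0.30).
#' @param cv_folds,cv_repeats CV shape (defaults 6, 2).
#' @param grid optional grid override.
#' @param drop_constant whether to run [drop_constant_features()] first
#'   (default TRUE, dataset-level scope).
#' @param config optional descriptor list (resolution, encoder, mode, ...)
#'   carried through to the result.
#' @return A `rawms_evaluation`: list with `config`, `classifier`,
#'   `best_params`, `cv_auc`, `metrics` (a `rawms_metric_set`), `split`,
#'   `retention`, `seed`.
#' @export
train_and_evaluate <- function(fm, classifier, seed = 1L,
                               test_fraction = 0.30, cv_folds = 6L,
                               cv_repeats = 2L, grid = NULL,
                               drop_constant = TRUE, config = list()) {
  stopifnot(inherits(fm, "rawms_feature_matrix"))
  retention <- 1
  if (drop_constant) {
    fm <- drop_constant_features(fm)
    retention <- attr(fm, "retention")
  }
  split <- stratified_split(fm$labels, test_fraction,
                            derive_seed(seed, "split"))
  x_train <- fm$values[split$train_idx, , drop = FALSE]
  x_test <- fm$values[split$test_idx, , drop = FALSE]
  y_train <- fm$labels[split$train_idx]
  y_test <- fm$labels[split$test_idx]

  scaler <- fit_minmax(x_train)
  x_train <- apply_scaler(scaler, x_train)
  x_test <- apply_scaler(scaler, x_test)

  gs <- grid_search(x_train, y_train, classifier, grid = grid,
                    folds = cv_folds, repeats = cv_repeats,
                    seed = derive_seed(seed, "grid_search"))
  model <- fit_classifier(classifier, gs$best_params, x_train, y_train,
                          derive_seed(seed, "final_fit"))
  pr <- model(x_test)
  metrics <- compute_metrics(pr$score, pr$prob, y_test)

  structure(
    list(config = config, classifier = classifier,
         best_params = gs$best_params, cv_auc = gs$cv_auc,
         cv_table = gs$cv_table, metrics = metrics, split = split,
         retention = retention, seed = as.integer(seed)),
    class = "rawms_evaluation"
  )
}

#' @export
print.rawms_evaluation <- function(x, ...) {
  cat(sprintf("<rawms_evaluation> %s\n", x$classifier))
  cat(sprintf("  best params: %s\n",
              paste(sprintf("%s=%s", names(x$best_params),
                            unlist(x$best_params)), collapse = ", ")))
  cat(sprintf("  mean CV AUC: %.3f | test AUC: %.3f | test accuracy: %.3f\n",
              x$cv_auc, x$metrics$auc, x$metrics$accuracy))
  invisible(x)
}
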