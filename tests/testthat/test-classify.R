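test_that("stratified split applies per-class rounding and is seed-deterministic", {
  labels <- rep(c(0, 1), each = 10)
  sp <- stratified_split(labels, 0.3, seed = 5)
  expect_equal(sum(labels[sp$test_idx] == 1), 3)
  expect_equal(sum(labels[sp$test_idx] == 0), 3)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_along(labels))

  sp2 <- stratified_split(labels, 0.3, seed = 5)
  expect_identical(sp, sp2)
  sp3 <- stratified_split(labels, 0.3, seed = 6)
  expect_false(identical(sp$test_idx, sp3$test_idx))

  # unbalanced classes still stratify within one sample of the cohort ratio
  lab2 <- c(rep(0, 14), rep(1, 7))
  sp4 <- stratified_split(lab2, 0.3, seed = 1)
  expect_equal(sum(lab2[sp4$test_idx] == 0), round(14 * 0.3))
  expect_equal(sum(lab2[sp4$test_idx] == 1), round(7 * 0.3))

  expect_error(stratified_split(labels, 0, seed = 1), class = "rawms_split_error")
  expect_error(stratified_split(c(0, 0, 0, 1), 0.3), class = "rawms_split_error")
  expect_error(stratified_split(rep(1, 10), 0.3), class = "rawms_split_error")
})

test_that("min-max scaling fits on train only and never clips test values", {
  train <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  sc <- fit_minmax(train)
  scaled <- apply_scaler(sc, train)
  expect_equal(scaled[, "a"], c(0, 0.5, 1))
  expect_equal(scaled[, "b"], c(0, 0, 0))  # constant train column -> all zero

  test <- cbind(a = c(8, 0), b = c(7, 5))
  st <- apply_scaler(sc, test)
  expect_equal(st[, "a"], c(1.5, -0.5))  # outside [0,1], unclipped
  expect_equal(st[, "b"], c(0, 0))       # constant-column rule covers test too

  # leakage guard: scaler parameters depend only on train rows
  sc2 <- fit_minmax(train)
  expect_identical(sc, sc2)
  expect_identical(apply_scaler(sc, test[2:1, ]), st[2:1, ])
})

test_that("metric suite reproduces closed-form values", {
  m <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$auc, 1.0, tolerance = 1e-12)
  expect_equal(m$accuracy, 1.0)
  expect_equal(m$youden, 1.0)

  expect_equal(compute_metrics(c(0.1, 0.2, 0.8, 0.9), c(0.1, 0.2, 0.8, 0.9),
                               c(1, 1, 0, 0))$auc, 0.0, tolerance = 1e-12)
  expect_equal(compute_metrics(c(0.9, 0.3, 0.5, 0.1), c(0.9, 0.3, 0.5, 0.1),
                               c(1, 1, 0, 0))$auc, 0.75, tolerance = 1e-12)

  # brier / log loss closed forms
  m2 <- compute_metrics(c(1, 0), c(0.8, 0.4), c(1, 0))
  expect_equal(m2$brier, mean(c((0.8 - 1)^2, 0.4^2)), tolerance = 1e-12)
  expect_equal(m2$log_loss, -mean(log(c(0.8, 0.6))), tolerance = 1e-12)

  # log loss probability floor keeps the value finite
  m3 <- compute_metrics(c(1, 0), c(0, 1), c(1, 0))
  expect_true(is.finite(m3$log_loss))

  expect_error(compute_metrics(c(1, 2), c(0.5, 0.5), c(1, 1)),
               class = "rawms_metric_error")
})

test_that("rank AUC agrees with pair counting and ROC integration", {
  skip_if_not_installed("pROC")
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(10:60, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- rnorm(n) + labels
    probs <- plogis(scores)
    auc <- compute_metrics(scores, probs, labels)$auc
    expect_equal(auc, pairwise_auc(scores, labels), tolerance = 1e-12)
    roc_auc <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<")))
    expect_equal(auc, roc_auc, tolerance = 1e-12)
    # antisymmetry for tie-free scores
    expect_equal(auc + compute_metrics(-scores, probs, labels)$auc, 1,
                 tolerance = 1e-12)
    # Youden dominates the fixed-threshold operating point
    mm <- compute_metrics(scores, probs, labels)
    tpr05 <- mm$recall; fpr05 <- 1 - mm$specificity
    expect_gte(mm$youden + 1e-12, tpr05 - fpr05)
  }
})

test_that("CV folds are stratified and grid search matches an independent loop", {
  fm <- separable_fm(n_per_class = 15, d = 4, gap = 1.5)
  x <- fm$values
  y <- fm$labels
  seed <- 3L

  # fold stratification: every fold's class ratio within 1 of the cohort
  folds <- rawms:::stratified_folds(y, 6, seed)
  for (f in 1:6) {
    expect_equal(sum(y[folds == f] == 1), sum(y[folds == f] == 0))
  }

  gs <- grid_search(x, y, "logreg", grid = data.frame(C = 1), folds = 6L,
                    repeats = 2L, seed = seed)
  expect_equal(gs$best_params$C, 1)

  # independent reimplementation of the 6-fold x 2-repeat loop: direct glmnet
  # fits and pair-counting AUC, sharing only the seed-derivation helpers
  aucs <- c()
  for (r in 1:2) {
    fs <- integer(length(y))
    fseed <- derive_seed(seed, sprintf("cv_repeat_%d", r))
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      shuffled <- with_seed(derive_seed(fseed, sprintf("folds_class_%d", cl)),
                            sample(idx))
      fs[shuffled] <- rep_len(1:6, length(idx))
    }
    for (f in 1:6) {
      tr <- fs != f
      fit <- glmnet::glmnet(x[tr, ], factor(y[tr], levels = c(0, 1)),
                            family = "binomial", alpha = 0,
                            lambda = 1 / sum(tr), standardize = FALSE)
      eta <- as.numeric(predict(fit, x[!tr, ], type = "link"))
      aucs <- c(aucs, pairwise_auc(eta, y[!tr]))
    }
  }
  expect_equal(gs$cv_auc, mean(aucs), tolerance = 1e-12)

  # duplicated grid point: the first occurrence wins
  gs2 <- grid_search(x, y, "logreg", grid = data.frame(C = c(1, 1)),
                     folds = 6L, repeats = 2L, seed = seed)
  expect_equal(rownames(gs2$best_params), "1")

  # perfectly separable data: CV AUC is 1 at any C
  fm_sep <- separable_fm(n_per_class = 12, gap = 10)
  gs3 <- grid_search(fm_sep$values, fm_sep$labels, "logreg", folds = 6L,
                     repeats = 2L, seed = 1L)
  expect_equal(gs3$cv_auc, 1.0, tolerance = 1e-12)

  few <- c(1:4, 16:19)  # 4 per class: below the 6-fold minimum
  expect_error(grid_search(x[few, ], y[few], "logreg", folds = 6L, seed = 1L),
               class = "rawms_cv_error")
})

test_that("all four classifier families run the full protocol deterministically", {
  fm <- separable_fm(n_per_class = 12, d = 6, gap = 3)
  for (clf in c("logreg", "svc", "random_forest", "gradient_boosted_trees")) {
    grid <- hyper_grid(clf)[1, , drop = FALSE]  # single point for speed
    r1 <- train_and_evaluate(fm, clf, seed = 2, grid = grid)
    expect_true(r1$metrics$auc >= 0.75,
                info = sprintf("%s separable AUC %.2f", clf, r1$metrics$auc))
    expect_true(all(unlist(r1$best_params) %in% unlist(grid)))
    r2 <- train_and_evaluate(fm, clf, seed = 2, grid = grid)
    r1$cv_table <- r2$cv_table <- NULL
    expect_equal(r1, r2, info = clf)
  }
})

test_that("the protocol recovers strong signal and stays null under permutation", {
  fm <- separable_fm(n_per_class = 30, d = 5, gap = 4)
  res <- train_and_evaluate(fm, "logreg", seed = 1)
  expect_gte(res$metrics$auc, 0.95)
  expect_true(all(res$best_params$C %in% hyper_grid("logreg")$C))

  # label permutation null: AUC should hover near 0.5
  fm_null <- fm
  fm_null$labels <- with_seed(99, sample(fm$labels))
  res_null <- train_and_evaluate(fm_null, "logreg", seed = 1)
  expect_gte(res_null$metrics$auc, 0.25)
  expect_lte(res_null$metrics$auc, 0.75)
})
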