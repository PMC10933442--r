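# Split, RFE-CV feature selection, TPE tuning, prediction contracts.

test_that("the split is a stratified partition with a ceiling test size", {
  df <- make_toy_classification(n_per_class = 52)      # N = 104
  sp <- split_dataset(df, test_frac = 0.2, seed = 3)
  expect_identical(nrow(sp$test), as.integer(ceiling(0.2 * 104)))
  expect_identical(nrow(sp$train) + nrow(sp$test), 104L)
  expect_length(intersect(sp$train$event_id, sp$test$event_id), 0L)
  expect_setequal(c(sp$train$event_id, sp$test$event_id), df$event_id)
  # stratification: per-class test quota within one of 0.2 * class size
  for (cl in unique(df$level)) {
    expect_lte(abs(sum(sp$test$level == cl) - 0.2 * sum(df$level == cl)), 1)
  }
  sp2 <- split_dataset(df, test_frac = 0.2, seed = 3)
  expect_identical(sort(sp$test$event_id), sort(sp2$test$event_id))
})

test_that("a level with fewer than two members blocks stratification", {
  df <- make_toy_classification(n_per_class = 20)
  df$level[df$level == 1][-1] <- 0L                    # leave a singleton
  expect_error(split_dataset(df, seed = 1), "at least 2 members")
})

test_that("RFE-CV keeps the informative features on a separable toy problem", {
  df <- make_toy_classification(n_per_class = 40, n_noise = 8, seed = 5)
  feats <- c("f1", "f2", paste0("noise", 1:8))
  sel <- rfecv_select(df, "random_forest", cv_folds = 5, seed = 2, step = 1,
                      features = feats)
  expect_true(all(c("f1", "f2") %in% sel$features))
  expect_gt(sel$mean_cv_accuracy, 0.9)

  # brute-force oracle over all subsets of size <= 2 with the same folds:
  # the informative pair must dominate every noise-only subset
  y <- factor(df$level)
  folds <- arousalint:::.make_folds(y, 5, seed = 2)
  cv_acc <- function(cols) {
    mean(arousalint:::.cv_scores(df[, cols, drop = FALSE], y, "random_forest",
                                 list(n_estimators = 100L), folds, seed = 2))
  }
  pair_acc <- cv_acc(c("f1", "f2"))
  noise_subsets <- c(as.list(paste0("noise", 1:8)),
                     list(c("noise1", "noise2"), c("noise3", "noise7")))
  for (cols in noise_subsets) expect_gt(pair_acc, cv_acc(cols) + 0.2)
})

test_that("a single-feature input selects that feature", {
  df <- make_toy_classification(n_per_class = 25, n_noise = 1)
  sel <- rfecv_select(df, "random_forest", seed = 1, features = "f1")
  expect_identical(sel$features, "f1")
  expect_identical(formals(rfecv_select)$cv_folds, 5L)
})

test_that("degenerate one-class labels are an error", {
  df <- make_toy_classification(n_per_class = 20)
  df$level <- 1L
  expect_error(rfecv_select(df, "random_forest", features = c("f1", "f2")),
               "one class")
})

test_that("choose_stage_config records the argmax family per stage", {
  df <- make_toy_classification(n_per_class = 40, n_noise = 4, seed = 8)
  specs <- choose_stage_config(list(N2 = df), cv_folds = 3, seed = 4,
                               step = 2)
  expect_s3_class(specs$N2, "stage_model_spec")
  expect_true(specs$N2$classifier_kind %in% c("random_forest",
                                              "gradient_boosting"))
  expect_gt(specs$N2$mean_cv_accuracy, 0.85)
  expect_true(any(c("f1", "f2") %in% specs$N2$selected_features))
  expect_identical(specs$N2$cv_folds, 3)
})

test_that("TPE returns the single point of a one-point space", {
  out <- tpe_optimize(function(p) p$x, list(x = param_cat(list(7))),
                      n_trials = 3, seed = 1)
  expect_identical(out$best_params$x, 7)
})

test_that("TPE finds the grid optimum of a deterministic quadratic", {
  # exhaustive oracle over the integer grid 1..20
  grid_vals <- vapply(1:20, function(x) -(x - 13)^2 + 4, numeric(1))
  oracle_best <- which.max(grid_vals)
  out <- tpe_optimize(function(p) -(p$x - 13)^2 + 4,
                      list(x = param_int(1L, 20L)),
                      n_trials = 25, seed = 7, prune = FALSE)
  expect_identical(out$best_params$x, oracle_best)
  expect_equal(out$best_value, max(grid_vals))
  out2 <- tpe_optimize(function(p) -(p$x - 13)^2 + 4,
                       list(x = param_int(1L, 20L)),
                       n_trials = 25, seed = 7, prune = FALSE)
  expect_identical(out2$best_params, out$best_params)  # seeded determinism
})

test_that("successive halving prunes weak trials but keeps the best", {
  fn <- function(p) rep(-(p$x - 5)^2, 5)               # 5 "folds"
  out <- tpe_optimize(fn, list(x = param_int(1L, 12L)), n_trials = 12,
                      seed = 3)
  expect_true(any(vapply(out$trials, `[[`, logical(1), "pruned")))
  expect_identical(out$best_params$x, 5L)
})

test_that("tune_and_fit falls back to defaults when n_trials is zero", {
  df <- make_toy_classification(n_per_class = 30, n_noise = 2)
  spec <- structure(list(stage = "N2", classifier_kind = "random_forest",
                         selected_features = c("f1", "f2"),
                         hyperparameters = list(), cv_folds = 3),
                    class = "stage_model_spec")
  expect_warning(m <- tune_and_fit(df, spec, n_trials = 0, seed = 1),
                 "default hyperparameters")
  expect_s3_class(m, "stage_model")
})

test_that("prediction contracts: labels 0-4, scores sum to one, column check", {
  df <- make_toy_classification(n_per_class = 40, n_noise = 2)
  spec <- structure(list(stage = "N2", classifier_kind = "random_forest",
                         selected_features = c("f1", "f2", "noise1"),
                         hyperparameters = list(), cv_folds = 3),
                    class = "stage_model_spec")
  m <- suppressWarnings(tune_and_fit(df, spec, n_trials = 0, seed = 2))
  pred <- predict_levels(m, df)
  expect_true(all(pred$levels %in% 0:4))
  expect_lt(max(abs(rowSums(pred$scores) - 1)), 1e-9)
  # overfit-capacity forest memorizes its own training data
  expect_gte(mean(pred$levels == df$level), 0.99)
  expect_error(predict_levels(m, df[, c("event_id", "f1")]),
               "noise1")
})

test_that("gradient boosting round-trips through fit and predict", {
  df <- make_toy_classification(n_per_class = 40, n_noise = 2)
  spec <- structure(list(stage = "REM", classifier_kind = "gradient_boosting",
                         selected_features = c("f1", "f2"),
                         hyperparameters = list(), cv_folds = 3),
                    class = "stage_model_spec")
  m <- suppressWarnings(tune_and_fit(df, spec, n_trials = 0, seed = 5))
  pred <- predict_levels(m, df)
  expect_gte(mean(pred$levels == df$level), 0.95)
  expect_lt(max(abs(rowSums(pred$scores) - 1)), 1e-6)
})
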