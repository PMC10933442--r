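# Per-sleep-stage classifiers: stratified split, classifier families,
# recursive feature elimination with cross-validation, TPE hyperparameter
# search with successive-halving pruning.

#' Stratified train/test split
#'
#' Random split stratified by intensity level; the test set holds
#' `ceiling(test_frac * N)` rows (per-level quotas by largest remainder), the
#' rest train. Deterministic per seed.
#'
#' @param matrix Feature data frame with `event_id` and `level` columns.
#' @param test_frac Test fraction (default 0.2).
#' @param seed Integer seed.
#' @return A list `train`, `test`, `seed`; row sets are disjoint and their
#'   union is the input.
#' @export
split_dataset <- function(matrix, test_frac = 0.2, seed = 1L) {
  n <- nrow(matrix)
  if (n < 10L) stop("need at least 10 rows to split")
  counts <- table(matrix$level)
  if (any(counts < 2L)) {
    stop("every intensity level needs at least 2 members for stratification; ",
         "short: ", paste(names(counts)[counts < 2L], collapse = ", "))
  }
  set.seed(seed)
  total <- as.integer(ceiling(test_frac * n))
  quota <- test_frac * as.numeric(counts)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  test_idx <- integer(0)
  for (j in seq_along(counts)) {
    rows <- which(matrix$level == as.integer(names(counts)[j]))
    test_idx <- c(test_idx, sample(rows, base[j]))
  }
  list(train = matrix[-test_idx, , drop = FALSE],
       test = matrix[test_idx, , drop = FALSE],
       seed = seed)
}

# ---- classifier family layer (random forest via ranger, gradient boosting
# ---- via xgboost), single-threaded for determinism ----

.default_params <- function(kind) {
  switch(kind,
    random_forest = list(n_estimators = 200L, max_depth = 0L,
                         min_samples_leaf = 1L, max_features = NA_real_),
    gradient_boosting = list(n_estimators = 150L, learning_rate = 0.1,
                             max_depth = 6L, min_child_samples = 1L,
                             feature_fraction = 0.9),
    stop("unknown classifier kind: ", kind))
}

.fit_classifier <- function(kind, X, y, params = .default_params(kind),
                            seed = 1L, importance = FALSE) {
  y <- factor(y)
  if (nlevels(y) < 2L) stop("degenerate labels: only one class present")
  p <- utils::modifyList(.default_params(kind), params)
  if (kind == "random_forest") {
    mtry <- if (is.na(p$max_features)) max(1L, floor(sqrt(ncol(X)))) else
      max(1L, floor(p$max_features * ncol(X)))
    fit <- ranger::ranger(x = X, y = y, num.trees = p$n_estimators,
                          max.depth = p$max_depth,
                          min.node.size = p$min_samples_leaf,
                          mtry = min(mtry, ncol(X)), probability = TRUE,
                          importance = if (importance) "impurity" else "none",
                          seed = seed, num.threads = 1L)
  } else {
    lv <- levels(y)
    dtrain <- xgboost::xgb.DMatrix(as.matrix(X),
                                   label = as.integer(y) - 1L)
    fit <- xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = length(lv),
                    eta = p$learning_rate, max_depth = p$max_depth,
                    min_child_weight = p$min_child_samples,
                    colsample_bytree = p$feature_fraction,
                    nthread = 1L, seed = seed, verbosity = 0),
      data = dtrain, nrounds = p$n_estimators, verbose = 0)
  }
  structure(list(kind = kind, fit = fit, classes = levels(y),
                 features = colnames(X), params = p, seed = seed),
            class = "stage_classifier")
}

.predict_classifier <- function(model, X) {
  X <- as.matrix(X[, model$features, drop = FALSE])
  if (model$kind == "random_forest") {
    prob <- stats::predict(model$fit, data = X, num.threads = 1L)$predictions
  } else {
    prob <- stats::predict(model$fit, xgboost::xgb.DMatrix(X))
    if (!is.matrix(prob)) {
      prob <- matrix(prob, ncol = length(model$classes), byrow = TRUE)
    }
  }
  colnames(prob) <- model$classes
  list(class = model$classes[max.col(prob, ties.method = "first")],
       prob = prob)
}

.importance <- function(model) {
  if (model$kind == "random_forest") {
    imp <- ranger::importance(model$fit)
    imp[model$features]
  } else {
    tab <- xgboost::xgb.importance(model = model$fit)
    imp <- stats::setNames(rep(0, length(model$features)), model$features)
    imp[tab$Feature] <- tab$Gain
    imp
  }
}

# stratified fold assignment (round-robin within shuffled classes)
.make_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    rows <- sample(which(y == cls))
    fold[rows] <- rep_len(seq_len(k), length(rows))
  }
  fold
}

.cv_scores <- function(X, y, kind, params, folds, seed,
                       objective = "mean_cv_accuracy",
                       fold_subset = NULL) {
  ks <- sort(unique(folds))
  if (!is.null(fold_subset)) ks <- ks[fold_subset]
  vapply(ks, function(k) {
    tr <- folds != k
    m <- .fit_classifier(kind, X[tr, , drop = FALSE], y[tr], params,
                         seed = seed)
    pred <- .predict_classifier(m, X[!tr, , drop = FALSE])$class
    if (objective == "level0_sensitivity" && any(y[!tr] == "0")) {
      mean(pred[y[!tr] == "0"] == "0")
    } else {
      mean(pred == y[!tr])
    }
  }, numeric(1))
}

#' Recursive feature elimination with cross-validation
#'
#' Starting from all features, repeatedly measures the mean stratified
#' `cv_folds`-fold CV accuracy of the current subset, then refits on the full
#' training data and drops the least important `step` fraction (at least one
#' feature) until one feature remains. Returns the subset with the highest
#' mean CV accuracy along the elimination path; ties favour the smaller
#' subset.
#'
#' @param train Feature data frame with `level` plus feature columns.
#' @param classifier_kind `"random_forest"` or `"gradient_boosting"`.
#' @param cv_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @param step Fraction (or integer count) of features eliminated per
#'   iteration (default 0.2).
#' @param features Candidate feature columns (default: the canonical
#'   [feature_names()] present in `train`, else every numeric column that is
#'   not `level`).
#' @return List `features` (selected names), `mean_cv_accuracy`, and the
#'   elimination `path` (data frame of subset size and accuracy).
#' @export
rfecv_select <- function(train, classifier_kind, cv_folds = 5L, seed = 1L,
                         step = 0.2, features = NULL) {
  if (is.null(features)) features <- intersect(feature_names(), names(train))
  if (!length(features)) {
    numeric_cols <- names(train)[vapply(train, is.numeric, logical(1))]
    features <- setdiff(numeric_cols, "level")
  }
  if (length(features) < 1L) stop("no candidate features")
  y <- factor(train$level)
  if (nlevels(y) < 2L) stop("degenerate labels: only one class present")
  folds <- .make_folds(y, cv_folds, seed)
  current <- features
  path <- list(); best <- NULL
  repeat {
    X <- train[, current, drop = FALSE]
    acc <- mean(.cv_scores(X, y, classifier_kind, list(), folds, seed))
    path[[length(path) + 1L]] <- data.frame(n_features = length(current),
                                            mean_cv_accuracy = acc)
    better <- is.null(best) || acc > best$mean_cv_accuracy ||
      (acc == best$mean_cv_accuracy && length(current) < length(best$features))
    if (better) best <- list(features = current, mean_cv_accuracy = acc)
    if (length(current) == 1L) break
    m <- .fit_classifier(classifier_kind, X, y, seed = seed,
                         importance = TRUE)
    imp <- .importance(m)
    n_drop <- if (step < 1) max(1L, floor(step * length(current))) else
      min(as.integer(step), length(current) - 1L)
    current <- current[order(imp, decreasing = TRUE)]
    current <- current[seq_len(length(current) - n_drop)]
  }
  best$path <- do.call(rbind, path)
  best
}

#' Choose the per-stage classifier configuration
#'
#' Runs [rfecv_select()] for both classifier families on each stage's
#' training data and keeps, per stage, the pair (family, feature subset) with
#' the highest mean CV accuracy; exact ties favour the random forest, then
#' the smaller subset.
#'
#' @param stage_trains Named list (stage -> training feature data frame).
#' @param cv_folds,seed,step Passed to [rfecv_select()].
#' @return Named list of `stage_model_spec` lists (`stage`,
#'   `classifier_kind`, `selected_features`, `mean_cv_accuracy`,
#'   `hyperparameters`, `cv_folds`).
#' @export
choose_stage_config <- function(stage_trains, cv_folds = 5L, seed = 1L,
                                step = 0.2) {
  lapply(stats::setNames(names(stage_trains), names(stage_trains)),
         function(stg) {
    cand <- lapply(c("random_forest", "gradient_boosting"), function(kind) {
      sel <- rfecv_select(stage_trains[[stg]], kind, cv_folds = cv_folds,
                          seed = seed, step = step)
      list(kind = kind, sel = sel)
    })
    accs <- vapply(cand, function(cc) cc$sel$mean_cv_accuracy, numeric(1))
    sizes <- vapply(cand, function(cc) length(cc$sel$features), integer(1))
    pick <- order(-accs, match(vapply(cand, `[[`, "", "kind"),
                               c("random_forest", "gradient_boosting")),
                  sizes)[1L]
    structure(list(stage = stg, classifier_kind = cand[[pick]]$kind,
                   selected_features = cand[[pick]]$sel$features,
                   mean_cv_accuracy = cand[[pick]]$sel$mean_cv_accuracy,
                   hyperparameters = list(), cv_folds = cv_folds),
              class = "stage_model_spec")
  })
}

# ---- TPE sampler with successive-halving pruning ----

#' Hyperparameter search space constructors
#'
#' `param_int`, `param_float` and `param_cat` declare one dimension of a
#' search space for [tpe_optimize()]; `log = TRUE` samples on the log scale.
#'
#' @param low,high Bounds (inclusive).
#' @param values Category values.
#' @param log Sample on log scale.
#' @return A parameter spec list.
#' @export
param_int <- function(low, high, log = FALSE) {
  list(type = "int", low = low, high = high, log = log)
}
#' @rdname param_int
#' @export
param_float <- function(low, high, log = FALSE) {
  list(type = "float", low = low, high = high, log = log)
}
#' @rdname param_int
#' @export
param_cat <- function(values) list(type = "cat", values = values)

.space_size <- function(space) {
  sizes <- vapply(space, function(s) {
    switch(s$type, int = s$high - s$low + 1, cat = length(s$values), Inf)
  }, numeric(1))
  prod(sizes)
}

.sample_uniform <- function(space) {
  lapply(space, function(s) {
    switch(s$type,
      int = if (isTRUE(s$log)) {
        as.integer(round(exp(stats::runif(1, log(s$low), log(s$high)))))
      } else sample(s$low:s$high, 1L),
      float = if (isTRUE(s$log)) {
        exp(stats::runif(1, log(s$low), log(s$high)))
      } else stats::runif(1, s$low, s$high),
      cat = s$values[[sample.int(length(s$values), 1L)]])
  })
}

# Parzen density of value v given observations obs for one dimension
.parzen_density <- function(v, obs, s) {
  if (s$type == "cat") {
    counts <- table(factor(vapply(obs, as.character, ""),
                           levels = as.character(s$values)))
    return((counts[[as.character(v)]] + 1) / (sum(counts) + length(s$values)))
  }
  x <- vapply(obs, as.numeric, numeric(1))
  v <- as.numeric(v)
  if (isTRUE(s$log)) { x <- log(x); v <- log(v) }
  lo <- if (isTRUE(s$log)) log(s$low) else s$low
  hi <- if (isTRUE(s$log)) log(s$high) else s$high
  bw <- max((hi - lo) / max(sqrt(length(x)), 1), (hi - lo) * 0.05, 1e-9)
  mean(stats::dnorm(v, mean = x, sd = bw)) + 1e-12
}

.draw_from_good <- function(space, good) {
  lapply(seq_along(space), function(j) {
    s <- space[[j]]
    obs <- lapply(good, `[[`, j)
    if (s$type == "cat") {
      counts <- table(factor(vapply(obs, as.character, ""),
                             levels = as.character(s$values)))
      p <- (as.numeric(counts) + 1) / (sum(counts) + length(s$values))
      return(s$values[[sample.int(length(s$values), 1L, prob = p)]])
    }
    x <- vapply(obs, as.numeric, numeric(1))
    if (isTRUE(s$log)) x <- log(x)
    lo <- if (isTRUE(s$log)) log(s$low) else s$low
    hi <- if (isTRUE(s$log)) log(s$high) else s$high
    bw <- max((hi - lo) / max(sqrt(length(x)), 1), (hi - lo) * 0.05, 1e-9)
    v <- stats::rnorm(1, mean = x[sample.int(length(x), 1L)], sd = bw)
    v <- min(max(v, lo), hi)
    if (isTRUE(s$log)) v <- exp(v)
    if (s$type == "int") as.integer(round(v)) else v
  })
}

#' Tree-structured Parzen estimator search with successive-halving pruning
#'
#' Maximizes `fn` over `space`. `fn(params)` returns a numeric vector of
#' per-resource scores (e.g. per-CV-fold accuracies); its mean is the trial
#' value. Trials are evaluated rung by rung (resource schedule
#' `1, ceil(R/2), R` elements of the score vector) and pruned when their
#' running mean falls below the median of completed trials at the same rung
#' (successive halving). After `n_startup` random trials, candidates are
#' drawn from a Parzen density over the best `gamma` fraction of trials and
#' ranked by the good/bad density ratio. For finite integer/categorical
#' spaces, already-evaluated configurations are not revisited and the search
#' stops once the space is exhausted.
#'
#' @param fn Objective; takes a named parameter list, returns numeric vector
#'   (or scalar) of scores to be averaged and maximized. For pruning support
#'   it may accept `fold_subset` to evaluate only some resources; otherwise
#'   the full vector is computed once and sliced.
#' @param space Named list of [param_int()] / [param_float()] / [param_cat()]
#'   specs.
#' @param n_trials Maximum number of trials.
#' @param seed Integer seed.
#' @param gamma Fraction of trials modelled as "good" (default 0.25).
#' @param n_candidates Candidates scored per TPE draw (default 24).
#' @param prune Use successive-halving pruning (default `TRUE`).
#' @return List `best_params`, `best_value`, and the trial log `trials`.
#' @export
tpe_optimize <- function(fn, space, n_trials = 30L, seed = 1L, gamma = 0.25,
                         n_candidates = 24L, prune = TRUE) {
  set.seed(seed)
  finite <- is.finite(.space_size(space)) && .space_size(space) <= 10000
  n_startup <- max(5L, ceiling(n_trials / 5))
  seen <- character(0)
  trials <- list()
  key <- function(p) paste(vapply(p, function(v) format(v, digits = 12), ""),
                           collapse = "|")
  for (t in seq_len(n_trials)) {
    done <- Filter(function(tr) !tr$pruned, trials)
    if (length(trials) < n_startup || length(done) < 4L) {
      params <- .sample_uniform(space)
      if (finite) {
        for (r in seq_len(50L)) {
          if (!key(params) %in% seen) break
          params <- .sample_uniform(space)
        }
        if (key(params) %in% seen) {
          remaining <- .enumerate_space(space, seen)
          if (is.null(remaining)) break
          params <- remaining
        }
      }
    } else {
      vals <- vapply(done, `[[`, numeric(1), "value")
      cut <- stats::quantile(vals, 1 - gamma, type = 7)
      good <- lapply(Filter(function(tr) tr$value >= cut, done), `[[`, "params")
      bad <- lapply(Filter(function(tr) tr$value < cut, done), `[[`, "params")
      if (!length(bad)) bad <- good
      cands <- replicate(n_candidates, .draw_from_good(space, good),
                         simplify = FALSE)
      if (finite) {
        cands <- Filter(function(p) !key(p) %in% seen, cands)
        if (!length(cands)) {
          remaining <- .enumerate_space(space, seen)
          if (is.null(remaining)) break
          cands <- list(remaining)
        }
      }
      score <- vapply(cands, function(p) {
        lg <- sum(vapply(seq_along(space), function(j) {
          log(.parzen_density(p[[j]], lapply(good, `[[`, j), space[[j]]))
        }, numeric(1)))
        lb <- sum(vapply(seq_along(space), function(j) {
          log(.parzen_density(p[[j]], lapply(bad, `[[`, j), space[[j]]))
        }, numeric(1)))
        lg - lb
      }, numeric(1))
      params <- cands[[which.max(score)]]
    }
    names(params) <- names(space)
    seen <- c(seen, key(params))
    scores <- fn(params)
    R <- length(scores)
    pruned <- FALSE
    if (prune && R > 1L && length(trials) >= 4L) {
      rungs <- unique(pmin(c(1L, ceiling(R / 2), R), R))
      for (r in rungs[-length(rungs)]) {
        running <- mean(scores[seq_len(r)])
        peers <- vapply(trials, function(tr) mean(tr$scores[seq_len(min(r, length(tr$scores)))]),
                        numeric(1))
        if (length(peers) >= 4L && running < stats::median(peers)) {
          pruned <- TRUE
          break
        }
      }
    }
    trials[[t]] <- list(params = params, scores = scores,
                        value = mean(scores), pruned = pruned)
  }
  done <- Filter(function(tr) !tr$pruned, trials)
  if (!length(done)) done <- trials
  best <- done[[which.max(vapply(done, `[[`, numeric(1), "value"))]]
  list(best_params = best$params, best_value = best$value, trials = trials)
}

# first not-yet-seen configuration of a small finite space, or NULL
.enumerate_space <- function(space, seen) {
  grids <- lapply(space, function(s) {
    if (s$type == "cat") s$values else as.list(s$low:s$high)
  })
  combos <- expand.grid(lapply(grids, seq_along))
  key <- function(p) paste(vapply(p, function(v) format(v, digits = 12), ""),
                           collapse = "|")
  for (i in seq_len(nrow(combos))) {
    p <- lapply(seq_along(grids), function(j) grids[[j]][[combos[i, j]]])
    if (!key(p) %in% seen) return(p)
  }
  NULL
}

.search_space <- function(kind) {
  if (kind == "random_forest") {
    list(n_estimators = param_int(100L, 400L),
         max_depth = param_int(4L, 24L),
         min_samples_leaf = param_int(1L, 10L),
         max_features = param_float(0.1, 0.9))
  } else {
    list(n_estimators = param_int(50L, 300L),
         learning_rate = param_float(0.02, 0.3, log = TRUE),
         max_depth = param_int(3L, 10L),
         min_child_samples = param_int(1L, 10L),
         feature_fraction = param_float(0.3, 1.0))
  }
}

#' Tune hyperparameters and fit the final stage model
#'
#' Runs [tpe_optimize()] over the classifier family's search space, scoring
#' each configuration by stratified `cv_folds`-fold CV on the selected
#' features (objective `mean_cv_accuracy`, or `level0_sensitivity` — the
#' sham-detection recall — when requested), then refits on the full training
#' data with the best parameters. With `n_trials = 0` the family defaults
#' are used with a warning.
#'
#' @param train Training feature data frame.
#' @param spec A `stage_model_spec` from [choose_stage_config()].
#' @param n_trials TPE trial budget (default 30).
#' @param objective `"mean_cv_accuracy"` or `"level0_sensitivity"`.
#' @param seed Integer seed.
#' @return A `stage_model` list: `spec` (with tuned `hyperparameters`),
#'   `classifier`, `cv_value`.
#' @export
tune_and_fit <- function(train, spec, n_trials = 30L,
                         objective = "mean_cv_accuracy", seed = 1L) {
  X <- train[, spec$selected_features, drop = FALSE]
  y <- factor(train$level)
  folds <- .make_folds(y, spec$cv_folds, seed)
  if (n_trials < 1L) {
    warning("n_trials = 0; using default hyperparameters")
    best <- list(best_params = .default_params(spec$classifier_kind),
                 best_value = NA_real_)
  } else {
    fn <- function(params) {
      .cv_scores(X, y, spec$classifier_kind, params, folds, seed,
                 objective = objective)
    }
    best <- tpe_optimize(fn, .search_space(spec$classifier_kind),
                         n_trials = n_trials, seed = seed)
  }
  spec$hyperparameters <- best$best_params
  classifier <- .fit_classifier(spec$classifier_kind, X, y,
                                best$best_params, seed = seed)
  structure(list(spec = spec, classifier = classifier,
                 cv_value = best$best_value),
            class = "stage_model")
}

#' Predict intensity levels with a fitted stage model
#'
#' @param model A `stage_model` from [tune_and_fit()].
#' @param features Feature data frame containing the model's selected
#'   feature columns (missing columns are an error naming them).
#' @return List `levels` (integer vector over 0-4) and `scores` (row-
#'   normalized per-class probability matrix, columns named by class).
#' @export
predict_levels <- function(model, features) {
  miss <- setdiff(model$spec$selected_features, names(features))
  if (length(miss)) {
    stop("feature table lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  pr <- .predict_classifier(model$classifier, features)
  list(levels = as.integer(pr$class), scores = pr$prob)
}
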