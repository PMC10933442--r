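# Per-class metrics, one-vs-rest AUROC, and the cross-stage aggregation.

test_that("binary one-vs-rest ratios match direct arithmetic", {
  # TP = 8, FN = 2, TN = 90, FP = 10 for level 1
  y_true <- c(rep(1, 10), rep(0, 100))
  y_pred <- c(rep(1, 8), rep(0, 2), rep(1, 10), rep(0, 90))
  m <- per_class_metrics(y_true, y_pred)$metrics
  r1 <- m[m$level == 1, ]
  expect_equal(r1$sensitivity, 0.800)
  expect_equal(r1$specificity, 0.900)
  expect_equal(r1$ppv, 8 / 18, tolerance = 1e-12)
  expect_equal(r1$npv, 90 / 92, tolerance = 1e-12)
  expect_identical(r1$support, 10L)
})

test_that("168 of 244 shams recovered is a 68.85% hit rate", {
  y_true <- rep(0, 244)
  y_pred <- c(rep(0, 168), rep(2, 76))
  m <- per_class_metrics(y_true, y_pred)$metrics
  hit <- 100 * m$sensitivity[m$level == 0]
  expect_equal(round(hit, 2), 68.85)
})

test_that("perfect predictions give unit metrics for every present level", {
  y <- rep(0:4, times = c(5, 7, 6, 8, 4))
  m <- per_class_metrics(y, y)$metrics
  expect_true(all(m$sensitivity == 1))
  expect_true(all(m$specificity == 1))
  expect_true(all(m$ppv == 1))
  expect_true(all(m$npv == 1))
})

test_that("undefined 0/0 ratios are reported as NA, not zero", {
  m <- per_class_metrics(c(1, 1, 2), c(1, 1, 1),
                         levels = 1:3)$metrics
  expect_true(is.na(m$ppv[m$level == 3]))              # never predicted 3
  expect_true(is.na(m$sensitivity[m$level == 3]))      # never true 3
})

test_that("confusion matrix rows sum to the per-level supports", {
  set.seed(13)
  y_true <- sample(0:4, 200, replace = TRUE)
  y_pred <- sample(0:4, 200, replace = TRUE)
  pm <- per_class_metrics(y_true, y_pred)
  expect_identical(sum(pm$confusion), 200L)
  expect_equal(unname(rowSums(pm$confusion)), unname(pm$metrics$support))
  expect_error(per_class_metrics(1:3, 1:4), "equal length")
})

test_that("AUROC equals the exhaustive positive-negative pair oracle", {
  set.seed(14)
  y <- sample(c(0L, 1L), 20, replace = TRUE, prob = c(0.6, 0.4))
  s <- round(runif(20), 1)                              # forces some ties
  scores <- cbind(`0` = 1 - s, `1` = s)
  auc <- ovr_auroc(y, scores)[["1"]]
  pos <- s[y == 1L]; neg <- s[y == 0L]
  oracle <- mean(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b)))                          # brute-force pairs
  expect_equal(auc, oracle, tolerance = 1e-12)
})

test_that("AUROC hits its degenerate anchors and is rank-invariant", {
  y <- c(rep(1, 5), rep(0, 5))
  perfect <- cbind(`1` = c(rep(0.9, 5), rep(0.1, 5)))
  expect_equal(ovr_auroc(y, perfect)[["1"]], 1.0)
  flat <- cbind(`1` = rep(0.5, 10))
  expect_equal(ovr_auroc(y, flat)[["1"]], 0.5)
  set.seed(15)
  s <- cbind(`1` = runif(10))
  expect_equal(ovr_auroc(y, s), ovr_auroc(y, cbind(`1` = exp(3 * s[, 1]))))
  expect_true(is.na(ovr_auroc(rep(0, 4), cbind(`1` = runif(4)))[["1"]]))
})

test_that("our rank AUROC matches pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(16)
  y <- sample(0:1, 60, replace = TRUE)
  s <- runif(60)
  ours <- ovr_auroc(y, cbind(`1` = s))[["1"]]
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

# helper: build y_true/y_pred with an exact level-0 sensitivity tp/n0
make_stage <- function(tp, n0, filler = 40) {
  y_true <- c(rep(0L, n0), rep(3L, filler))
  y_pred <- c(rep(0L, tp), rep(3L, n0 - tp), rep(3L, filler))
  list(y_true = y_true, y_pred = y_pred)
}

test_that("cross-stage averages are unweighted over stages holding the level", {
  # level-0 sensitivities 37/45, 29/36, 70/81 (82.22 / 80.56 / 86.42 %);
  # the fourth stage has no level-0 cases at all
  res <- list(REM = make_stage(37, 45), N1 = make_stage(29, 36),
              N2 = make_stage(70, 81),
              N3 = list(y_true = rep(3L, 20), y_pred = rep(3L, 20)))
  rep0 <- aggregate_report(res)
  avg0 <- rep0$average[rep0$average$level == 0, ]
  expect_identical(avg0$n_stages, 3L)
  expect_equal(round(100 * avg0$sensitivity, 2), 83.07)
  expect_equal(avg0$sensitivity, mean(c(37 / 45, 29 / 36, 70 / 81)))
})

test_that("a single stage aggregates to its own metrics", {
  res <- list(N2 = make_stage(70, 81))
  rep1 <- aggregate_report(res)
  expect_equal(rep1$average$sensitivity[rep1$average$level == 0], 70 / 81)
})

test_that("the pooled total equals brute-force pooling of all predictions", {
  set.seed(17)
  res <- lapply(stats::setNames(nm = c("REM", "N1", "N2")), function(s) {
    n <- sample(40:80, 1)
    list(y_true = sample(0:4, n, replace = TRUE),
         y_pred = sample(0:4, n, replace = TRUE))
  })
  rep2 <- aggregate_report(res)
  y_true <- unlist(lapply(res, `[[`, "y_true"))
  y_pred <- unlist(lapply(res, `[[`, "y_pred"))
  pm <- per_class_metrics(y_true, y_pred)$metrics     # brute-force pool
  oracle <- sum(pm$sensitivity * pm$support) / sum(pm$support)
  expect_equal(rep2$total$sensitivity, oracle)
  expect_identical(rep2$total$support, length(y_true))
})
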