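# Amplitude distance, quartile thresholds, level assignment, sham selection.

test_that("amplitude distance is the mean of the C3 and C4 ranges", {
  pair <- make_sine_pair()
  pair$arousal$C3 <- rep(1e-4, 100)                    # constant -> range 0
  pair$arousal$C4 <- rep(-2e-4, 100)
  expect_equal(amplitude_distance(pair), 0)
  pair$arousal$C3 <- c(rep(0, 50), 100e-6)             # range 100 uV
  pair$arousal$C4 <- c(rep(0, 50), -120e-6)            # range 120 uV
  expect_equal(amplitude_distance(pair), 110e-6)
})

test_that("amplitude distance is homogeneous of degree one", {
  pair <- make_sine_pair()
  set.seed(2)
  pair$arousal$C3 <- rnorm(200); pair$arousal$C4 <- rnorm(200)
  base <- amplitude_distance(pair)
  for (k in c(0.5, 3, 10)) {
    scaled <- pair
    scaled$arousal$C3 <- k * pair$arousal$C3
    scaled$arousal$C4 <- k * pair$arousal$C4
    expect_equal(amplitude_distance(scaled), k * base)
  }
})

test_that("empty segments are an error", {
  pair <- make_sine_pair()
  pair$arousal$C3 <- numeric(0)
  expect_error(amplitude_distance(pair), "empty")
})

test_that("quartile thresholds use linear-interpolation quantiles", {
  th <- fit_quartile_thresholds(1:8)
  # oracle: sorted-list interpolation at p(n-1)+1 gives 2.75 / 4.5 / 6.25
  expect_equal(th$q1, 2.75)
  expect_equal(th$q2, 4.5)
  expect_equal(th$q3, 6.25)
  expect_lt(th$lower_edge, 1)
  expect_gt(th$upper_edge, 8)
  expect_error(fit_quartile_thresholds(rep(2, 20)), "at least 8 distinct")
})

test_that("fitting then binning balances the four levels to within one", {
  set.seed(9)
  amps <- rlnorm(203, log(1.6e-4), 0.8)
  th <- fit_quartile_thresholds(amps)
  lev <- vapply(amps, assign_level, integer(1), thresholds = th)
  counts <- table(factor(lev, levels = 1:4))
  expect_identical(sum(counts), length(amps))          # binning conserves count
  expect_lte(diff(range(counts)), 1)
})

test_that("the reference fixture carries the published interval edges", {
  th <- reference_thresholds()
  expect_equal(th$q1, 9.3e-5)
  expect_equal(th$q2, 1.64e-4)
  expect_equal(th$q3, 4.04e-4)
  expect_equal(th$lower_edge, -0.001)
  expect_equal(th$upper_edge, 6.03e-3)
})

test_that("levels follow right-closed intervals with sham pinned to 0", {
  th <- reference_thresholds()
  expect_identical(assign_level(0.00011, th), 2L)
  expect_identical(assign_level(0.0005, th), 4L)
  expect_identical(assign_level(9.3e-5, th), 1L)       # boundary is closed
  expect_identical(assign_level(9.3e-5 + 1e-9, th), 2L)
  expect_identical(assign_level(0.005, th, is_sham = TRUE), 0L)
  expect_error(assign_level(-1e-5, th), "non-negative")
  expect_warning(lev <- assign_level(0.01, th), "clamped")
  expect_identical(lev, 4L)
})

test_that("level assignment is monotone in amplitude", {
  set.seed(12)
  amps <- sort(rlnorm(100, log(1.6e-4), 0.9))
  th <- fit_quartile_thresholds(amps)
  lev <- vapply(amps, assign_level, integer(1), thresholds = th)
  expect_true(all(diff(lev) >= 0))
})

test_that("sham windows respect count, length, stage and clearance contracts", {
  hyp <- hypnogram(c("W", rep("N2", 38), "W"))         # 20 min recording
  ev <- arousal_events(onset = c(300, 700), duration = c(10, 5))
  sham <- select_sham_windows(hyp, ev, seed = 3)
  expect_gte(nrow(sham), 10L)
  expect_lte(nrow(sham), 14L)
  expect_true(all(sham$duration == 9))
  expect_true(all(sham$is_sham))
  expect_true(all(sham$stage != "W"))
  for (i in seq_len(nrow(sham))) {
    s0 <- sham$onset[i]; s1 <- s0 + 9
    expect_true(all(stage_at(hyp, c(s0, s1 - 1e-9)) != "W"))
    expect_true(all(ev$onset >= s1 + 10 | ev$onset + ev$duration <= s0 - 10))
    others <- sham$onset[-i]
    expect_true(all(abs(others - s0) >= 9 + 10))
  }
})

test_that("an all-wake hypnogram yields no sham windows, with a warning", {
  hyp <- hypnogram(rep("W", 20))
  expect_warning(sham <- select_sham_windows(hyp, arousal_events(), seed = 1),
                 "sham windows")
  expect_identical(nrow(sham), 0L)
})

test_that("score_events conserves the event count across levels", {
  g <- tiny_sim()
  prep <- preprocess_recording(g$recording)
  sham <- suppressWarnings(select_sham_windows(g$hypnogram, g$events, seed = 2))
  allev <- rbind(g$events, sham)
  scored <- score_events(prep, allev)
  expect_identical(sum(scored$level == 0), sum(scored$is_sham))
  expect_identical(sum(scored$level %in% 1:4), sum(!scored$is_sham))
  expect_true(all(scored$level[!scored$is_sham] %in% 1:4))
  expect_s3_class(attr(scored, "thresholds"), "binning_thresholds")
})
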