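# Synthetic polysomnography generator: hypnogram chain, event placement,
# burst scaling, strata recovery, determinism.

test_that("hypnogram length is ceil(duration / 30) and starts in wake", {
  cfg <- synthetic_config(duration = 90, n_recordings = 1)
  hyp <- sample_hypnogram(cfg, seed = 1)
  expect_length(hyp$labels, 3L)
  expect_identical(hyp$labels[1], "W")
  expect_length(sample_hypnogram(synthetic_config(duration = 100), 1)$labels,
                4L)  # 100/30 -> 4 epochs
})

test_that("a near-absorbing N2 chain matches its stationary distribution", {
  # N2-dominant but fast-mixing, so 10,000 epochs estimate the stationary
  # mass well
  P <- matrix(0.025, 5, 5, dimnames = list(STAGES, STAGES))
  P[, "N2"] <- 0.9
  P["N2", ] <- c(0.025, 0.025, 0.9, 0.025, 0.025)
  P <- P / rowSums(P)
  # brute-force power iteration oracle for the stationary vector
  Pi <- P
  for (i in 1:2000) Pi <- Pi %*% P
  stationary <- Pi[1, ]
  cfg <- synthetic_config(duration = 10000 * 30, n_recordings = 1,
                          stage_transition = P)
  hyp <- sample_hypnogram(cfg, seed = 4)
  emp <- mean(hyp$labels == "N2")
  expect_lt(abs(emp - stationary[["N2"]]), 0.02)
})

test_that("non-stochastic transition matrices are a configuration error", {
  P <- matrix(0.3, 5, 5, dimnames = list(STAGES, STAGES))
  expect_error(synthetic_config(stage_transition = P), "row-stochastic")
})

test_that("the same seed reproduces hypnogram, signals and annotations exactly", {
  cfg <- synthetic_config(n_recordings = 1, duration = 300, arousal_rate = 24,
                          seed = 17)
  a <- generate_recording(cfg, seed = 17)
  b <- generate_recording(cfg, seed = 17)
  expect_identical(sample_hypnogram(cfg, 17)$labels,
                   sample_hypnogram(cfg, 17)$labels)
  expect_identical(a$recording$channels, b$recording$channels)
  expect_identical(a$events, b$events)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("zero arousal rate gives no events and the configured background level", {
  cfg <- synthetic_config(n_recordings = 1, duration = 300, arousal_rate = 0,
                          seed = 5)
  g <- generate_recording(cfg, seed = 5)
  expect_identical(nrow(g$events), 0L)
  st <- stage_at(g$hypnogram, (seq_len(n_samples(g$recording)) - 1) / cfg$fs)
  for (s in unique(st)) {
    target <- cfg$stage_spectra[[s]]$rms
    expect_lt(abs(sd(g$recording$channels$C3[st == s]) - target),
              0.2 * target)
  }
})

test_that("channel sample counts follow duration * fs", {
  cfg <- synthetic_config(n_recordings = 1, duration = 600, fs = 200,
                          arousal_rate = 0)
  g <- generate_recording(cfg, seed = 2)
  expect_identical(vapply(g$recording$channels, length, integer(1)),
                   stats::setNames(rep(120000L, 7),
                                   names(g$recording$channels)))
})

test_that("injected bursts have the drawn peak-to-peak on the EEG channels", {
  g <- tiny_sim()
  expect_gt(nrow(g$ground_truth), 0)
  fs <- g$recording$fs
  for (i in seq_len(nrow(g$ground_truth))) {
    ev <- g$ground_truth[i, ]
    sel <- (round(ev$onset * fs) + 1):(round(ev$onset * fs) +
                                         round(ev$duration * fs))
    for (ch in c("C3", "C4")) {
      burst <- g$recording$channels[[ch]][sel] - g$background[[ch]][sel]
      expect_lt(abs((max(burst) - min(burst)) - ev$amplitude) / ev$amplitude,
                0.1)
    }
  }
})

test_that("every event lasts >= 3 s with >= 10 s of stable non-wake sleep before", {
  g <- tiny_sim()
  ev <- g$events
  expect_true(all(ev$duration >= 3))
  expect_true(all(ev$stage != "W"))
  for (i in seq_len(nrow(ev))) {
    pre <- seq(ev$onset[i] - 10, ev$onset[i], by = 1)
    expect_true(all(stage_at(g$hypnogram, pre) != "W"))
    others <- ev[-i, , drop = FALSE]
    clash <- others$onset < ev$onset[i] &
      (others$onset + others$duration) > ev$onset[i] - 10
    expect_false(any(clash))
  }
  # no overlaps
  expect_true(all(diff(ev$onset) >= ev$duration[-nrow(ev)]))
})

test_that("quartile binning of measured amplitudes recovers the true strata", {
  cfg <- synthetic_config(n_recordings = 3, duration = 1200,
                          arousal_rate = 36, seed = 21, class_separation = 8)
  sims <- simulate_psg_dataset(cfg)
  sc <- NULL
  for (s in sims) {
    mm <- measure_amplitudes(preprocess_recording(s$recording), s$events)
    m <- merge(mm, s$ground_truth, by = "onset")
    sc <- rbind(sc, data.frame(stratum = m$stratum,
                               measured = m$amplitude.x))
  }
  th <- fit_quartile_thresholds(sc$measured)
  lev <- vapply(sc$measured, assign_level, integer(1), thresholds = th)
  expect_gte(mean(lev == sc$stratum), 0.95)
})

test_that("simulate_psg_dataset writes EDF + CSV artifacts that read back", {
  cfg <- synthetic_config(n_recordings = 1, duration = 120,
                          arousal_rate = 20, seed = 31)
  dir <- withr::local_tempdir()
  sims <- simulate_psg_dataset(cfg, out_dir = dir)
  expect_true(file.exists(file.path(dir, "rec01.edf")))
  ann <- read_annotations(file.path(dir, "rec01_hypnogram.csv"),
                          file.path(dir, "rec01_events.csv"))
  expect_identical(ann$hypnogram$labels, sims[[1]]$hypnogram$labels)
  expect_equal(nrow(ann$events), nrow(sims[[1]]$events))
  back <- read_recording(file.path(dir, "rec01.edf"), c("C3", "chin"))
  expect_identical(n_samples(back), n_samples(sims[[1]]$recording))
})
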