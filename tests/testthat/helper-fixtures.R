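# Shared fixtures, built in code at test time.

# a seven-channel recording of band-limited noise, whole seconds long
make_noise_recording <- function(duration = 60, fs = 200, seed = 42,
                                 rms = 2e-5) {
  set.seed(seed)
  n <- round(duration * fs)
  ch <- c("C3", "C4", "O1", "O2", "F3", "F4", "chin")
  bt <- signal::butter(2, c(1, 40) / (fs / 2), type = "pass")
  channels <- stats::setNames(lapply(ch, function(x) {
    v <- as.numeric(signal::filter(bt, rnorm(n)))
    v / sd(v) * rms
  }), ch)
  psg_recording(channels, fs = fs)
}

# a small synthetic dataset memoised across tests in one run
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_recordings = 1, duration = 900,
                              arousal_rate = 40, seed = 99,
                              class_separation = 6)
      cache <<- generate_recording(cfg, seed = 99, keep_background = TRUE)
      cache$config <- cfg
    }
    cache
  }
})

# segment pair with known content: pure sines on every composite channel
make_sine_pair <- function(len = 640, fs = 128, freq = 10, amp = 1) {
  t <- (seq_len(len) - 1) / fs
  seg <- amp * sin(2 * pi * freq * t)
  sigs <- list(C34 = seg, O12 = seg, F34 = seg, chin = seg,
               C3 = seg, C4 = seg)
  structure(list(arousal = sigs, pre = sigs, fs = fs,
                 event = list(onset = 60, duration = len / fs)),
            class = "segment_pair")
}

# labelled toy features: the class is the XOR of sign(f1) and sign(f2) with
# a margin, so BOTH informative features are required (either alone is
# useless); the rest are pure noise
make_toy_classification <- function(n_per_class = 40, n_noise = 8, seed = 5) {
  set.seed(seed)
  n <- 2 * n_per_class
  sgn <- function() sample(c(-1, 1), n, replace = TRUE)
  s1 <- sgn(); s2 <- sgn()
  f1 <- s1 * runif(n, 0.25, 1)
  f2 <- s2 * runif(n, 0.25, 1)
  lv <- as.integer(s1 * s2 > 0)
  noise <- matrix(rnorm(n * n_noise), ncol = n_noise)
  colnames(noise) <- paste0("noise", seq_len(n_noise))
  df <- data.frame(event_id = sprintf("t%03d", seq_len(n)), level = lv,
                   f1 = f1, f2 = f2, noise)
  df[sample(nrow(df)), ]
}
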