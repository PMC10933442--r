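# Detrended fluctuation analysis.

#' Detrended fluctuation analysis scaling exponent
#'
#' Standard first-order DFA: the mean-removed series is integrated, divided
#' into non-overlapping windows of sizes log-spaced between `min_window` and
#' `length(series)/4`, each window is linearly detrended, and the scaling
#' exponent `alpha` is the least-squares slope of `log F(n)` against `log n`,
#' where `F(n)` is the root-mean-square residual fluctuation at window size
#' `n`. White noise yields `alpha` near 0.5; Brownian-like (integrated white)
#' signals near 1.5.
#'
#' @param series Numeric vector, length at least `4 * min_window`.
#' @param min_window Smallest window size (default 4 samples).
#' @param n_sizes Number of log-spaced window sizes (default 12).
#' @return The scaling exponent `alpha` (dimensionless scalar).
#' @export
dfa_exponent <- function(series, min_window = 4L, n_sizes = 12L) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 4L * min_window) {
    stop(sprintf("series too short for DFA: need >= %d samples, got %d",
                 4L * min_window, n))
  }
  y <- cumsum(series - mean(series))
  sizes <- unique(round(exp(seq(log(min_window), log(n %/% 4L),
                                length.out = n_sizes))))
  sizes <- sizes[sizes >= min_window & sizes <= n %/% 2L]
  fluct <- vapply(sizes, function(s) {
    m <- n %/% s
    ym <- matrix(y[seq_len(m * s)], nrow = s)
    t <- seq_len(s)
    tc <- t - mean(t)
    stt <- sum(tc^2)
    slope <- drop(crossprod(tc, ym)) / stt          # per-window OLS slope
    resid <- ym - mean(t) * 0 -                      # detrend each column
      (matrix(colMeans(ym), nrow = s, ncol = m, byrow = TRUE) +
         outer(tc, slope))
    sqrt(mean(resid^2))
  }, numeric(1))
  keep <- fluct > 0
  stats::coef(stats::lm(log(fluct[keep]) ~ log(sizes[keep])))[[2L]]
}
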