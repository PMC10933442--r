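# Discrete wavelet transform (Daubechies-4, periodization) and the per-signal
# wavelet feature block.

# Orthonormal db4 analysis filters (4 vanishing moments, 8 taps).
# dec_hi is the quadrature mirror of dec_lo: h[m] = (-1)^m lo[L-1-m].
.db4_dec_lo <- c(-0.010597401785069032, 0.0328830116668852,
                 0.030841381835560764, -0.18703481171909309,
                 -0.027983769416859854, 0.6308807679298589,
                 0.7148465705529157, 0.2303778133088965)
.db4_dec_hi <- rev(.db4_dec_lo) * c(1, -1, 1, -1, 1, -1, 1, -1)

.dwt_step <- function(x, lo = .db4_dec_lo, hi = .db4_dec_hi) {
  n <- length(x)
  if (n %% 2L == 1L) {              # edge-pad odd lengths to even
    x <- c(x, x[n])
    n <- n + 1L
  }
  half <- n %/% 2L
  L <- length(lo)
  # circular convolution + dyadic downsampling: row k uses x[(2k+1-m) mod n]
  idx <- (outer(2L * seq_len(half) - 1L, 0:(L - 1L), "-") %% n) + 1L
  xm <- matrix(x[idx], nrow = half)
  list(approx = drop(xm %*% lo), detail = drop(xm %*% hi))
}

#' 5-level discrete wavelet transform of a segment
#'
#' Decomposes a signal segment with the Daubechies order-4 wavelet using
#' periodization boundary handling, returning the detail coefficient sets
#' `D1`..`D5` (finest to coarsest) and the level-5 approximation `A5`.
#' At a sampling rate of 128 Hz the detail sets cover the dyadic bands
#' 32-64, 16-32, 8-16, 4-8 and 2-4 Hz, with `A5` holding 0-2 Hz.
#'
#' With periodization the transform is orthonormal, so total coefficient
#' energy equals signal energy exactly when the segment length is divisible
#' by `2^levels`; odd intermediate lengths are edge-padded (as PyWavelets
#' does), which perturbs energy conservation slightly.
#'
#' @param segment Numeric vector, length at least `2^levels`.
#' @param levels Number of decomposition levels (default 5).
#' @return A named list `D1`,...,`D5`,`A5` of coefficient vectors, with
#'   attribute `levels`.
#' @export
dwt_decompose <- function(segment, levels = 5L) {
  segment <- as.numeric(segment)
  minimum <- 2L^levels
  if (length(segment) < minimum) {
    stop(sprintf("segment too short for a %d-level DWT: need >= %d samples, got %d",
                 levels, minimum, length(segment)))
  }
  if (any(!is.finite(segment))) stop("segment contains non-finite samples")
  details <- vector("list", levels)
  a <- segment
  for (lev in seq_len(levels)) {
    st <- .dwt_step(a)
    details[[lev]] <- st$detail
    a <- st$approx
  }
  out <- details
  names(out) <- paste0("D", seq_len(levels))
  out[[paste0("A", levels)]] <- a
  attr(out, "levels") <- levels
  out
}

# Coefficient sets ordered fine -> coarse; ratio numerators are always the
# finer set, following the enumeration D1/D2, D1/D3, ..., D5/A5.
.dwt_set_names <- c("D1", "D2", "D3", "D4", "D5", "A5")

.mabs_ratio_pairs <- function(sets = .dwt_set_names) {
  pairs <- utils::combn(seq_along(sets), 2L)
  data.frame(num = sets[pairs[1L, ]], den = sets[pairs[2L, ]],
             stringsAsFactors = FALSE)
}

#' Wavelet feature block for one signal
#'
#' Computes the 33 wavelet-domain statistics of one decomposed signal: the
#' mean power (mean squared coefficient), the mean absolute value (MABS) and
#' the variance of each of the six coefficient sets, plus the 15 MABS ratios
#' over all unordered set pairs with the finer-scale set in the numerator.
#'
#' @param decomposition A decomposition from [dwt_decompose()].
#' @param eps Guard for zero MABS denominators (default 1e-24, far below any
#'   genuine coefficient power in volts); a zero denominator is floored
#'   at `eps` and the result flagged via the `"guarded"` attribute.
#' @return Named numeric vector of length 33 (names carry no signal prefix).
#' @export
wavelet_feature_block <- function(decomposition, eps = 1e-24) {
  sets <- .dwt_set_names
  stopifnot(all(sets %in% names(decomposition)))
  mpow <- vapply(sets, function(s) mean(decomposition[[s]]^2), numeric(1))
  mabs <- vapply(sets, function(s) mean(abs(decomposition[[s]])), numeric(1))
  varc <- vapply(sets, function(s) {
    v <- decomposition[[s]]
    if (length(v) < 2L) 0 else stats::var(v)
  }, numeric(1))
  pairs <- .mabs_ratio_pairs(sets)
  guarded <- FALSE
  ratios <- vapply(seq_len(nrow(pairs)), function(i) {
    den <- mabs[[pairs$den[i]]]
    if (den < eps) {
      guarded <<- TRUE
      den <- eps
    }
    mabs[[pairs$num[i]]] / den
  }, numeric(1))
  out <- c(stats::setNames(mpow, paste0("mpow_", sets)),
           stats::setNames(mabs, paste0("mabs_", sets)),
           stats::setNames(ratios, paste0("mabsratio_", pairs$num, "_", pairs$den)),
           stats::setNames(varc, paste0("var_", sets)))
  attr(out, "guarded") <- guarded
  out
}
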