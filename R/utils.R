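# Shared numerical helpers: random variates, 1/f noise, interval algebra,
# and zero-phase FIR filtering via FFT convolution.

#' Inverse-Gaussian random variates
#'
#' Draws from the inverse-Gaussian (Wald) distribution with mean `mu` and
#' shape `lambda`, using the Michael-Schucany-Haas transformation.
#' The density is right-skewed, which matches the empirical shape of
#' response-time distributions; variance is `mu^3 / lambda`.
#'
#' @param n Number of draws.
#' @param mu Mean (> 0).
#' @param lambda Shape (> 0).
#' @return Numeric vector of positive draws.
#' @export
rinvgauss <- function(n, mu, lambda) {
  stopifnot(all(mu > 0), all(lambda > 0))
  nu <- stats::rnorm(n)
  y <- nu^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

#' Power-law (1/f^alpha) background noise
#'
#' Generates Gaussian noise whose power spectral density falls off as
#' `1/f^alpha`, the canonical shape of broadband EEG background activity,
#' by shaping white Gaussian noise in the frequency domain. The output is
#' scaled to the requested standard deviation.
#'
#' @param n Number of samples.
#' @param fs Sampling rate in Hz.
#' @param alpha Spectral exponent (1 = pink noise).
#' @param sd Target standard deviation (microvolts).
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, fs, alpha = 1, sd = 1) {
  nfft <- 2^ceiling(log2(max(n, 2)))
  half <- nfft %/% 2
  f <- (seq_len(half - 1)) * fs / nfft
  gain <- ifelse(f >= 0.25, 1 / f^(alpha / 2), 0)  # avoid blow-up at DC
  # synthesize a Hermitian spectrum with complex-Gaussian bins, one IFFT
  pos <- complex(real = stats::rnorm(half - 1), imaginary = stats::rnorm(half - 1)) * gain
  spec <- c(0, pos, 0, Conj(rev(pos)))
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  if (sd == 0) return(numeric(n))
  x * sd / stats::sd(x)
}

# --- half-open interval [a, b) algebra for artifact masks ------------------

#' Merge overlapping half-open intervals
#' @param intervals Two-column matrix (start, end), seconds; may have 0 rows.
#' @return Matrix of disjoint, sorted half-open intervals.
#' @keywords internal
merge_intervals <- function(intervals) {
  if (is.null(intervals) || NROW(intervals) == 0L)
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  iv <- matrix(as.numeric(intervals), ncol = 2)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    if (iv[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else out <- rbind(out, iv[i, ])
  }
  colnames(out) <- c("start", "end")
  out
}

#' Fraction of a window covered by mask intervals
#' @keywords internal
masked_fraction <- function(mask, start, end) {
  if (NROW(mask) == 0L || end <= start) return(0)
  ov <- pmin(mask[, 2], end) - pmax(mask[, 1], start)
  sum(pmax(ov, 0)) / (end - start)
}

#' Logical index of samples falling inside mask intervals
#' @keywords internal
mask_to_samples <- function(mask, n, fs) {
  bad <- logical(n)
  if (NROW(mask) == 0L) return(bad)
  for (i in seq_len(nrow(mask))) {
    a <- max(1L, floor(mask[i, 1] * fs) + 1L)
    b <- min(n, ceiling(mask[i, 2] * fs))
    if (b >= a) bad[a:b] <- TRUE
  }
  bad
}

# --- zero-phase FIR filtering ----------------------------------------------

#' Design a Hamming-windowed FIR band-pass filter
#'
#' Transition bandwidth is 25% of each band edge with a 1 Hz floor; the
#' filter order follows the Hamming-window rule (normalized transition
#' width ~ 3.3 / N). Band edges are the -6 dB points, so the passband is
#' flat across the nominal band and transitions are symmetric about the
#' printed edges.
#'
#' @param low,high Band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of FIR coefficients (odd length, linear phase).
#' @keywords internal
design_bandpass <- function(low, high, fs) {
  stopifnot(low > 0, high > low)
  if (high >= fs / 2) stop("band edge at or above Nyquist (", fs / 2, " Hz)")
  tb <- min(max(1, 0.25 * low), max(1, 0.25 * high))
  n <- ceiling(3.3 * fs / tb)
  if (n %% 2 == 1) n <- n + 1          # even order -> odd length, integer delay
  signal::fir1(n, c(low, high) / (fs / 2), type = "pass")
}

#' Zero-phase FIR filtering via FFT convolution
#'
#' Applies a linear-phase FIR filter with the group delay removed, so the
#' output is aligned 1:1 with the input samples. Linear convolution is done
#' in the frequency domain (zero-padded FFT), which keeps long filters on
#' long recordings cheap.
#'
#' @param x Signal vector.
#' @param h FIR coefficients (odd length, symmetric).
#' @return Filtered signal, same length as `x`.
#' @keywords internal
fir_filtfft <- function(x, h) {
  n <- length(x); m <- length(h)
  nfft <- 2^ceiling(log2(n + m - 1))
  y <- Re(stats::fft(stats::fft(c(x, rep(0, nfft - n))) *
                     stats::fft(c(h, rep(0, nfft - m))), inverse = TRUE)) / nfft
  delay <- (m - 1) / 2
  y[seq_len(n) + delay]
}

#' Low-pass and downsample a multichannel recording
#'
#' Zero-phase (centered symmetric FIR) anti-alias filtering followed by
#' decimation. The filter is designed to keep the analysis band (up to
#' `protect` Hz) flat and to attenuate everything that would fold back
#' onto it, which permits a short kernel and fast convolution. Used to
#' bring 512 Hz data to a rate where narrow low-frequency band-pass
#' filters are short.
#'
#' @param samples channels x time matrix.
#' @param fs Original sampling rate.
#' @param fs_out Target sampling rate; must divide `fs`.
#' @param protect Upper edge (Hz) of the band that must pass undistorted;
#'   must be below `fs_out / 2`.
#' @return List with `samples` (decimated matrix) and `fs`.
#' @keywords internal
decimate_channels <- function(samples, fs, fs_out, protect = 13) {
  stopifnot(fs %% fs_out == 0)
  if (fs == fs_out) return(list(samples = samples, fs = fs))
  stopifnot(protect < fs_out / 2)
  tb <- fs_out - 2 * protect           # transition protect .. fs_out - protect
  ntap <- ceiling(3.3 * fs / tb)
  if (ntap %% 2 == 1) ntap <- ntap + 1
  h <- signal::fir1(ntap, (fs_out / 2) / (fs / 2), type = "low")
  pad <- (length(h) - 1) / 2
  idx <- seq(1, ncol(samples), by = fs %/% fs_out)
  # polyphase: the kept output samples are computed directly, so the
  # convolution costs 1/decimation-factor of a full filtering pass
  out <- matrix(0, nrow(samples), length(idx))
  for (i in seq_len(nrow(samples))) {
    xp <- c(rep(0, pad), samples[i, ], rep(0, pad))
    y <- numeric(length(idx))
    for (j in seq_along(h))
      y <- y + h[j] * xp[idx + j - 1]
    out[i, ] <- y
  }
  list(samples = out, fs = fs_out)
}
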