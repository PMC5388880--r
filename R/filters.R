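#' @keywords internal
# odd tap count so the linear-phase FIR has an integer group delay
.odd_taps <- function(n) {
  n <- max(9L, as.integer(round(n)))
  if (n %% 2L == 0L) n + 1L else n
}

# windowed-sinc (Hamming) linear-phase FIR band-pass; order is `cycles`
# periods of the band's low edge
.fir_gain <- function(h, f, fs) {
  Mod(sum(h * exp(-2i * pi * f * (seq_along(h) - 1) / fs)))
}

.fir_bandpass <- function(fs, low, high, cycles = 3, taps = NULL) {
  if (low <= 0 || high <= low) stop("invalid band")
  if (high >= fs / 2) stop("band edge at or above Nyquist")
  ntaps <- if (is.null(taps)) .odd_taps(cycles * fs / low) else .odd_taps(taps)
  h <- as.numeric(signal::fir1(ntaps - 1L, c(low, high) / (fs / 2),
                               type = "pass"))
  h / .fir_gain(h, (low + high) / 2, fs)   # unit gain at band center
}

.fir_lowpass <- function(fs, cutoff, cycles = 3) {
  if (cutoff <= 0 || cutoff >= fs / 2) stop("invalid cutoff")
  ntaps <- .odd_taps(cycles * fs / cutoff)
  h <- as.numeric(signal::fir1(ntaps - 1L, cutoff / (fs / 2), type = "low"))
  h / sum(h)                               # unit gain at DC
}

# zero-phase FIR filtering: forward-backward application of a symmetric
# linear-phase FIR, computed in one pass as convolution with conv(h, rev(h))
# via FFT. Exact group delay compensation; the first/last length(h) samples
# carry edge transients and must be excluded downstream.
.fir_filtfilt <- function(x, h) {
  n <- length(x)
  m <- length(h)
  if (m >= n) stop("filter longer than signal")
  g <- stats::convolve(h, rev(h), type = "open")  # length 2m-1, symmetric
  L <- stats::nextn(n + 2L * m - 2L, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(L - n)))
  G <- stats::fft(c(g, numeric(L - (2L * m - 1L))))
  y <- Re(stats::fft(X * G, inverse = TRUE)) / L
  y[m:(m + n - 1L)]
}

# analytic signal via FFT: x + i * Hilbert(x)
.analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2L == 0L) {
    w[1L] <- 1
    w[n / 2L + 1L] <- 1
    w[2:(n / 2L)] <- 2
  } else {
    w[1L] <- 1
    w[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * w, inverse = TRUE) / n
}

# largest 5-smooth (2^a 3^b 5^c) integer <= n; keeps FFTs on friendly lengths
.prev_nice_length <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2, 3, 5)) while (k %% p == 0) k <- k / p
    if (k == 1) return(m)
    m <- m - 1L
  }
}
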