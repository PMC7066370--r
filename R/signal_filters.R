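# The two smoothing operators of the pipeline: a zero-lag 2nd-order
# Butterworth low-pass for coordinates and a zero-phase moving average for
# ankle-speed signals.

# Direct-form II transposed IIR filter with optional initial state.
lfilter <- function(b, a, x, zi = NULL) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  n <- length(x)
  y <- numeric(n)
  z <- if (is.null(zi)) rep(0, nf - 1) else zi
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nf > 2)
      for (j in seq_len(nf - 2)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    z[nf - 1] <- b[nf] * xi - a[nf] * yi
    y[i] <- yi
  }
  y
}

# Steady-state filter state for a unit-amplitude step input, so that a
# constant signal passes through with no transient.
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  n <- nf - 1
  comp <- matrix(0, n, n)           # companion matrix of a
  comp[1, ] <- -a[-1]
  if (n > 1) comp[cbind(2:n, 1:(n - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n) - t(comp), B)
}

# Odd (point-symmetric) reflection padding about the end samples.
odd_pad <- function(x, pad) {
  n <- length(x)
  if (pad >= n) stop("signal too short for edge padding")
  c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
}

#' Zero-phase 2nd-order Butterworth low-pass filter
#'
#' Designs a 2nd-order digital Butterworth low-pass (bilinear transform with
#' frequency prewarping) and applies it forward and backward, giving zero
#' phase lag and an effective 4th-order magnitude response. Edges are
#' handled by odd reflection padding of length `3 * (order + 1)` with
#' steady-state initial conditions, so a constant signal is left untouched.
#'
#' @param x Numeric signal.
#' @param fs Sampling frequency (Hz).
#' @param fc Cut-off frequency (Hz), default 10; must satisfy `fc < fs / 2`.
#'
#' @return Filtered signal, same length as `x`.
#' @export
butter2_zero_phase <- function(x, fs, fc = 10) {
  if (fc >= fs / 2) stop("cut-off must be below the Nyquist frequency fs/2")
  ba <- signal::butter(2, fc / (fs / 2), type = "low")
  filtfilt_pad(ba$b, ba$a, x, pad = 3 * (2 + 1))
}

# Forward-backward filtering with odd reflection padding and steady-state
# initialization on both passes.
filtfilt_pad <- function(b, a, x, pad) {
  if (length(x) < pad + 1)
    stop(sprintf("signal too short to filter (need > %d samples)", pad))
  zi <- lfilter_zi(b, a)
  xp <- odd_pad(x, pad)
  y <- lfilter(b, a, xp, zi * xp[1])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + length(x))]
}

# Symmetric moving-average kernel of effective width `window` samples.
# Odd windows are a plain centered boxcar; even windows are centered between
# samples, realised as window+1 taps with half-weight endpoints.
ma_kernel <- function(window) {
  if (window < 1 || window != round(window)) stop("window must be a positive integer")
  if (window %% 2 == 1) rep(1 / window, window)
  else c(0.5, rep(1, window - 1), 0.5) / window
}

#' Zero-phase moving-average smoother
#'
#' Centered moving average of effective width `window` samples with DC gain
#' exactly 1. Even windows are realised as a symmetric `window + 1`-tap
#' kernel with half-weight endpoints. Edges are handled by odd reflection
#' padding. The default window of 24 samples places the first zero of the
#' transfer function at 1.25 Hz for a 30 Hz signal, the band edge used to
#' smooth ankle-speed signals before gait-event detection.
#'
#' @param x Numeric signal, at least `window + 1` samples.
#' @param window Effective averaging width in samples (default 24).
#'
#' @return Smoothed signal, same length as `x`.
#' @export
moving_average_smooth <- function(x, window = 24) {
  h <- ma_kernel(window)
  half <- (length(h) - 1) / 2
  if (window >= length(x)) stop("window must be shorter than the signal")
  xp <- odd_pad(x, max(half, 1))
  y <- stats::filter(xp, h, method = "convolution", sides = 2)
  as.numeric(y[(max(half, 1) + 1):(max(half, 1) + length(x))])
}

#' Transfer-function magnitude of the moving-average smoother
#'
#' Evaluates the magnitude of the frequency response of the kernel used by
#' [moving_average_smooth()] at the requested frequencies.
#'
#' @param f Frequencies (Hz) at which to evaluate.
#' @param fs Sampling frequency (Hz).
#' @param window Effective averaging width in samples (default 24).
#'
#' @return Numeric vector of magnitudes (1 at DC).
#' @export
moving_average_gain <- function(f, fs, window = 24) {
  h <- ma_kernel(window)
  k <- seq_along(h) - (length(h) + 1) / 2   # taps centered at zero
  vapply(f, function(fi) {
    Mod(sum(h * exp(-2i * pi * fi * k / fs)))
  }, numeric(1))
}

#' Lowest frequency at which the smoother's transfer function vanishes
#'
#' Scans the gain of the default ankle-speed smoother on a dense grid over
#' `(0, fs/2]` and refines each sign change of the (real, zero-phase)
#' frequency response by root finding.
#'
#' @param fs Sampling frequency (Hz).
#' @param window Effective averaging width in samples (default 24).
#' @param grid_n Number of grid points (default 30000).
#'
#' @return Frequency in Hz of the first transfer-function zero.
#' @export
first_transfer_zero <- function(fs, window = 24, grid_n = 30000) {
  h <- ma_kernel(window)
  k <- seq_along(h) - (length(h) + 1) / 2
  # zero-phase kernel: response is real; zeros are sign changes
  resp <- function(fi) sum(h * cos(2 * pi * fi * k / fs))
  f <- seq(0, fs / 2, length.out = grid_n + 1)[-1]
  r <- vapply(f, resp, numeric(1))
  sc <- which(r[-1] * r[-length(r)] <= 0)
  if (length(sc) == 0) stop("no transfer-function zero below Nyquist")
  root <- stats::uniroot(resp, c(f[sc[1]], f[sc[1] + 1]), tol = 1e-12)
  root$root
}
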