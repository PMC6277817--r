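# Shared numerical utilities: analytic signal, Morlet wavelet transform,
# Butterworth design + zero-phase filtering, circular statistics.

#' Analytic signal via the FFT
#'
#' Returns the complex analytic signal whose real part is `x` and whose
#' modulus is the instantaneous amplitude (Hilbert envelope).
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) return(as.complex(x))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) / 2L)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase (radians) of a signal
#' @param x numeric vector.
#' @return phase in (-pi, pi].
#' @export
instantaneous_phase <- function(x) Arg(analytic_signal(x))

# amplitude-weighted mean Hilbert instantaneous frequency of one signal
mean_instantaneous_frequency <- function(x, fs) {
  a <- analytic_signal(x)
  n <- length(a)
  if (n < 3L || all(abs(x) < .Machine$double.eps)) return(0)
  dphi <- Arg(a[-1L] * Conj(a[-n]))     # wrapped phase increments
  instf <- dphi * fs / (2 * pi)
  w <- (Mod(a)[-1L] + Mod(a)[-n]) / 2
  if (sum(w) <= 0) return(0)
  f <- sum(pmax(instf, 0) * w) / sum(w)
  max(f, 0)
}

# ---------------------------------------------------------------------------
# Morlet wavelet machinery.  The analytic Morlet at frequency f has the
# frequency-domain window 2 * exp(-(s*w - omega0)^2 / 2) for w > 0 with
# s = omega0 / (2*pi*f), so a real tone A*cos(2*pi*f*t) yields wavelet
# amplitude A at its own frequency.

morlet_fft_plan <- function(x, fs) {
  n <- length(x)
  nfft <- 2L^ceiling(log2(n + max(64L, round(fs))))
  X <- fft(c(x, numeric(nfft - n)))
  w <- 2 * pi * fs * c(0L:(nfft %/% 2L), -(nfft %/% 2L - 1L):-1L) / nfft
  list(X = X, w = w, n = n, nfft = nfft)
}

morlet_amplitude_one <- function(plan, f, omega0 = 5) {
  s <- omega0 / (2 * pi * f)
  H <- numeric(plan$nfft)
  pos <- plan$w > 0
  H[pos] <- 2 * exp(-(s * plan$w[pos] - omega0)^2 / 2)
  Mod(fft(plan$X * H, inverse = TRUE)[seq_len(plan$n)]) / plan$nfft
}

#' Morlet wavelet amplitude spectrogram
#'
#' Complex Morlet amplitude (envelope) of `x` on a grid of main frequencies.
#' Computed by FFT convolution; for long signals prefer the per-frequency
#' accumulators used internally ([spectral_signatures()] etc.) to avoid
#' holding the full matrix.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param freqs main frequencies, Hz (default 10-200 Hz in 1-Hz steps).
#' @param omega0 dimensionless Morlet width parameter (default 5).
#' @return matrix `length(freqs)` x `length(x)` of amplitudes.
#' @export
wavelet_amplitude <- function(x, fs, freqs = 10:200, omega0 = 5) {
  plan <- morlet_fft_plan(x, fs)
  out <- matrix(0, length(freqs), length(x))
  for (i in seq_along(freqs))
    out[i, ] <- morlet_amplitude_one(plan, freqs[i], omega0)
  rownames(out) <- freqs
  out
}

# apply fun(i, amp_vector) for each frequency without storing the matrix
morlet_apply <- function(x, fs, freqs, omega0 = 5, fun) {
  plan <- morlet_fft_plan(x, fs)
  for (i in seq_along(freqs)) fun(i, morlet_amplitude_one(plan, freqs[i], omega0))
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Butterworth design (bilinear transform of the analog prototype) and
# zero-phase filtering.  Order `n` is the analog prototype order; a
# band-pass therefore has 2n poles, matching the usual "2nd-order
# Butterworth band-pass" phrasing.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p) * ri
  p
}

#' Butterworth filter coefficients
#'
#' @param n prototype order.
#' @param cutoff cutoff frequency in Hz (length 1 for low/high pass,
#'   length 2 for band-pass).
#' @param fs sampling rate, Hz.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return list with numerator `b` and denominator `a` (a\[1\] = 1).
#' @export
butter_design <- function(n, cutoff, fs, type = c("pass", "low", "high")) {
  type <- match.arg(type)
  stopifnot(n >= 1, all(cutoff > 0), all(cutoff < fs / 2))
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))   # prototype poles, Re < 0
  wc <- 2 * fs * tan(pi * cutoff / fs)            # prewarped rad/s
  if (type == "low") {
    pa <- p * wc; za <- complex(0); ka <- wc^n
  } else if (type == "high") {
    pa <- wc / p; za <- rep(0 + 0i, n)
    ka <- 1
  } else {
    if (length(cutoff) != 2L || cutoff[1] >= cutoff[2])
      stop("band-pass needs cutoff = c(low, high)")
    w0 <- sqrt(prod(wc)); bw <- wc[2] - wc[1]
    pb <- p * bw / 2
    disc <- sqrt(pb^2 - w0^2)
    pa <- c(pb + disc, pb - disc)
    za <- rep(0 + 0i, n)
    ka <- bw^n
  }
  fs2 <- 2 * fs
  zd <- (fs2 + za) / (fs2 - za)
  pd <- (fs2 + pa) / (fs2 - pa)
  kd <- ka * Re(prod(fs2 - za) / prod(fs2 - pa))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b / a[1], a = a / a[1])
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter twice (time-reversed the second pass), doubling the
#' effective order and cancelling phase distortion.  Edges are padded with
#' odd reflection before filtering.
#'
#' @param b,a filter coefficients as from [butter_design()].
#' @param x signal.
#' @return filtered signal, same length as `x`.
#' @export
filtfilt_iir <- function(b, a, x) {
  n <- length(x)
  npad <- min(n - 1L, max(3L * (max(length(a), length(b)) - 1L), 250L))
  pre <- 2 * x[1L] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xp <- c(pre, x, post)
  y <- iir_filter_cpp(b, a, xp)
  y <- rev(iir_filter_cpp(b, a, rev(y)))
  y[(npad + 1L):(npad + n)]
}

# ---------------------------------------------------------------------------
# Circular statistics (phases in radians unless noted)

circ_r <- function(phi) {
  if (!length(phi)) return(NA_real_)
  Mod(mean(exp(1i * phi)))
}

circ_mean <- function(phi) Arg(mean(exp(1i * phi)))

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

wrap_deg <- function(d) ((d + 180) %% 360) - 180

# circular Gaussian smoothing of a vector sampled on equally spaced bins
circ_gauss_smooth <- function(v, sd_bins) {
  nb <- length(v)
  if (sd_bins <= 0) return(v)
  lag <- c(0:(nb %/% 2), -((nb - nb %/% 2 - 1):1))
  k <- exp(-lag^2 / (2 * sd_bins^2))
  k <- k / sum(k)
  na <- is.na(v)
  v0 <- ifelse(na, 0, v)
  sm <- Re(fft(fft(v0) * fft(k), inverse = TRUE)) / nb
  wt <- Re(fft(fft(as.numeric(!na)) * fft(k), inverse = TRUE)) / nb
  out <- sm / wt
  out[wt < 1e-10] <- NA_real_
  out
}
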