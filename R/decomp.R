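# EEMD decomposition of an LFP into intrinsic mode functions (IMFs) and
# their classification into low (< 5 Hz), theta (5-12 Hz) and supra-theta
# (> 12 Hz) composite signals by mean instantaneous frequency.

#' Ensemble empirical mode decomposition
#'
#' Decomposes `signal` into IMFs by sifting (cubic-spline envelopes,
#' Cauchy-type stop criterion, mirror-extended boundaries), averaged over
#' an ensemble of added white-noise realizations.  Noise realizations are
#' added in complementary `+/-` pairs so the averaged IMFs plus the
#' residual reconstruct the input exactly (complete-ensemble variant).
#' The mean frequency of each IMF is the amplitude-weighted mean of its
#' Hilbert instantaneous frequency.
#'
#' @param signal numeric vector.
#' @param fs sampling rate, Hz.
#' @param ensemble_size number of noise realizations (rounded up to an
#'   even number; 1 gives a single noisy realization).
#' @param noise_scale white-noise SD as a fraction of `sd(signal)`.
#' @param seed RNG seed.
#' @param max_imfs maximum number of IMFs (default `floor(log2(n)) - 1`).
#' @param max_sift maximum sifting sweeps per IMF.
#' @param sift_tol Cauchy stop criterion threshold.
#' @return an object of class `imf_set`: list with `imfs` (matrix,
#'   n_imfs x n, ordered by decreasing mean frequency), `residual`,
#'   `mean_freqs` (Hz) and `fs`.
#' @export
eemd <- function(signal, fs, ensemble_size = 100, noise_scale = 0.2,
                 seed = 1L, max_imfs = NULL, max_sift = 10L,
                 sift_tol = 0.2) {
  if (!all(is.finite(signal))) stop("signal contains non-finite values")
  n <- length(signal)
  if (n < 10 * fs / 5) stop("signal too short (need >= 10 slow cycles)")
  if (noise_scale <= 0) stop("noise_scale must be positive")
  if (is.null(max_imfs)) max_imfs <- max(floor(log2(n)) - 1L, 3L)
  set.seed(seed)
  s0 <- sd(signal)
  acc <- matrix(0, n, max_imfs)
  if (ensemble_size <= 1L) {
    w <- rnorm(n) * noise_scale * s0
    dec <- emd_cpp(signal + w, max_imfs, max_sift, sift_tol)
    k <- dec$n_imfs
    if (k > 0) acc[, seq_len(k)] <- dec$imfs[, seq_len(k)]
    n_real <- 1L
  } else {
    n_pair <- ceiling(ensemble_size / 2)
    n_real <- 2L * n_pair
    for (j in seq_len(n_pair)) {
      w <- rnorm(n) * noise_scale * s0
      for (sgn in c(1, -1)) {
        dec <- emd_cpp(signal + sgn * w, max_imfs, max_sift, sift_tol)
        k <- dec$n_imfs
        if (k > 0)
          acc[, seq_len(k)] <- acc[, seq_len(k)] + dec$imfs[, seq_len(k)]
      }
    }
    acc <- acc / n_real
  }
  # drop trailing all-(near-)zero modes
  keep <- apply(acc, 2L, function(v) sd(v) > 1e-12 * max(s0, 1e-300))
  acc <- acc[, keep, drop = FALSE]
  mf <- apply(acc, 2L, mean_instantaneous_frequency, fs = fs)
  ord <- order(mf, decreasing = TRUE)
  acc <- acc[, ord, drop = FALSE]
  mf <- mf[ord]
  residual <- signal - rowSums(acc)
  structure(list(imfs = t(acc), residual = residual,
                 mean_freqs = as.numeric(mf), fs = fs),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs, mean freqs (Hz): %s\n",
              nrow(x$imfs),
              paste(sprintf("%.2f", x$mean_freqs), collapse = ", ")))
  invisible(x)
}

#' Classify IMFs into low / theta / supra-theta composites
#'
#' Each IMF is assigned to exactly one band by its mean instantaneous
#' frequency: low below 5 Hz, theta in \[5, 12\] Hz (boundaries inclusive
#' to theta), supra-theta above 12 Hz.  Composites are sums of whole
#' IMFs; empty bands give zero composites.
#'
#' @param imfset an [eemd()] result.
#' @param theta_band theta frequency bounds, Hz.
#' @return an object of class `band_decomposition`: list with `low`,
#'   `theta`, `supra` (vectors), `bands` (per-IMF label) and `imfset`.
#' @export
classify_imfs <- function(imfset, theta_band = c(5, 12)) {
  stopifnot(inherits(imfset, "imf_set"))
  mf <- imfset$mean_freqs
  band <- ifelse(mf < theta_band[1], "low",
                 ifelse(mf <= theta_band[2], "theta", "supra"))
  n <- ncol(imfset$imfs)
  comp <- function(lbl) {
    sel <- band == lbl
    if (!any(sel)) return(numeric(n))
    colSums(imfset$imfs[sel, , drop = FALSE])
  }
  structure(list(low = comp("low"), theta = comp("theta"),
                 supra = comp("supra"), bands = band, imfset = imfset),
            class = "band_decomposition")
}

#' @export
print.band_decomposition <- function(x, ...) {
  cat(sprintf("<band_decomposition> bands: %s\n",
              paste(x$bands, collapse = ", ")))
  invisible(x)
}
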