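# Current source density (CSD) across a linear probe and layer-resolved
# phase-amplitude profiles of tSC cycles.

#' Current source density of a laminar LFP
#'
#' Discrete second spatial difference across equally spaced channels.
#' The default `"laplacian"` convention is
#' `CSD_n = -(V_{n-1} - 2 V_n + V_{n+1})` (a current sink between
#' channels appears positive); `"printed"` flips the sign of the
#' `V_{n+1}` term, `CSD_n = -(V_{n-1} - 2 V_n - V_{n+1})`, a variant
#' occasionally seen in print that is not a spatial Laplacian (a linear
#' depth profile then maps to a nonzero output).  Outer channels are
#' dropped.
#'
#' @param lfp an [lfp_record()] with at least 3 channels at uniform
#'   spacing.
#' @param formula `"laplacian"` (default) or `"printed"`.
#' @return matrix (channels - 2) x time, unscaled; row i corresponds to
#'   input channel i + 1.
#' @export
csd <- function(lfp, formula = c("laplacian", "printed")) {
  formula <- match.arg(formula)
  stopifnot(inherits(lfp, "lfp_record"))
  V <- lfp$samples
  nc <- nrow(V)
  if (nc < 3L) stop("CSD needs at least 3 channels")
  sp <- diff(lfp$channel_depths)
  if (max(abs(sp - sp[1])) > 1e-6 * abs(sp[1]))
    stop("channel spacing must be uniform")
  up <- V[1:(nc - 2L), , drop = FALSE]
  mid <- V[2:(nc - 1L), , drop = FALSE]
  dn <- V[3:nc, , drop = FALSE]
  out <- if (formula == "laplacian") -(up - 2 * mid + dn)
  else -(up - 2 * mid - dn)
  rownames(out) <- rownames(V)[2:(nc - 1L)]
  out
}

#' Pyramidal-layer channel: the one with the largest ripple-band power
#'
#' @param lfp laminar [lfp_record()].
#' @param band ripple band, Hz.
#' @return channel index.
#' @export
find_pyramidal_channel <- function(lfp, band = c(135, 250)) {
  bf <- butter_design(2, band, lfp$fs, "pass")
  pw <- apply(lfp$samples, 1L, function(x) mean(filtfilt_iir(bf$b, bf$a,
                                                             x)^2))
  which.max(pw)
}

#' Layer-resolved phase-amplitude profiles of CSD traces
#'
#' Applies [phase_amplitude_profile()] to each interior CSD trace, with
#' theta phase and tSC cycle selection always taken from the
#' pyramidal-layer LFP.
#'
#' @param csd_matrix output of [csd()].
#' @param phase [theta_phase()] series from the pyramidal-layer LFP.
#' @param cycle_subsets named list of cycle-id vectors (e.g. one per
#'   tSC); `NULL` entries mean all cycles.
#' @param fs sampling rate, Hz.
#' @param freqs frequency grid, Hz.
#' @param n_bins phase bins.
#' @return nested list: `[[subset]][[channel]]` phase x frequency
#'   matrices.
#' @export
layer_profiles <- function(csd_matrix, phase, cycle_subsets = list(all = NULL),
                           fs, freqs = 10:200, n_bins = 60L) {
  lapply(cycle_subsets, function(sub) {
    lapply(seq_len(nrow(csd_matrix)), function(ch) {
      phase_amplitude_profile(csd_matrix[ch, ], phase, cycle_subset = sub,
                              fs = fs, freqs = freqs, n_bins = n_bins)
    })
  })
}
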