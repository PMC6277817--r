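# Principal-cell firing modulation within tSC cycles: peak-triggered
# rates, spike-probability change (SPC) with per-phase ANOVA, tSC-signal
# phase coupling with circular-shift nulls, and trough-triggered rates.

spike_samples <- function(times, fs, t0 = 0) round((times - t0) * fs) + 1L

# cycle row index (in `cycles`) of each spike, using the spike-analysis
# bounds [spike_start, spike_end); NA when outside every cycle
assign_spikes_to_cycles <- function(times, cycles, fs, t0 = 0,
                                    bounds = c("spike", "trough")) {
  bounds <- match.arg(bounds)
  s <- spike_samples(times, fs, t0)
  lo <- if (bounds == "spike") cycles$spike_start else cycles$trough_start
  hi <- if (bounds == "spike") cycles$spike_end else cycles$trough_end
  ok <- !is.na(lo) & !is.na(hi)
  row <- rep(NA_integer_, length(s))
  idx <- which(ok)
  if (!length(idx)) return(row)
  o <- idx[order(lo[idx])]
  pos <- findInterval(s, lo[o])
  cand <- o[pmax(pos, 1L)]
  hit <- pos >= 1L & s >= lo[cand] & s < hi[cand]
  row[hit] <- cand[hit]
  row
}

#' Peak-triggered firing-rate curve
#'
#' Mean firing rate of one unit aligned to the theta-cycle peaks of a
#' cycle subset, in 0.8-ms bins, Gaussian-smoothed (10 ms SD) and
#' z-scored by the mean and SD of the all-cycles curve.
#'
#' @param times spike times of one unit, s.
#' @param cycles cycle table.
#' @param subset cycle ids defining the subset (default all).
#' @param fs sampling rate, Hz.
#' @param window half-width of the alignment window, s.
#' @param bin_s bin width, s (default 0.8 ms).
#' @param smooth_sd Gaussian kernel SD, s.
#' @param t0 time of the first LFP sample.
#' @return list with `lag` (s), `z` (z-scored subset curve), `rate`
#'   (smoothed subset mean rate, Hz), `baseline_rate` (all-cycles mean),
#'   `flagged` (TRUE when the unit has no spikes in the window).
#' @export
cycle_triggered_rate <- function(times, cycles, subset = NULL, fs,
                                 window = 0.08, bin_s = 0.0008,
                                 smooth_sd = 0.010, t0 = 0) {
  nb <- 2L * round(window / bin_s) + 1L
  lag <- (seq_len(nb) - (nb + 1L) / 2) * bin_s
  nc <- nrow(cycles)
  pk_t <- (cycles$peak - 1L) / fs + t0
  times <- sort(times)
  C <- matrix(0, nc, nb)
  for (j in seq_len(nc)) {
    lo <- findInterval(pk_t[j] - window - bin_s / 2, times) + 1L
    hi <- findInterval(pk_t[j] + window + bin_s / 2, times)
    if (hi >= lo) {
      d <- times[lo:hi] - pk_t[j]
      b <- pmin(pmax(round(d / bin_s) + (nb + 1L) / 2, 1L), nb)
      C[j, ] <- C[j, ] + tabulate(b, nb)
    }
  }
  rate <- C / bin_s
  # Gaussian smoothing along the lag axis (columns renormalized at edges)
  K <- outer(lag, lag, function(a, b) dnorm(a - b, sd = smooth_sd))
  K <- sweep(K, 2L, colSums(K), "/")
  S <- rate %*% K
  mu <- colMeans(S)
  sdv <- apply(S, 2L, sd)
  sdv[sdv == 0] <- 1
  sub_rows <- if (is.null(subset)) seq_len(nc) else
    which(cycles$cycle_id %in% subset)
  sub_curve <- colMeans(S[sub_rows, , drop = FALSE])
  list(lag = lag, z = (sub_curve - mu) / sdv, rate = sub_curve,
       baseline_rate = mu, flagged = all(sub_curve == 0))
}

# phase-binned rate of one unit over a set of cycle rows:
# spikes assigned by spike-analysis bounds, occupancy by valid samples
phase_binned_rate <- function(times, cycles, rows, phase, fs, n_bins,
                              t0 = 0) {
  row_of <- assign_spikes_to_cycles(times, cycles, fs, t0)
  keep <- !is.na(row_of) & row_of %in% rows
  s <- spike_samples(times[keep], fs, t0)
  ph <- phase$phase[pmin(pmax(s, 1L), length(phase$phase))]
  ph <- ph[!is.na(ph)]
  bin_of <- function(p) pmin(floor((p + 180) / (360 / n_bins)) + 1L, n_bins)
  cnt <- tabulate(bin_of(ph), n_bins)
  in_rows <- !is.na(phase$cycle) &
    phase$cycle %in% cycles$cycle_id[rows] & phase$valid
  occ <- tabulate(bin_of(phase$phase[in_rows]), n_bins) / fs
  rate <- ifelse(occ > 0, cnt / occ, NA_real_)
  rate
}

#' Spike-probability change vs theta phase
#'
#' `SPC(phase) = 100 * (rate_subset(phase) - rate_all(phase)) /
#' rate_all(phase)` per unit, over 60 theta-phase bins, circularly
#' smoothed with a 24-degree-SD Gaussian.  Spikes are assigned to cycles
#' by the ascending-zero spike-analysis bounds.  Bins where the overall
#' rate is zero are masked `NA`.
#'
#' @param spikes spike table (`unit`, `time`).
#' @param cycles cycle table.
#' @param subset cycle ids of the subset (e.g. cycles above one tSC's
#'   threshold).
#' @param phase a [theta_phase()] series.
#' @param fs sampling rate, Hz.
#' @param n_bins phase bins (default 60).
#' @param smooth_sd_deg circular Gaussian SD, degrees (default 24).
#' @param t0 time of the first LFP sample.
#' @return list with `bins` (degrees), `spc` (units x bins matrix) and
#'   `mean_spc` (unweighted unit average).
#' @export
spike_probability_change <- function(spikes, cycles, subset, phase, fs,
                                     n_bins = 60L, smooth_sd_deg = 24,
                                     t0 = 0) {
  units <- sort(unique(spikes$unit))
  sub_rows <- which(cycles$cycle_id %in% subset)
  all_rows <- seq_len(nrow(cycles))
  sd_bins <- smooth_sd_deg / (360 / n_bins)
  spc <- matrix(NA_real_, length(units), n_bins)
  for (i in seq_along(units)) {
    tt <- spikes$time[spikes$unit == units[i]]
    r_all <- phase_binned_rate(tt, cycles, all_rows, phase, fs, n_bins, t0)
    r_sub <- phase_binned_rate(tt, cycles, sub_rows, phase, fs, n_bins, t0)
    v <- ifelse(!is.na(r_all) & r_all > 0,
                100 * (r_sub - r_all) / r_all, NA_real_)
    spc[i, ] <- circ_gauss_smooth(v, sd_bins)
  }
  rownames(spc) <- units
  list(bins = -180 + (seq_len(n_bins) - 0.5) * 360 / n_bins, spc = spc,
       mean_spc = colMeans(spc, na.rm = TRUE))
}

#' Per-phase ANOVA of spike-probability change across tSCs
#'
#' At each theta phase bin, fits `SPC ~ tSC dummies + animal dummies`
#' (one animal as reference) by ordinary least squares over units, and
#' flags a tSC as significantly modulated when its coefficient's p value
#' stays below `alpha` in at least `min_run` consecutive bins
#' (circularly).
#'
#' @param spc_by_tsc list (one element per tSC) of unit x bin SPC
#'   matrices as from [spike_probability_change()].
#' @param animal_ids animal label per unit (recycled across tSCs).
#' @param alpha per-test threshold; default Bonferroni 0.05 / (n_tsc *
#'   n_bins).
#' @param min_run run length required (default 5).
#' @return list with `beta` (tSC x bin), `p` (tSC x bin), `alpha`, and
#'   `significant_runs` (per tSC, logical vector of bins inside a
#'   qualifying run).
#' @export
spc_significance <- function(spc_by_tsc, animal_ids, alpha = NULL,
                             min_run = 5L) {
  n_tsc <- length(spc_by_tsc)
  n_bins <- ncol(spc_by_tsc[[1]])
  n_units <- nrow(spc_by_tsc[[1]])
  if (is.null(alpha)) alpha <- 0.05 / (n_tsc * n_bins)
  stopifnot(length(animal_ids) == n_units)
  animal <- factor(rep(animal_ids, n_tsc))
  tsc <- factor(rep(seq_len(n_tsc), each = n_units))
  beta <- p <- matrix(NA_real_, n_tsc, n_bins)
  for (b in seq_len(n_bins)) {
    y <- unlist(lapply(spc_by_tsc, function(m) m[, b]))
    ok <- is.finite(y)
    df <- data.frame(y = y[ok], tsc = tsc[ok], animal = animal[ok])
    # no global intercept: each tSC dummy then measures that tSC's own
    # (animal-adjusted) mean SPC against zero; animal dummies keep their
    # first (lexicographic) level as reference
    fit <- if (nlevels(droplevels(df$animal)) > 1L)
      lm(y ~ 0 + tsc + animal, data = df) else lm(y ~ 0 + tsc, data = df)
    sm <- summary(fit)$coefficients
    for (k in seq_len(n_tsc)) {
      nm <- paste0("tsc", k)
      if (nm %in% rownames(sm)) {
        beta[k, b] <- sm[nm, 1L]; p[k, b] <- sm[nm, 4L]
      }
    }
  }
  runs <- lapply(seq_len(n_tsc), function(k) {
    sig <- !is.na(p[k, ]) & p[k, ] < alpha
    # circular run detection
    ext <- c(sig, sig)
    r <- rle(ext)
    inrun <- rep(FALSE, 2L * n_bins)
    at <- cumsum(c(1L, r$lengths))
    for (j in seq_along(r$lengths))
      if (r$values[j] && r$lengths[j] >= min_run)
        inrun[at[j]:(at[j] + r$lengths[j] - 1L)] <- TRUE
    inrun[seq_len(n_bins)] | inrun[n_bins + seq_len(n_bins)]
  })
  list(beta = beta, p = p, alpha = alpha, significant_runs = runs)
}

#' tSC signal: the IMF nearest a component's peak frequency
#'
#' Selects the IMF whose mean frequency is closest to the component's
#' peak frequency (ties broken toward the lower frequency) and returns
#' it with its Hilbert phase.
#'
#' @param model tSC model.
#' @param imfset the [eemd()] result.
#' @param tsc integer component index.
#' @return list with `signal`, `phase` (radians), `imf_index`,
#'   `mean_freq`.
#' @export
tsc_signal <- function(model, imfset, tsc) {
  pf <- model$peak_freqs[tsc]
  d <- abs(imfset$mean_freqs - pf)
  cand <- which(d == min(d))
  idx <- cand[which.min(imfset$mean_freqs[cand])]
  sig <- imfset$imfs[idx, ]
  list(signal = sig, phase = instantaneous_phase(sig), imf_index = idx,
       mean_freq = imfset$mean_freqs[idx])
}

#' Spike phase coupling to a tSC signal with a circular-shift null
#'
#' Mean vector length `r` of the tSC-signal phases sampled at the spikes
#' of one unit inside the subset cycles.  The null preserves each
#' spike's theta phase: every shift re-assigns each spike to a random
#' other subset cycle at the sample where that cycle reaches the spike's
#' original theta phase (inverse anchor interpolation), then re-reads
#' the tSC phase.  Significant iff `r` exceeds the 99.9th percentile of
#' `n_shift` such re-assignments; units with 100 or fewer spikes are
#' flagged ineligible.
#'
#' @param times spike times of one unit, s.
#' @param tsc_phase tSC-signal phase per sample, radians.
#' @param theta a [theta_phase()] series.
#' @param cycles cycle table.
#' @param subset cycle ids to use (e.g. above-threshold cycles).
#' @param fs sampling rate, Hz.
#' @param n_shift number of shift controls (default 2000).
#' @param min_spikes eligibility threshold (default 100, exclusive).
#' @param seed RNG seed.
#' @param t0 time of the first LFP sample.
#' @return list with `r`, `preferred_phase_deg`, `n_spikes`,
#'   `null_percentile`, `null_q999`, `significant`, `eligible`.
#' @export
phase_coupling <- function(times, tsc_phase, theta, cycles, subset = NULL,
                           fs, n_shift = 2000L, min_spikes = 100L,
                           seed = 1L, t0 = 0) {
  rows <- if (is.null(subset)) seq_len(nrow(cycles)) else
    which(cycles$cycle_id %in% subset)
  row_of <- assign_spikes_to_cycles(times, cycles, fs, t0,
                                    bounds = "trough")
  keep <- !is.na(row_of) & row_of %in% rows
  s <- spike_samples(times[keep], fs, t0)
  th <- theta$phase[s]
  ok <- !is.na(th)
  s <- s[ok]; th <- th[ok]
  n_sp <- length(s)
  phi <- tsc_phase[s]
  r <- circ_r(phi)
  pref <- rad2deg(circ_mean(phi))
  eligible <- n_sp > min_spikes
  set.seed(seed)
  null_r <- rep(NA_real_, n_shift)
  if (n_sp >= 2L && length(rows) >= 2L) {
    # hoist the anchor interpolation setup out of the shift loop
    A <- cycle_anchor_matrix(cycles)
    seg <- pmin(pmax(floor((th + 180) / 90) + 1, 1), 4)
    frac <- (th - anchor_phases[seg]) / 90
    np <- length(tsc_phase)
    for (b in seq_len(n_shift)) {
      tgt <- rows[sample.int(length(rows), n_sp, replace = TRUE)]
      a0 <- A[cbind(tgt, seg)]
      ns <- pmin(pmax(as.integer(a0 + frac * (A[cbind(tgt, seg + 1L)] -
                                                a0) + 0.5), 1L), np)
      null_r[b] <- circ_r(tsc_phase[ns])
    }
  }
  q999 <- quantile(null_r, 0.999, na.rm = TRUE, names = FALSE)
  pct <- mean(null_r < r, na.rm = TRUE) * 100
  list(r = r, preferred_phase_deg = pref, n_spikes = n_sp,
       null_percentile = pct, null_q999 = q999,
       significant = eligible && is.finite(q999) && r > q999,
       eligible = eligible)
}

#' Trough-triggered population rate around tSC-signal troughs
#'
#' One trigger per cycle: the most negative trough of the tSC signal
#' within each subset cycle.  Returns the mean spike rate around the
#' triggers.
#'
#' @param spikes spike table.
#' @param tsc_sig tSC signal vector (from [tsc_signal()]).
#' @param cycles cycle table.
#' @param subset cycle ids.
#' @param fs sampling rate, Hz.
#' @param window half-width, s.
#' @param bin_s bin width, s.
#' @param t0 time of the first LFP sample.
#' @return list with `lag`, `rate` (Hz, pooled over units), `triggers`
#'   (sample indices).
#' @export
trough_triggered_rate <- function(spikes, tsc_sig, cycles, subset = NULL,
                                  fs, window = 0.05, bin_s = 0.002,
                                  t0 = 0) {
  rows <- if (is.null(subset)) seq_len(nrow(cycles)) else
    which(cycles$cycle_id %in% subset)
  trig <- vapply(rows, function(j) {
    span <- cycles$trough_start[j]:(cycles$trough_end[j] - 1L)
    span[which.min(tsc_sig[span])]
  }, integer(1))
  nb <- 2L * round(window / bin_s) + 1L
  lag <- (seq_len(nb) - (nb + 1L) / 2) * bin_s
  cnt <- numeric(nb)
  tt <- spikes$time
  for (g in (trig - 1L) / fs + t0) {
    d <- tt - g
    d <- d[abs(d) <= window + bin_s / 2]
    if (length(d))
      cnt <- cnt + tabulate(pmin(pmax(round(d / bin_s) + (nb + 1L) / 2,
                                      1L), nb), nb)
  }
  list(lag = lag, rate = cnt / (length(trig) * bin_s), triggers = trig)
}
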