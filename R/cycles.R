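# Detection of individual theta cycles and anchor-interpolated theta phase.
#
# Candidate extrema of the theta composite must exceed the Hilbert
# amplitude envelope of the low-frequency composite; cycles run trough to
# trough (71-200 ms) around one candidate peak; cycles during slow
# locomotion (speed <= 2 cm/s) are excluded.  All sample indices are
# 1-based; the TSV export is 0-based.

# interior local extrema; plateaus (runs of tied samples, e.g. a trough
# sampled symmetrically) count once, at their midpoint
local_extrema <- function(x) {
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2L) return(list(max = integer(), min = integer()))
  s <- sign(d[nz])
  ch <- which(s[-1L] != s[-length(s)])
  i1 <- nz[ch] + 1L
  i2 <- nz[ch + 1L]
  mid <- (i1 + i2) %/% 2L
  list(max = mid[s[ch] > 0], min = mid[s[ch] < 0])
}

# last upward zero-crossing of x in (i0, i1); NA when absent
ascending_zero_in <- function(x, i0, i1) {
  if (i1 <= i0 + 1L) return(NA_integer_)
  seg <- i0:(i1 - 1L)
  up <- seg[x[seg] < 0 & x[seg + 1L] >= 0]
  if (!length(up)) return(NA_integer_)
  up[length(up)]
}

descending_zero_in <- function(x, i0, i1) {
  if (i1 <= i0 + 1L) return(NA_integer_)
  seg <- i0:(i1 - 1L)
  dn <- seg[x[seg] > 0 & x[seg + 1L] <= 0]
  if (!length(dn)) return(NA_integer_)
  dn[1L]
}

#' Detect individual theta cycles
#'
#' @param decomp a [classify_imfs()] result.
#' @param fs sampling rate, Hz.
#' @param behavior optional behavior trace ([generate_behavior()] format);
#'   when supplied it must cover the LFP time span, cycles get the mean
#'   interpolated speed over their extent, and cycles with speed below
#'   `speed_thresh` are excluded.
#' @param speed_thresh minimum per-cycle speed, cm/s.
#' @param min_period,max_period trough-to-trough duration bounds, s
#'   (defaults 71 and 200 ms).
#' @param t0 time of the first sample, s.
#' @return data frame of class `cycle_table`, one row per cycle, with
#'   1-based sample indices `trough_start`, `asc_zero`, `peak`,
#'   `desc_zero`, `trough_end`, spike-analysis bounds `spike_start`
#'   (ascending zero before the peak) and `spike_end` (ascending zero
#'   after the trough), `speed`, `stage`, `x`, `y` and a `flagged`
#'   indicator for cycles lacking a zero-crossing (anchor fallback).
#' @export
detect_theta_cycles <- function(decomp, fs, behavior = NULL,
                                speed_thresh = 2,
                                min_period = 0.071, max_period = 0.2,
                                t0 = 0) {
  stopifnot(inherits(decomp, "band_decomposition"))
  theta <- decomp$theta
  n <- length(theta)
  if (sd(theta) == 0) stop("theta composite is degenerate")
  env_low <- Mod(analytic_signal(decomp$low))
  ex <- local_extrema(theta)
  cand_peak <- ex$max[theta[ex$max] > env_low[ex$max]]
  cand_trough <- ex$min[-theta[ex$min] > env_low[ex$min]]
  if (length(cand_trough) < 2L)
    return(empty_cycle_table())

  tm <- (seq_len(n) - 1L) / fs + t0
  if (!is.null(behavior)) {
    slack <- 0.1        # one-to-few behavior frames at camera rates
    if (min(behavior$time) > tm[1] + slack ||
        max(behavior$time) < tm[n] - slack)
      stop("behavior trace does not cover the LFP time span")
  }

  rows <- list()
  i <- 1L
  while (i < length(cand_trough)) {
    t1 <- cand_trough[i]; t2 <- cand_trough[i + 1L]
    dur <- (t2 - t1) / fs
    if (dur < min_period || dur > max_period) { i <- i + 1L; next }
    pks <- cand_peak[cand_peak > t1 & cand_peak < t2]
    if (!length(pks)) { i <- i + 1L; next }
    pk <- pks[which.max(theta[pks])]
    az <- ascending_zero_in(theta, t1, pk)
    dz <- descending_zero_in(theta, pk, t2)
    flagged <- is.na(az) || is.na(dz)
    if (is.na(az)) az <- as.integer(round((t1 + pk) / 2))
    if (is.na(dz)) dz <- as.integer(round((pk + t2) / 2))
    # spike bounds: ascending zero before peak -> ascending zero after trough
    nxt <- ascending_zero_in(theta, t2, min(n, t2 + round(max_period * fs)))
    # take the FIRST upward crossing after the trough
    if (!is.na(nxt)) {
      seg <- t2:(min(n, t2 + round(max_period * fs)) - 1L)
      up <- seg[theta[seg] < 0 & theta[seg + 1L] >= 0]
      nxt <- if (length(up)) up[1L] else NA_integer_
    }
    rows[[length(rows) + 1L]] <-
      data.frame(trough_start = t1, asc_zero = az, peak = pk,
                 desc_zero = dz, trough_end = t2,
                 spike_start = az, spike_end = nxt, flagged = flagged)
    i <- i + 1L          # troughs may be shared: [t1, t2) is half-open
  }
  if (!length(rows)) return(empty_cycle_table())
  cyc <- do.call(rbind, rows)

  cyc$speed <- NA_real_
  cyc$stage <- NA_character_
  cyc$x <- NA_real_; cyc$y <- NA_real_
  if (!is.null(behavior)) {
    mid <- tm[round((cyc$trough_start + cyc$trough_end) / 2)]
    for (j in seq_len(nrow(cyc))) {
      sel <- seq(cyc$trough_start[j], cyc$trough_end[j], by = 5L)
      cyc$speed[j] <- mean(approx(behavior$time, behavior$speed,
                                  xout = tm[sel], rule = 2)$y)
    }
    cyc$x <- approx(behavior$time, behavior$x, xout = mid, rule = 2)$y
    cyc$y <- approx(behavior$time, behavior$y, xout = mid, rule = 2)$y
    ib <- findInterval(mid, behavior$time, rightmost.closed = TRUE)
    cyc$stage <- as.character(behavior$stage[pmax(ib, 1L)])
    cyc <- cyc[cyc$speed > speed_thresh, , drop = FALSE]
  }
  rownames(cyc) <- NULL
  cyc$cycle_id <- seq_len(nrow(cyc))
  class(cyc) <- c("cycle_table", "data.frame")
  cyc
}

empty_cycle_table <- function() {
  out <- data.frame(trough_start = integer(), asc_zero = integer(),
                    peak = integer(), desc_zero = integer(),
                    trough_end = integer(), spike_start = integer(),
                    spike_end = integer(), flagged = logical(),
                    speed = numeric(), stage = character(), x = numeric(),
                    y = numeric(), cycle_id = integer())
  class(out) <- c("cycle_table", "data.frame")
  out
}

# per-cycle phase anchors: sample indices and phase values (deg)
cycle_anchor_matrix <- function(cycles) {
  cbind(cycles$trough_start, cycles$asc_zero, cycles$peak,
        cycles$desc_zero, cycles$trough_end)
}

anchor_phases <- c(-180, -90, 0, 90, 180)

#' Anchor-interpolated theta phase
#'
#' Piecewise-linear phase within each cycle with anchors trough_start =
#' -180, ascending zero = -90, peak = 0, descending zero = +90,
#' trough_end = +180 degrees (wrapped to \[-180, 180)); samples outside
#' cycles are masked invalid.
#'
#' @param decomp a [classify_imfs()] result (used for signal length).
#' @param cycles a [detect_theta_cycles()] table.
#' @return object of class `phase_series`: list with `phase` (degrees in
#'   \[-180, 180)), `valid` (logical), `cycle` (cycle id per sample or
#'   NA).
#' @export
theta_phase <- function(decomp, cycles) {
  n <- length(decomp$theta)
  phase <- rep(NA_real_, n)
  cyc_of <- rep(NA_integer_, n)
  A <- cycle_anchor_matrix(cycles)
  for (j in seq_len(nrow(cycles))) {
    idx <- A[j, 1L]:(A[j, 5L] - 1L)            # half-open [trough, trough)
    phase[idx] <- approx(A[j, ], anchor_phases, xout = idx)$y
    cyc_of[idx] <- cycles$cycle_id[j]
  }
  phase <- ifelse(is.na(phase), NA_real_, wrap_deg(phase))
  structure(list(phase = phase, valid = !is.na(phase), cycle = cyc_of),
            class = "phase_series")
}

# invert the anchor interpolation: sample index at which `phase_deg` is
# reached inside cycle row `row` of `cycles` (vectorized over both)
phase_to_sample <- function(cycles, phase_deg, row) {
  A <- cycle_anchor_matrix(cycles)
  seg <- pmin(pmax(floor((phase_deg + 180) / 90) + 1, 1), 4)
  p0 <- anchor_phases[seg]
  a0 <- A[cbind(row, seg)]
  a1 <- A[cbind(row, seg + 1L)]
  a0 + (phase_deg - p0) / 90 * (a1 - a0)
}

#' Export a cycle table as TSV (0-based sample indices)
#' @param cycles cycle table.
#' @param path output path.
#' @param fs sampling rate (adds `_s` time columns).
#' @export
write_cycle_table <- function(cycles, path, fs = NULL) {
  out <- as.data.frame(cycles)
  for (cl in c("trough_start", "asc_zero", "peak", "desc_zero",
               "trough_end", "spike_start", "spike_end"))
    out[[cl]] <- out[[cl]] - 1L
  if (!is.null(fs)) out$trough_start_s <- out$trough_start / fs
  write_tsv(out, path)
}
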