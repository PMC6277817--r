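# SWR detection and offline reactivation of tSC-specific theta co-firing
# patterns, with matched-cycle controls.

#' Detect sharp-wave/ripple events
#'
#' Band-passes each channel (135-250 Hz Butterworth, zero-phase),
#' computes RMS power in a sliding window, sums across channels,
#' z-scores per epoch, and takes local power peaks above `threshold_sd`
#' occurring while speed is below `speed_thresh`.  Event windows are
#' 100 ms centered on the power peak.  A designated ripple-free
#' reference channel is subtracted from all others when provided.
#'
#' @param lfp an [lfp_record()] of a rest epoch.
#' @param speed optional per-sample speed, cm/s (default all zero).
#' @param band ripple band, Hz.
#' @param threshold_sd detection threshold in SDs above the mean power.
#' @param rms_window RMS window, s (default 8 ms, about one ripple
#'   cycle).
#' @param speed_thresh maximum speed, cm/s.
#' @param ref_channel index of a ripple-free reference channel to
#'   subtract, or NULL.
#' @param min_separation minimum peak separation, s.
#' @return data frame of class `swr_event_table`: `peak_time` (s),
#'   `start`, `end` (100-ms window bounds, s), `peak_z`.
#' @export
detect_swr <- function(lfp, speed = NULL, band = c(135, 250),
                       threshold_sd = 7, rms_window = 0.008,
                       speed_thresh = 2, ref_channel = NULL,
                       min_separation = 0.05) {
  stopifnot(inherits(lfp, "lfp_record"))
  fs <- lfp$fs
  X <- lfp$samples
  if (!is.null(ref_channel)) {
    ref <- X[ref_channel, ]
    X <- X[-ref_channel, , drop = FALSE]
    X <- sweep(X, 2L, ref)
  }
  n <- ncol(X)
  if (is.null(speed)) speed <- numeric(n)
  stopifnot(length(speed) == n)
  bf <- butter_design(2, band, fs, "pass")
  w <- max(3L, round(rms_window * fs))
  kern <- rep(1 / w, w)
  power <- numeric(n)
  for (ch in seq_len(nrow(X))) {
    y <- filtfilt_iir(bf$b, bf$a, X[ch, ])
    ms <- as.numeric(stats::filter(y^2, kern, sides = 2))
    ms[is.na(ms)] <- 0
    power <- power + sqrt(pmax(ms, 0))
  }
  z <- (power - mean(power)) / sd(power)
  ex <- local_extrema(z)
  pk <- ex$max[z[ex$max] >= threshold_sd & speed[ex$max] < speed_thresh]
  if (length(pk) > 1L) {          # enforce minimum separation, keep larger
    keep <- logical(length(pk))
    ord <- order(z[pk], decreasing = TRUE)
    taken <- numeric(0)
    for (i in ord) {
      if (!length(taken) || all(abs(pk[i] - taken) > min_separation * fs)) {
        keep[i] <- TRUE; taken <- c(taken, pk[i])
      }
    }
    pk <- sort(pk[keep])
  }
  out <- data.frame(peak_time = (pk - 1L) / fs + lfp$t0,
                    peak_z = z[pk])
  out$start <- out$peak_time - 0.05
  out$end <- out$peak_time + 0.05
  class(out) <- c("swr_event_table", "data.frame")
  out
}

#' Spike counts in arbitrary time windows
#' @param spikes spike table.
#' @param start,end window bounds, s (half-open).
#' @param units unit ids (default all present, sorted).
#' @return matrix windows x units.
#' @export
window_spike_counts <- function(spikes, start, end, units = NULL) {
  if (is.null(units)) units <- sort(unique(spikes$unit))
  M <- matrix(0L, length(start), length(units),
              dimnames = list(NULL, units))
  for (j in seq_along(units)) {
    tt <- spikes$time[spikes$unit == units[j]]
    for (i in seq_along(start))
      M[i, j] <- sum(tt >= start[i] & tt < end[i])
  }
  M
}

#' Pairwise co-firing correlations
#'
#' Pearson correlation of each unit pair's spike counts across analysis
#' windows (theta cycles of one tSC, or SWR windows).  Pairs where
#' either unit has zero count variance, or fewer than `min_spikes`
#' total spikes, are masked `NA`.
#'
#' @param counts windows x units count matrix.
#' @param min_spikes minimum total spikes per unit in the window set.
#' @return data frame with `i`, `j` (unit column indices, i < j), `r`.
#' @export
cofiring <- function(counts, min_spikes = 5L) {
  u <- ncol(counts)
  v <- apply(counts, 2L, var)
  tot <- colSums(counts)
  pairs <- which(upper.tri(matrix(0, u, u)), arr.ind = TRUE)
  r <- rep(NA_real_, nrow(pairs))
  C <- suppressWarnings(cor(counts))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    if (v[i] > 0 && v[j] > 0 && tot[i] >= min_spikes && tot[j] >= min_spikes)
      r[p] <- C[i, j]
  }
  data.frame(i = pairs[, 1L], j = pairs[, 2L], r = r)
}

#' SWR reactivation strength of one tSC's co-firing pattern
#'
#' Least-squares fit of `post-SWR co-firing ~ theta co-firing + pre-SWR
#' co-firing` across cell pairs; the pre term controls for correlation
#' structure already present before exploration.
#'
#' @param theta_cof per-pair theta co-firing for one tSC.
#' @param pre,post per-pair SWR co-firing before / after exploration.
#' @return list with `beta` (theta coefficient), `se`, `p`, `ci`
#'   (95%), `fit`, `collinear` flag.
#' @export
reactivation_strength <- function(theta_cof, pre, post) {
  ok <- is.finite(theta_cof) & is.finite(pre) & is.finite(post)
  df <- data.frame(post = post[ok], theta = theta_cof[ok], pre = pre[ok])
  collinear <- abs(suppressWarnings(cor(df$theta, df$pre))) > 1 - 1e-10
  if (collinear) warning("theta and pre co-firing are collinear")
  fit <- lm(post ~ theta + pre, data = df)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)["theta", ]
  list(beta = sm["theta", 1L], se = sm["theta", 2L], p = sm["theta", 4L],
       ci = unname(ci), fit = fit, collinear = collinear)
}

#' Joint regression of the SWR co-firing change on all tSC patterns
#'
#' `delta = post - pre ~ theta co-firing of every tSC` simultaneously;
#' each coefficient isolates that tSC's contribution.
#'
#' @param theta_cof_matrix pairs x tSC matrix of theta co-firing.
#' @param pre,post per-pair SWR co-firing.
#' @return list with `beta` (per tSC), `se`, `p`, `fit`, `collinear`.
#' @export
delta_swr_regression <- function(theta_cof_matrix, pre, post) {
  delta <- post - pre
  ok <- is.finite(delta) & apply(is.finite(theta_cof_matrix), 1L, all)
  X <- theta_cof_matrix[ok, , drop = FALSE]
  qx <- qr(cbind(1, X))
  collinear <- qx$rank < ncol(X) + 1L
  if (collinear) warning("collinear tSC co-firing columns")
  df <- data.frame(delta = delta[ok], X)
  fit <- lm(delta ~ ., data = df)
  sm <- summary(fit)$coefficients
  idx <- rownames(sm) != "(Intercept)"
  list(beta = sm[idx, 1L], se = sm[idx, 2L], p = sm[idx, 4L], fit = fit,
       collinear = collinear)
}

#' Speed- and location-matched control cycle subsets
#'
#' Each control replaces every target cycle with a random pool cycle
#' whose speed differs by at most `speed_tol` and whose position is
#' within `dist_tol`; when no such cycle exists, the speed-matched
#' cycle at the smallest distance is used (or, failing that, the
#' closest-speed cycle).  Also supports plain random subsets of equal
#' size (`match = "random"`).
#'
#' @param cycles cycle table with `speed`, `x`, `y`.
#' @param target cycle ids to be matched.
#' @param pool cycle ids to draw controls from.
#' @param n_controls number of control subsets.
#' @param speed_tol cm/s.
#' @param dist_tol cm.
#' @param match `"matched"` or `"random"`.
#' @param seed RNG seed.
#' @return integer matrix n_controls x length(target) of cycle ids.
#' @export
matched_cycle_control <- function(cycles, target, pool, n_controls = 1000L,
                                  speed_tol = 0.5, dist_tol = 5,
                                  match = c("matched", "random"),
                                  seed = 1L) {
  match <- match.arg(match)
  set.seed(seed)
  ti <- base::match(target, cycles$cycle_id)
  pi_ <- base::match(pool, cycles$cycle_id)
  stopifnot(!anyNA(ti), !anyNA(pi_))
  nt <- length(ti)
  out <- matrix(NA_integer_, n_controls, nt)
  if (match == "random") {
    for (b in seq_len(n_controls))
      out[b, ] <- pool[sample.int(length(pool), nt,
                                  replace = length(pool) < nt)]
    return(out)
  }
  cand <- vector("list", nt)
  for (q in seq_len(nt)) {
    dspeed <- abs(cycles$speed[pi_] - cycles$speed[ti[q]])
    dist <- sqrt((cycles$x[pi_] - cycles$x[ti[q]])^2 +
                   (cycles$y[pi_] - cycles$y[ti[q]])^2)
    ok <- which(dspeed <= speed_tol & dist <= dist_tol)
    if (!length(ok)) {
      sp_ok <- which(dspeed <= speed_tol)
      ok <- if (length(sp_ok)) sp_ok[which.min(dist[sp_ok])]
      else which.min(dspeed)
    }
    cand[[q]] <- pool[ok]
  }
  for (b in seq_len(n_controls))
    out[b, ] <- vapply(cand, function(cc)
      cc[sample.int(length(cc), 1L)], numeric(1))
  out
}
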