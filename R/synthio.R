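# Synthetic LFP / spike / behavior / rest generators with known ground
# truth.  The generative model mirrors what the analysis pipeline assumes:
# an asymmetric theta carrier, Gaussian-windowed burst families at fixed
# supra-theta frequencies locked to fixed theta phases and present in a
# random subset of cycles, 1/f background noise, phase- and rate-modulated
# Poisson spike trains, and ripple-bearing rest epochs with latent-factor
# co-activation.

#' Ground-truth configuration for the synthetic generators
#'
#' @param burst_families data frame with columns `freq` (Hz, in (0, 200]),
#'   `phase_deg` (preferred theta phase, peak = 0, trough = +/-180),
#'   `prob` (per-cycle occurrence probability in \[0,1\]) and `amp`
#'   (amplitude relative to the unit theta carrier).
#' @param theta_freq theta carrier frequency, Hz.
#' @param theta_asymmetry ratio of ascending to descending limb duration
#'   (< 1 means a shorter ascending limb, as in CA1 theta).
#' @param snr_supra target ratio of burst variance to supra-theta (> 12 Hz)
#'   noise variance; `Inf` disables noise.
#' @param unit_specs data frame with columns `rate` (mean rate, Hz >= 0),
#'   `kappa_theta`, `theta_mu_deg` (von Mises theta-phase tuning),
#'   `family` (index of the coupled burst family or `NA`), `kappa_fast`,
#'   `fast_mu_deg` (tuning to the coupled family's fast phase) and
#'   `speed_slope` (fractional rate gain per cm/s).
#' @param swr_times optional fixed ripple-center times (s) for
#'   [generate_rest()].
#' @param ensemble_loadings per-unit latent-factor loadings in \[0,1\]
#'   controlling SWR co-activation (see [generate_rest()]).
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(burst_families = NULL,
                         theta_freq = 8,
                         theta_asymmetry = 0.8,
                         snr_supra = 2,
                         unit_specs = NULL,
                         swr_times = NULL,
                         ensemble_loadings = NULL) {
  if (is.null(burst_families))
    burst_families <- data.frame(freq = numeric(), phase_deg = numeric(),
                                 prob = numeric(), amp = numeric())
  stopifnot(all(c("freq", "phase_deg", "prob", "amp") %in%
                  names(burst_families)),
            theta_freq > 0, theta_asymmetry > 0)
  if (nrow(burst_families)) {
    stopifnot(all(burst_families$prob >= 0 & burst_families$prob <= 1),
              all(burst_families$freq > 0 & burst_families$freq <= 200),
              all(burst_families$amp >= 0))
  }
  if (!is.null(unit_specs)) {
    stopifnot(all(c("rate", "kappa_theta", "theta_mu_deg", "family",
                    "kappa_fast", "fast_mu_deg", "speed_slope") %in%
                    names(unit_specs)))
    if (any(unit_specs$rate < 0)) stop("negative base rates are not allowed")
    stopifnot(all(unit_specs$kappa_theta >= 0),
              all(unit_specs$kappa_fast >= 0))
  }
  structure(list(burst_families = burst_families, theta_freq = theta_freq,
                 theta_asymmetry = theta_asymmetry, snr_supra = snr_supra,
                 unit_specs = unit_specs, swr_times = swr_times,
                 ensemble_loadings = ensemble_loadings, realized = NULL),
            class = "ground_truth")
}

#' Default ground truth: five burst families at the canonical tSC
#' frequencies
#'
#' Families at 22, 35, 54, 80 and 169 Hz, each present in a random 20% of
#' theta cycles and locked to a distinct theta phase, on an 8-Hz
#' asymmetric theta carrier with supra-theta SNR 2.
#'
#' @param n_units number of spiking units to specify (0 for none).
#' @param seed seed used only to draw unit tuning parameters.
#' @return a [ground_truth()] object.
#' @export
default_ground_truth <- function(n_units = 0L, seed = 1L) {
  fam <- data.frame(
    freq = c(22, 35, 54, 80, 169),
    phase_deg = c(-144, -72, 0, 72, 144),
    prob = rep(0.2, 5),
    amp = rep(0.25, 5))
  units <- NULL
  if (n_units > 0L) {
    set.seed(seed)
    units <- data.frame(
      rate = runif(n_units, 1, 5),
      kappa_theta = runif(n_units, 0.3, 1),
      theta_mu_deg = runif(n_units, -180, 180),
      family = sample(c(NA, 1:5), n_units, replace = TRUE),
      kappa_fast = runif(n_units, 0.5, 1.5),
      fast_mu_deg = 180,
      speed_slope = runif(n_units, 0, 0.05))
  }
  ground_truth(burst_families = fam, unit_specs = units)
}

# unwrapped theta phase anchors (degrees) for an asymmetric carrier:
# troughs at k*T, peaks at k*T + a*T with a = asym/(1+asym)
theta_phase_anchors <- function(theta_freq, theta_asymmetry, duration) {
  T <- 1 / theta_freq
  a <- theta_asymmetry / (1 + theta_asymmetry)
  k <- 0:ceiling(duration / T)
  t_anchor <- as.vector(rbind(k * T, k * T + a * T))
  p_anchor <- as.vector(rbind(k * 360 - 180, k * 360))
  list(time = t_anchor, phase = p_anchor, period = T, asc_frac = a)
}

# unwrapped phase (degrees) at arbitrary times
theta_phase_at <- function(anchors, t) {
  approx(anchors$time, anchors$phase, xout = t, rule = 2)$y
}

# time at which unwrapped phase (degrees) is reached
theta_time_at_phase <- function(anchors, phase_unwrapped) {
  approx(anchors$phase, anchors$time, xout = phase_unwrapped, rule = 2)$y
}

# 1/f-power noise with unit variance, deterministic under the current RNG
pink_noise <- function(n, fs) {
  W <- fft(rnorm(n))
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                 # two-sided frequency magnitude
  g <- ifelse(f > 0, 1 / sqrt(pmax(f, fs / n)), 0)
  x <- Re(fft(W * g, inverse = TRUE) / n)
  x / sd(x)
}

# variance of x restricted to frequencies above f_hi (FFT mask)
variance_above <- function(x, fs, f_hi) {
  n <- length(x)
  X <- fft(x - mean(x))
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  sum(Mod(X[f > f_hi])^2) / n^2
}

#' Generate a synthetic single-channel LFP with known ground truth
#'
#' The trace is the sum of an asymmetric theta carrier (unit amplitude),
#' Gaussian-windowed burst trains for each configured family (envelope
#' SD = 1.5 cycles of the family frequency, centered where the theta
#' phase equals the family's preferred phase, present in an independent
#' Bernoulli subset of cycles), and 1/f background noise scaled to the
#' configured supra-theta SNR.
#'
#' @param truth a [ground_truth()].
#' @param duration seconds (>= 10).
#' @param fs sampling rate, Hz; must exceed 4x the fastest burst family.
#' @param seed RNG seed.
#' @return list with elements `lfp` (an [lfp_record()]) and `truth` (the
#'   input updated with realized cycle labels, burst times and theta
#'   anchors in `$realized`).
#' @export
generate_lfp <- function(truth, duration, fs = 1250, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (duration < 10) stop("duration must be at least 10 s")
  fam <- truth$burst_families
  if (nrow(fam) && fs < 4 * max(fam$freq))
    stop("fs must be at least 4x the maximum burst frequency")
  if (nrow(fam) && any(fam$freq >= fs / 2))
    stop("burst frequency at or above Nyquist")
  set.seed(seed)

  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  anchors <- theta_phase_anchors(truth$theta_freq, truth$theta_asymmetry,
                                 duration)
  phase <- theta_phase_at(anchors, t)
  theta <- cos(deg2rad(phase))

  n_cyc <- floor(duration / anchors$period)   # complete cycles
  labels <- matrix(FALSE, n_cyc, nrow(fam))
  bursts <- numeric(n)
  burst_times <- data.frame(family = integer(), cycle = integer(),
                            time = numeric())
  if (nrow(fam)) {
    for (f in seq_len(nrow(fam))) {
      occ <- runif(n_cyc) < fam$prob[f]
      labels[, f] <- occ
      sigma <- 1.5 / fam$freq[f]
      for (k in which(occ)) {
        tc <- theta_time_at_phase(anchors, (k - 1) * 360 + fam$phase_deg[f])
        i0 <- max(1L, floor((tc - 4 * sigma) * fs) + 1L)
        i1 <- min(n, ceiling((tc + 4 * sigma) * fs) + 1L)
        if (i1 <= i0) next
        tt <- t[i0:i1] - tc
        bursts[i0:i1] <- bursts[i0:i1] +
          fam$amp[f] * exp(-tt^2 / (2 * sigma^2)) *
          cos(2 * pi * fam$freq[f] * tt)
        burst_times <- rbind(burst_times,
                             data.frame(family = f, cycle = k, time = tc))
      }
    }
  }

  noise <- numeric(n)
  vb <- var(bursts)
  if (is.finite(truth$snr_supra) && vb > 0) {
    nz <- pink_noise(n, fs)
    v_supra <- variance_above(nz, fs, 12)
    noise <- nz * sqrt(vb / (truth$snr_supra * v_supra))
  }

  truth$realized <- list(
    anchors = anchors, n_cycles = n_cyc, cycle_labels = labels,
    burst_times = burst_times, fs = fs, duration = duration,
    var_theta = var(theta), var_bursts = vb, var_noise = var(noise))
  list(lfp = lfp_record(theta + bursts + noise, fs = fs),
       truth = truth)
}

# wrapped fast phase (radians) of each sample w.r.t. its cycle's burst of
# family f; NA where the family does not occur
family_fast_phase <- function(truth, t, f) {
  rl <- truth$realized
  bt <- rl$burst_times[rl$burst_times$family == f, ]
  cyc <- findInterval(t, rl$anchors$time[seq(1, length(rl$anchors$time),
                                             by = 2)])
  out <- rep(NA_real_, length(t))
  idx <- match(cyc, bt$cycle)
  has <- !is.na(idx)
  fr <- truth$burst_families$freq[f]
  out[has] <- (2 * pi * fr * (t[has] - bt$time[idx[has]]) + pi) %% (2 * pi) - pi
  out
}

#' Generate inhomogeneous-Poisson spike trains from ground truth
#'
#' Per-sample rate = base rate x von Mises theta-phase gain x von Mises
#' fast-phase gain (phase of the unit's coupled burst family, applied
#' only in cycles where that family occurs) x linear speed gain
#' `(1 + slope * speed)`.  The theta-phase gain is normalized by
#' `besselI(kappa, 0)` so it preserves the mean rate; the fast-phase
#' gain is not, so a coupled unit fires `besselI(kappa_fast, 0)`-fold
#' more in cycles where its family occurs — the count-level ensemble
#' signature the GLM analyses decode.
#'
#' @param truth a [ground_truth()] that has been realized by
#'   [generate_lfp()] and carries `unit_specs`.
#' @param lfp the matching [lfp_record()].
#' @param behavior optional behavior trace from [generate_behavior()];
#'   speed defaults to a constant 10 cm/s when absent.
#' @param seed RNG seed.
#' @return data frame (class `spike_table`) with columns `unit`, `time`.
#' @export
generate_spikes <- function(truth, lfp, behavior = NULL, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), !is.null(truth$realized))
  us <- truth$unit_specs
  if (is.null(us) || nrow(us) == 0L) stop("truth carries no unit specs")
  set.seed(seed)
  fs <- lfp$fs
  n <- ncol(lfp$samples)
  t <- (seq_len(n) - 1L) / fs
  phase <- deg2rad(theta_phase_at(truth$realized$anchors, t))
  speed <- if (is.null(behavior)) rep(10, n) else
    approx(behavior$time, behavior$speed, xout = t, rule = 2)$y

  fast_cache <- list()
  res <- vector("list", nrow(us))
  for (u in seq_len(nrow(us))) {
    gain <- rep(us$rate[u], n)
    if (us$kappa_theta[u] > 0)
      gain <- gain * exp(us$kappa_theta[u] *
                           cos(phase - deg2rad(us$theta_mu_deg[u]))) /
        besselI(us$kappa_theta[u], 0)
    if (!is.na(us$family[u]) && us$kappa_fast[u] > 0) {
      f <- us$family[u]
      key <- as.character(f)
      if (is.null(fast_cache[[key]]))
        fast_cache[[key]] <- family_fast_phase(truth, t, f)
      fp <- fast_cache[[key]]
      # deliberately NOT normalized by I0(kappa): a coupled unit then
      # fires I0(kappa)-fold more in cycles where its family occurs, so
      # ensembles carry a count-level signature of tSC strength
      g <- rep(1, n)
      has <- !is.na(fp)
      g[has] <- exp(us$kappa_fast[u] *
                      cos(fp[has] - deg2rad(us$fast_mu_deg[u])))
      gain <- gain * g
    }
    if (us$speed_slope[u] != 0)
      gain <- gain * pmax(1 + us$speed_slope[u] * speed, 0)
    fire <- runif(n) < gain / fs
    res[[u]] <- data.frame(unit = u, time = t[fire])
  }
  out <- do.call(rbind, res)
  class(out) <- c("spike_table", "data.frame")
  out
}

#' Generate a synthetic behavior trace
#'
#' @param duration seconds.
#' @param fs_beh behavior sampling rate, Hz (camera-like, default 40).
#' @param arena arena width and height, cm.
#' @param mode `"walk"` (smooth random walk with speed autocorrelation),
#'   `"constant"` (straight-line motion at `speed_value`) or
#'   `"stationary"`.
#' @param speed_value speed for `mode = "constant"`, cm/s.
#' @param tau velocity autocorrelation time constant, s.
#' @param sigma_v velocity diffusion, cm/s per sqrt(s).
#' @param stage stage label applied to all samples.
#' @param seed RNG seed.
#' @return data frame (class `behavior_trace`) with columns `time`, `x`,
#'   `y`, `speed`, `stage`.
#' @export
generate_behavior <- function(duration, fs_beh = 40, arena = c(100, 100),
                              mode = c("walk", "constant", "stationary"),
                              speed_value = 10, tau = 1, sigma_v = 8,
                              stage = "exploration", seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  n <- round(duration * fs_beh)
  dt <- 1 / fs_beh
  tm <- (seq_len(n) - 1L) * dt
  if (mode == "stationary") {
    x <- rep(arena[1] / 2, n); y <- rep(arena[2] / 2, n)
  } else if (mode == "constant") {
    x <- (arena[1] / 10 + speed_value * tm) %% arena[1]
    y <- rep(arena[2] / 2, n)
  } else {
    vx <- numeric(n); vy <- numeric(n); x <- numeric(n); y <- numeric(n)
    x[1] <- arena[1] / 2; y[1] <- arena[2] / 2
    for (i in 2:n) {
      vx[i] <- vx[i - 1] - vx[i - 1] / tau * dt + sigma_v * sqrt(dt) * rnorm(1)
      vy[i] <- vy[i - 1] - vy[i - 1] / tau * dt + sigma_v * sqrt(dt) * rnorm(1)
      x[i] <- x[i - 1] + vx[i] * dt
      y[i] <- y[i - 1] + vy[i] * dt
      if (x[i] < 0 || x[i] > arena[1]) { vx[i] <- -vx[i]; x[i] <- x[i - 1] }
      if (y[i] < 0 || y[i] > arena[2]) { vy[i] <- -vy[i]; y[i] <- y[i - 1] }
    }
  }
  sp <- c(0, sqrt(diff(x)^2 + diff(y)^2) / dt)
  if (mode == "constant") sp <- rep(speed_value, n)
  if (mode == "stationary") sp <- rep(0, n)
  out <- data.frame(time = tm, x = x, y = y, speed = sp,
                    stage = stage, stringsAsFactors = FALSE)
  class(out) <- c("behavior_trace", "data.frame")
  out
}

#' Expected pairwise SWR co-firing correlation of the rest generator
#'
#' Under the latent-factor model of [generate_rest()] (per-event shared
#' Poisson count thinned independently into units), the count correlation
#' of units i and j inside ripple windows is
#' `c * w_i * w_j / sqrt((a_i + c * w_i) * (a_j + c * w_j))`.
#'
#' @param a_i,a_j private mean counts per window.
#' @param c_shared shared latent mean count per window.
#' @param w_i,w_j loadings in \[0,1\].
#' @return expected Pearson correlation.
#' @export
rest_pair_correlation <- function(a_i, a_j, c_shared, w_i, w_j) {
  c_shared * w_i * w_j /
    sqrt((a_i + c_shared * w_i) * (a_j + c_shared * w_j))
}

#' Generate a rest epoch with ripples and co-firing structure
#'
#' The LFP is 1/f noise plus Gaussian-windowed ripple bursts
#' (`ripple_freq` Hz, envelope SD `ripple_sd` s) at the configured times.
#' Spikes are homogeneous Poisson outside ripples; inside each 100-ms
#' ripple window, unit counts follow a latent-factor co-activation model:
#' a shared Poisson count (mean `c_shared`) is thinned into each unit by
#' its `ensemble_loadings` entry, on top of private Poisson counts, so
#' the pairwise correlation structure is the outer product of loadings
#' (see [rest_pair_correlation()]).
#'
#' @param truth a [ground_truth()] with `unit_specs` (and optionally
#'   `swr_times`, `ensemble_loadings`).
#' @param duration seconds.
#' @param fs sampling rate, Hz.
#' @param ripple_freq ripple carrier frequency, Hz.
#' @param ripple_amp ripple amplitude relative to the unit-SD noise.
#' @param ripple_sd ripple Gaussian envelope SD, s.
#' @param ripple_rate mean ripple rate (events/s) when `swr_times` absent.
#' @param c_shared shared latent mean count per ripple window.
#' @param rest_rate_factor multiplier on unit base rates outside ripples.
#' @param seed RNG seed.
#' @return list with `lfp`, `spikes`, `swr_windows` (data frame `start`,
#'   `end`, `center` in s) and `speed` (all-zero vector at `fs`).
#' @export
generate_rest <- function(truth, duration, fs = 1250, ripple_freq = 150,
                          ripple_amp = 1, ripple_sd = 0.015,
                          ripple_rate = 0.15, c_shared = 2,
                          rest_rate_factor = 0.3, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  us <- truth$unit_specs
  if (is.null(us)) stop("truth carries no unit specs")
  set.seed(seed)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  x <- pink_noise(n, fs)
  centers <- truth$swr_times
  if (is.null(centers)) {
    n_ev <- rbinom(1L, size = round(duration), prob = min(ripple_rate, 1))
    centers <- sort(runif(n_ev, 0.2, duration - 0.2))
    centers <- centers[c(TRUE, diff(centers) > 0.5)]
  }
  for (tc in centers) {
    i0 <- max(1L, floor((tc - 4 * ripple_sd) * fs) + 1L)
    i1 <- min(n, ceiling((tc + 4 * ripple_sd) * fs) + 1L)
    tt <- t[i0:i1] - tc
    x[i0:i1] <- x[i0:i1] + ripple_amp * exp(-tt^2 / (2 * ripple_sd^2)) *
      cos(2 * pi * ripple_freq * tt)
  }
  w <- truth$ensemble_loadings
  if (is.null(w)) w <- rep(0.5, nrow(us))
  stopifnot(length(w) == nrow(us), all(w >= 0 & w <= 1))
  spk <- list()
  base <- us$rate * rest_rate_factor
  for (u in seq_len(nrow(us))) {
    n_out <- rbinom(1L, n, base[u] / fs)
    spk[[u]] <- data.frame(unit = rep(u, n_out),
                           time = sort(runif(n_out, 0, duration)))
  }
  win <- data.frame(start = centers - 0.05, end = centers + 0.05,
                    center = centers)
  for (e in seq_len(nrow(win))) {
    shared <- stats::rpois(1L, c_shared)
    for (u in seq_len(nrow(us))) {
      k <- rbinom(1L, shared, w[u]) + stats::rpois(1L, base[u] * 0.1)
      if (k > 0)
        spk[[u]] <- rbind(spk[[u]],
                          data.frame(unit = u,
                                     time = runif(k, win$start[e], win$end[e])))
    }
  }
  spikes <- do.call(rbind, lapply(spk, function(d) d[order(d$time), ]))
  class(spikes) <- c("spike_table", "data.frame")
  list(lfp = lfp_record(x, fs = fs), spikes = spikes, swr_windows = win,
       speed = numeric(n))
}
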