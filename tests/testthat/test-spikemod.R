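# Firing modulation within tSC cycles: triggered rates, SPC, phase
# coupling with shift nulls.  Fixtures use regular synthetic cycles so
# phases are exact.

make_spike_fixture <- function(n_cycles = 200, fs = fs_test) {
  cyc <- make_regular_cycles(n_cycles, fs = fs)
  n <- max(cyc$spike_end) + fs
  list(cycles = cyc, n = n, phase = make_regular_phase(cyc, n), fs = fs)
}

test_that("cycle-triggered rate localizes trough-locked firing", {
  fx <- make_spike_fixture(300)
  sub <- fx$cycles$cycle_id[seq_len(150)]
  # unit firing 3 ms after trough_start, but only in the subset cycles
  times <- (fx$cycles$trough_start[seq_len(150)] - 1) / fx$fs + 0.003
  res <- cycle_triggered_rate(times, fx$cycles, subset = sub, fs = fx$fs)
  # trough_start sits half a period (62.5 ms) before the peak; with
  # periodic cycles the mirrored alignment (+65 ms) also peaks, so
  # assert the trough-lag bin carries (near-)maximal rate and high z
  i_tr <- which.min(abs(res$lag - (-0.0625 + 0.003)))
  expect_gt(res$rate[i_tr], 0.9 * max(res$rate))
  expect_gt(res$z[i_tr], 0.9)

  # homogeneous Poisson unit: subset curve stays near the baseline
  set.seed(1)
  tp <- sort(runif(5000, 0, fx$n / fx$fs))
  rp <- cycle_triggered_rate(tp, fx$cycles, subset = sub, fs = fx$fs)
  expect_lt(max(abs(rp$z)), 0.5)
  # subset = all cycles reproduces the baseline exactly (z = 0)
  rall <- cycle_triggered_rate(tp, fx$cycles, fs = fx$fs)
  expect_true(all(abs(rall$z) < 1e-12))
})

test_that("SPC is exactly zero when the subset is all cycles", {
  fx <- make_spike_fixture(150)
  set.seed(2)
  spk <- data.frame(unit = 1, time = sort(runif(2000, 0, fx$n / fx$fs)))
  res <- spike_probability_change(spk, fx$cycles,
                                  subset = fx$cycles$cycle_id,
                                  phase = fx$phase, fs = fx$fs)
  expect_true(all(abs(res$spc) < 1e-9, na.rm = TRUE))
})

test_that("SPC arithmetic matches planted rate ratios", {
  # rate 1.5x in subset at every phase -> +50%; 0.5x -> -50%
  fx <- make_spike_fixture(400)
  cyc <- fx$cycles
  subset <- cyc$cycle_id[seq_len(200)]
  set.seed(3)
  dur <- fx$n / fx$fs
  # uniform spikes, thinned to 3x rate inside subset cycles
  base <- sort(runif(30000, 0, dur))
  row_of <- thetanest:::assign_spikes_to_cycles(base, cyc, fx$fs)
  in_sub <- !is.na(row_of) & row_of <= 200
  keep <- ifelse(in_sub, TRUE, runif(length(base)) < 1 / 3)
  spk <- data.frame(unit = 1, time = base[keep])
  res <- spike_probability_change(spk, cyc, subset = subset,
                                  phase = fx$phase, fs = fx$fs)
  # subset rate = 3x the 1x non-subset rate; overall = 2x -> SPC = +50%
  expect_lt(abs(mean(res$spc, na.rm = TRUE) - 50), 8)
})

test_that("per-phase ANOVA detects a planted contiguous SPC run", {
  set.seed(4)
  n_units <- 50; n_bins <- 60
  animals <- rep(c("m1", "m2", "m3"), length.out = n_units)
  base <- function() matrix(rnorm(n_units * n_bins, 0, 10), n_units,
                            n_bins)
  spc <- list(base(), base(), base())
  spc[[2]][, 20:29] <- spc[[2]][, 20:29] + 30   # planted +30% over 10 bins
  res <- spc_significance(spc, animals)
  expect_equal(res$alpha, 0.05 / (3 * 60))
  runs2 <- res$significant_runs[[2]]
  expect_gte(sum(runs2[20:29]), 5)
  # null components show no runs
  expect_equal(sum(res$significant_runs[[1]]), 0)
  expect_equal(sum(res$significant_runs[[3]]), 0)
})

test_that("Bonferroni alpha approximates the printed threshold", {
  # 5 tSCs x 60 phases
  spc <- replicate(5, matrix(rnorm(10 * 60), 10, 60), simplify = FALSE)
  res <- spc_significance(spc, rep("m1", 10))
  expect_equal(res$alpha, 0.05 / 300)
  expect_lt(abs(res$alpha - 0.00017), 2e-5)
})

test_that("tsc_signal picks the nearest IMF with low-frequency tie-break", {
  imfset <- structure(list(
    imfs = matrix(rnorm(3 * 100), 3, 100), residual = numeric(100),
    mean_freqs = c(70, 33, 8), fs = 1000), class = "imf_set")
  model <- list(peak_freqs = c(35, 51.5))
  expect_equal(tsc_signal(model, imfset, 1)$imf_index, 2)
  # 51.5 is equidistant from 33 and 70 -> lower frequency wins
  expect_equal(tsc_signal(model, imfset, 2)$imf_index, 2)
})

test_that("pure-tone IMF phase advances at the tone frequency", {
  fs <- 1000
  t <- (seq_len(2 * fs) - 1) / fs
  sig <- cos(2 * pi * 40 * t)
  imfset <- structure(list(imfs = matrix(sig, 1), residual = numeric(length(t)),
                           mean_freqs = 40, fs = fs), class = "imf_set")
  ts <- tsc_signal(list(peak_freqs = 40), imfset, 1)
  dphi <- diff(ts$phase[100:1900])
  dphi <- (dphi + pi) %% (2 * pi) - pi
  expect_equal(mean(dphi) * fs / (2 * pi), 40, tolerance = 0.01)
})

test_that("phase coupling statistics match circular-statistics oracles", {
  fx <- make_spike_fixture(300)
  fs <- fx$fs
  # tSC phase: 80-Hz sawtooth phase signal
  tt <- (seq_len(fx$n) - 1) / fs
  tsc_phase <- ((2 * pi * 80 * tt + pi) %% (2 * pi)) - pi

  # all spikes exactly at tsc-phase pi (signal trough)
  trough_samp <- which(abs(abs(tsc_phase) - pi) < 2 * pi * 80 / fs / 1.9)
  keep <- trough_samp[!is.na(fx$phase$cycle[trough_samp])][1:150]
  times <- (keep - 1) / fs
  res <- phase_coupling(times, tsc_phase, fx$phase, fx$cycles,
                        fs = fs, n_shift = 200, seed = 5)
  expect_gt(res$r, 0.95)
  expect_lt(abs(abs(res$preferred_phase_deg) - 180), 10)
  expect_true(res$significant)

  # von Mises kappa = 1 sample has r ~ I1(1)/I0(1)
  set.seed(6)
  n_sp <- 5000
  vm <- function(n, mu, kappa) {     # rejection sampler adequate here
    out <- numeric(0)
    while (length(out) < n) {
      x <- runif(2 * n, -pi, pi)
      acc <- runif(2 * n) < exp(kappa * (cos(x - mu) - 1))
      out <- c(out, x[acc])
    }
    out[seq_len(n)]
  }
  r_vm <- thetanest:::circ_r(vm(n_sp, 0, 1))
  expect_lt(abs(r_vm - besselI(1, 1) / besselI(1, 0)), 0.03)

  # uniform phases: r near the Rayleigh expectation, not significant
  set.seed(7)
  in_cyc <- which(!is.na(fx$phase$cycle))
  u_times <- (sample(in_cyc, 500) - 1) / fs
  res_u <- phase_coupling(u_times, tsc_phase, fx$phase, fx$cycles,
                          fs = fs, n_shift = 500, seed = 8)
  expect_lt(res_u$r, 0.15)
  expect_false(res_u$significant)
})

test_that("phase-coupling r is rotation-invariant, preferred phase rotates", {
  fx <- make_spike_fixture(100)
  fs <- fx$fs
  tt <- (seq_len(fx$n) - 1) / fs
  base_phase <- ((2 * pi * 60 * tt + pi) %% (2 * pi)) - pi
  set.seed(9)
  in_cyc <- which(!is.na(fx$phase$cycle))
  times <- (sort(sample(in_cyc, 300)) - 1) / fs
  r0 <- phase_coupling(times, base_phase, fx$phase, fx$cycles, fs = fs,
                       n_shift = 10, seed = 10)
  rot <- ((base_phase + pi / 3 + pi) %% (2 * pi)) - pi
  r1 <- phase_coupling(times, rot, fx$phase, fx$cycles, fs = fs,
                       n_shift = 10, seed = 10)
  expect_equal(r1$r, r0$r, tolerance = 1e-12)
  d <- thetanest:::wrap_deg(r1$preferred_phase_deg -
                              r0$preferred_phase_deg - 60)
  expect_lt(abs(d), 1e-6)
})

test_that("units at or below 100 spikes are ineligible", {
  fx <- make_spike_fixture(80)
  tt <- (seq_len(fx$n) - 1) / fx$fs
  tsc_phase <- ((2 * pi * 60 * tt + pi) %% (2 * pi)) - pi
  in_cyc <- which(!is.na(fx$phase$cycle))
  set.seed(11)
  times <- (sample(in_cyc, 90) - 1) / fx$fs
  res <- phase_coupling(times, tsc_phase, fx$phase, fx$cycles,
                        fs = fx$fs, n_shift = 50, seed = 12)
  expect_false(res$eligible)
  expect_false(res$significant)
})

test_that("trough-triggered rate uses the deepest trough once per cycle", {
  fx <- make_spike_fixture(120)
  fs <- fx$fs
  tt <- (seq_len(fx$n) - 1) / fs
  # two troughs per cycle: deeper one at the cycle's 3/4 point
  sig <- sin(2 * pi * 16 * tt)
  res <- trough_triggered_rate(data.frame(unit = integer(0),
                                          time = numeric(0)),
                               sig, fx$cycles, fs = fs)
  expect_equal(length(res$triggers), nrow(fx$cycles))
  expect_true(all(sig[res$triggers] <= -0.99))
  # spikes locked at triggers produce a central peak
  spk <- data.frame(unit = 1, time = (res$triggers - 1) / fs)
  res2 <- trough_triggered_rate(spk, sig, fx$cycles, fs = fs)
  expect_equal(res2$lag[which.max(res2$rate)], 0)
})

test_that("coupling null calibration: uncoupled units rarely flagged", {
  # reduced-scale version of the 99.9th-percentile false-positive check
  fx <- make_spike_fixture(150)
  fs <- fx$fs
  tt <- (seq_len(fx$n) - 1) / fs
  tsc_phase <- ((2 * pi * 70 * tt + pi) %% (2 * pi)) - pi
  in_cyc <- which(!is.na(fx$phase$cycle))
  set.seed(13)
  flags <- vapply(1:60, function(i) {
    times <- (sample(in_cyc, 150) - 1) / fs
    phase_coupling(times, tsc_phase, fx$phase, fx$cycles, fs = fs,
                   n_shift = 300, seed = 100 + i)$significant
  }, logical(1))
  expect_lte(mean(flags), 0.05)
})
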