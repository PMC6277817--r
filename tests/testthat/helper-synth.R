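# Shared fixture builders.  Everything is generated in code at test time;
# sizes are kept small so the default run stays fast.

fs_test <- 1250

# band decomposition built directly from known tones (bypasses EEMD) so
# cycle/phase tests are exact
make_tone_decomp <- function(duration = 10, f_theta = 8, fs = fs_test,
                             supra = NULL, low = NULL) {
  t <- (seq_len(round(duration * fs)) - 1L) / fs
  theta <- cos(2 * pi * f_theta * t)
  n <- length(t)
  structure(list(low = if (is.null(low)) numeric(n) else low,
                 theta = theta,
                 supra = if (is.null(supra)) numeric(n) else supra,
                 bands = c("theta"),
                 imfset = NULL),
            class = "band_decomposition")
}

# regular synthetic cycle table: n_cycles cycles of period `period_s`
# with exact quarter-phase anchors; speeds default 10 cm/s
make_regular_cycles <- function(n_cycles = 100, period_s = 0.125,
                                fs = fs_test, speed = 10) {
  p <- round(period_s * fs)
  q <- round(p / 4)
  ts <- (seq_len(n_cycles) - 1L) * p + 1L
  out <- data.frame(trough_start = ts, asc_zero = ts + q,
                    peak = ts + 2L * q, desc_zero = ts + 3L * q,
                    trough_end = ts + p,
                    spike_start = ts + q, spike_end = ts + p + q,
                    flagged = FALSE, speed = speed, stage = "exploration",
                    x = 50, y = 50, cycle_id = seq_len(n_cycles))
  class(out) <- c("cycle_table", "data.frame")
  out
}

# phase series matching make_regular_cycles on a signal of n samples
make_regular_phase <- function(cycles, n) {
  dec <- list(theta = numeric(n))
  theta_phase(dec, cycles)
}

# signature matrix from non-negative mixtures of Gaussian spectral
# templates (identifiable ICA construction)
make_template_signatures <- function(n_cycles = 400, centers = c(35, 80),
                                     width = 6, noise_sd = 0.02,
                                     prob = 0.3, amp = 1, seed = 1) {
  set.seed(seed)
  freqs <- 10:200
  tmpl <- vapply(centers, function(fc) exp(-((freqs - fc)^2) /
                                             (2 * width^2)),
                 numeric(length(freqs)))
  S <- matrix(stats::rbinom(n_cycles * length(centers), 1, prob) *
                stats::runif(n_cycles * length(centers), 0.5, 1.5) * amp,
              n_cycles, length(centers))
  X <- S %*% t(tmpl) + matrix(abs(rnorm(n_cycles * length(freqs),
                                        sd = noise_sd)),
                              n_cycles, length(freqs))
  structure(X, freqs = as.numeric(freqs), cycle_id = seq_len(n_cycles),
            class = c("signature_matrix", "matrix"),
            sources = S, templates = t(tmpl))
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# small cached end-to-end pipeline run shared by several test files
pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    truth <- default_ground_truth(n_units = 12, seed = 7)
    truth$unit_specs$rate <- runif(12, 3, 6)
    truth$unit_specs$kappa_fast <- 2   # strong count-level coupling
    sim <- generate_lfp(truth, 60, fs_test, seed = 7)
    dec <- eemd(sim$lfp$samples[1, ], fs_test, ensemble_size = 10,
                seed = 8)
    bd <- classify_imfs(dec)
    cyc <- detect_theta_cycles(bd, fs_test)
    sig <- spectral_signatures(bd$supra, cyc, fs_test)
    mod <- extract_tscs(sig, seed = 9)
    st <- tsc_strength(mod, sig)
    spikes <- generate_spikes(sim$truth, sim$lfp, seed = 10)
    cache <<- list(truth = sim$truth, lfp = sim$lfp, imfset = dec,
                   decomp = bd, cycles = cyc, sigs = sig, model = mod,
                   strength = st, spikes = spikes)
    cache
  }
})
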