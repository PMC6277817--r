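# Spectral signatures, ICA extraction, strengths, thresholds, profiles.

test_that("signatures of a constant tone peak at the tone frequency", {
  fs <- fs_test
  cyc <- make_regular_cycles(40)
  n <- max(cyc$spike_end) + fs
  t <- (seq_len(n) - 1) / fs
  supra <- cos(2 * pi * 60 * t)
  sig <- spectral_signatures(supra, cyc, fs)
  pk <- attr(sig, "freqs")[apply(sig, 1L, which.max)]
  expect_true(all(abs(pk - 60) <= 1))
  # zero supra -> all-zero signatures
  sig0 <- spectral_signatures(numeric(n), cyc, fs)
  expect_true(all(sig0 == 0))
})

test_that("a burst confined to one cycle dominates that row only", {
  fs <- fs_test
  cyc <- make_regular_cycles(40)
  n <- max(cyc$spike_end) + fs
  t <- (seq_len(n) - 1) / fs
  k <- 17
  tc <- (cyc$peak[k] - 1) / fs
  supra <- exp(-(t - tc)^2 / (2 * 0.02^2)) * cos(2 * pi * 35 * (t - tc))
  sig <- spectral_signatures(supra, cyc, fs)
  f35 <- which(attr(sig, "freqs") == 35)
  expect_lte(abs(attr(sig, "freqs")[which.max(sig[k, ])] - 35), 1)
  expect_lt(median(sig[-k, f35]), 0.1 * sig[k, f35])
})

test_that("cycles beyond the signal end are dropped with a warning", {
  cyc <- make_regular_cycles(20)
  n <- cyc$trough_end[10] + 10L
  expect_warning(sig <- spectral_signatures(rnorm(n), cyc, fs_test),
                 "dropped")
  expect_equal(nrow(sig), 10)
})

test_that("two-template mixtures are recovered with high cosine similarity", {
  sig <- make_template_signatures(n_cycles = 400, centers = c(35, 80),
                                  seed = 1)
  mod <- extract_tscs(sig, n_pcs = 2, seed = 2)
  tmpl <- attr(sig, "templates")
  sims <- vapply(1:2, function(k)
    max(cosine_sim(mod$components[k, ], tmpl[1, ]),
        cosine_sim(mod$components[k, ], tmpl[2, ])), numeric(1))
  expect_true(all(sims > 0.95))
  expect_equal(mod$peak_freqs, c(35, 80), tolerance = 0.05)
})

test_that("components satisfy the positive mean-projection rule and ordering", {
  fix <- pipeline_fixture()
  mod <- fix$model
  proj <- unclass(fix$sigs) %*% t(mod$components)
  expect_true(all(colMeans(proj) > 0))
  expect_true(!is.unsorted(mod$peak_freqs))
})

test_that("row permutation of signatures leaves components unchanged", {
  sig <- make_template_signatures(n_cycles = 300, seed = 3)
  set.seed(4)
  perm <- sample(nrow(sig))
  sig_p <- structure(unclass(sig)[perm, ], freqs = attr(sig, "freqs"),
                     cycle_id = seq_len(nrow(sig)),
                     class = c("signature_matrix", "matrix"))
  m1 <- extract_tscs(sig, n_pcs = 2, seed = 5)
  m2 <- extract_tscs(sig_p, n_pcs = 2, seed = 5)
  for (k in 1:2)
    expect_gt(abs(cosine_sim(m1$components[k, ], m2$components[k, ])),
              0.999)
})

test_that("strengths are inner products with the expected special cases", {
  sig <- make_template_signatures(n_cycles = 300, seed = 6)
  mod <- extract_tscs(sig, n_pcs = 2, seed = 7)
  w <- mod$components[1, ]
  S <- rbind(w, 0 * w, mod$components[2, ] -
               w * sum(w * mod$components[2, ]) / sum(w^2))
  st <- tsc_strength(mod, S)
  expect_equal(st$strengths[1, 1], sum(w^2))
  expect_equal(st$strengths[2, 1], 0)
  expect_equal(st$strengths[3, 1], 0, tolerance = 1e-10)
})

test_that("tsc_threshold matches the direct arithmetic oracle", {
  expect_equal(tsc_threshold(c(1, 2, 3, 4, 5)), 3 + 2 * 1 / 0.6745,
               tolerance = 1e-12)
  expect_equal(tsc_threshold(rep(4.2, 10)), 4.2)
  expect_error(tsc_threshold(c(1, 2)), "at least 3")
})

test_that("tsc_threshold is equivariant under affine maps", {
  set.seed(8)
  p <- rnorm(500)
  a <- 2.5; b <- -3
  expect_equal(tsc_threshold(a * p + b), a * tsc_threshold(p) + b,
               tolerance = 1e-10)
})

test_that("threshold estimates mu + 2 sigma for Gaussian strengths", {
  set.seed(9)
  p <- rnorm(1e5, mean = 3, sd = 2)
  expect_lt(abs(tsc_threshold(p) - (3 + 2 * 2)), 0.05 * 2)
  # fraction above threshold for standard normal ~ P(Z > 2)
  z <- rnorm(1e5)
  frac <- mean(z > tsc_threshold(z))
  expect_lt(abs(frac - pnorm(2, lower.tail = FALSE)), 0.005)
})

test_that("strength scales linearly with supra-theta content", {
  fs <- fs_test
  cyc <- make_regular_cycles(60)
  n <- max(cyc$spike_end) + fs
  t <- (seq_len(n) - 1) / fs
  set.seed(10)
  supra <- cos(2 * pi * 40 * t) * (0.5 + runif(1))
  sig1 <- spectral_signatures(supra, cyc, fs)
  sig3 <- spectral_signatures(3 * supra, cyc, fs)
  mod <- extract_tscs(make_template_signatures(300, seed = 11),
                      n_pcs = 2, seed = 12)
  s1 <- tsc_strength(mod, sig1)$strengths
  s3 <- tsc_strength(mod, sig3)$strengths
  expect_equal(s3, 3 * s1, tolerance = 1e-8)
})

test_that("strength timecourse localizes injected families in phase", {
  fs <- fs_test
  cyc <- make_regular_cycles(200)
  n <- max(cyc$spike_end) + fs
  t <- (seq_len(n) - 1) / fs
  phase <- make_regular_phase(cyc, n)
  ph0 <- ifelse(is.na(phase$phase), 0, phase$phase)
  cyc_of <- ifelse(is.na(phase$cycle), 1L, phase$cycle)
  set.seed(13)
  # two families, phase-locked at +120 and -60 deg, independent per-cycle
  # amplitudes so ICA can separate them
  mk <- function(f, mu) {
    amp <- (stats::rbinom(nrow(cyc), 1, 0.4) *
              runif(nrow(cyc), 0.5, 1.5))[cyc_of]
    amp * exp(2 * cos(thetanest:::deg2rad(ph0 - mu))) * cos(2 * pi * f * t)
  }
  supra <- mk(40, 120) + mk(90, -60)
  sig <- spectral_signatures(supra, cyc, fs)
  mod <- extract_tscs(sig, n_pcs = 2, n_comp = 2, seed = 14)
  expect_lt(abs(mod$peak_freqs[1] - 40), 4)
  expect_lt(abs(mod$peak_freqs[2] - 90), 6)
  tc <- strength_timecourse(mod, supra, fs)
  prof <- strength_phase_profile(tc, phase)
  expect_lt(abs(thetanest:::wrap_deg(prof$peak_phase[1] - 120)), 15)
  expect_lt(abs(thetanest:::wrap_deg(prof$peak_phase[2] + 60)), 15)
  # z-scored series
  expect_lt(abs(mean(tc[1, ])), 1e-8)
  expect_equal(sd(tc[1, ]), 1, tolerance = 1e-6)
})

test_that("phase-amplitude profile peaks where the modulation peaks", {
  fs <- fs_test
  cyc <- make_regular_cycles(100)
  n <- max(cyc$spike_end) + fs
  t <- (seq_len(n) - 1) / fs
  phase <- make_regular_phase(cyc, n)
  gain <- 1 + cos(thetanest:::deg2rad(ifelse(is.na(phase$phase), 0,
                                             phase$phase)))
  x <- gain * cos(2 * pi * 80 * t)
  prof <- phase_amplitude_profile(x, phase, fs = fs, freqs = seq(20, 120,
                                                                 by = 5))
  row80 <- prof[, attr(prof, "freqs") == 80]
  expect_lt(abs(attr(prof, "bins")[which.max(row80)]), 15)
  # duplicate-all subset equals all
  p2 <- phase_amplitude_profile(x, phase,
                                cycle_subset = cyc$cycle_id,
                                fs = fs, freqs = seq(20, 120, by = 5))
  expect_equal(prof, p2)
  expect_error(phase_amplitude_profile(x, phase, cycle_subset = integer(),
                                       fs = fs), "empty")
})

test_that("speed modulation detects planted coupling and its sign", {
  set.seed(14)
  n <- 400
  cyc <- make_regular_cycles(n)
  cyc$speed <- runif(n, 2, 20)
  S <- cbind(0.5 * cyc$speed + rnorm(n, sd = 0.3),
             -0.5 * cyc$speed + rnorm(n, sd = 0.3),
             rnorm(n))
  st <- structure(list(strengths = S, cycle_id = cyc$cycle_id),
                  class = "strength_table")
  colnames(st$strengths) <- paste0("tSC", 1:3)
  res <- speed_modulation(st, cyc, n_boot = 500, seed = 15)
  expect_gt(res$r[1], 0.9)
  expect_lt(res$p_boot[1], 2 / 500)
  expect_lt(res$r[2], -0.9)
  expect_lt(abs(res$r[3]), 0.15)
})

test_that("tsc model JSON round-trips", {
  sig <- make_template_signatures(300, seed = 16)
  mod <- extract_tscs(sig, n_pcs = 2, seed = 17)
  p <- tempfile(fileext = ".json")
  write_tsc_model(mod, p)
  back <- read_tsc_model(p)
  expect_equal(unname(back$components), unname(mod$components),
               tolerance = 1e-12)
  expect_equal(back$peak_freqs, mod$peak_freqs)
  expect_equal(back$thresholds, unname(mod$thresholds), tolerance = 1e-12)
})

test_that("session subsampling balances cycle counts and is seeded", {
  s1 <- make_template_signatures(300, seed = 20)
  s2 <- make_template_signatures(180, seed = 21)
  bal <- subsample_sessions(list(fam = s1, nov = s2), seed = 22)
  expect_equal(nrow(bal), 360)
  expect_equal(as.vector(table(attr(bal, "session"))), c(180, 180))
  expect_equal(attr(bal, "seed"), 22)
  bal2 <- subsample_sessions(list(fam = s1, nov = s2), seed = 22)
  expect_identical(unclass(bal), unclass(bal2))
  # a model still fits on the balanced matrix
  mod <- extract_tscs(bal, n_pcs = 2, seed = 23)
  expect_equal(length(mod$peak_freqs), 2)
})
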