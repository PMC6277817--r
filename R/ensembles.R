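# Cross-validated GLM prediction of per-cycle tSC strength from ensemble
# spike counts, with circular-shift nulls, cross-tSC transfer, speed
# controls and spatial information.

#' Per-cycle spike-count matrix
#'
#' Counts each unit's spikes inside each cycle's spike-analysis bounds
#' (ascending zero-crossings flanking the peak), half-open: a spike at
#' the left bound counts, one at the right bound does not.
#'
#' @param spikes spike table (`unit`, `time`).
#' @param cycles cycle table.
#' @param fs sampling rate, Hz.
#' @param units unit ids to include (default all present, sorted).
#' @param t0 time of the first LFP sample.
#' @return integer matrix units x cycles with dimnames.
#' @export
cycle_spike_counts <- function(spikes, cycles, fs, units = NULL, t0 = 0) {
  if (is.null(units)) units <- sort(unique(spikes$unit))
  M <- matrix(0L, length(units), nrow(cycles),
              dimnames = list(units, cycles$cycle_id))
  for (i in seq_along(units)) {
    tt <- spikes$time[spikes$unit == units[i]]
    row_of <- assign_spikes_to_cycles(tt, cycles, fs, t0)
    tab <- table(row_of)
    if (length(tab))
      M[i, as.integer(names(tab))] <- as.integer(tab)
  }
  M
}

# One full k-fold CV pass; counts: units x cycles, y: strengths.
# Per fold, counts and strengths are z-scored by training statistics and
# an intercept OLS is fit; implemented on centered normal equations
# (training Gram = full Gram - test Gram) so repeated calls (shift
# nulls) stay cheap.  The standardized coefficient is
# beta_std_j = beta_centered_j * sd_j / sd_y, and the standardized
# test prediction is ((x - mu) . beta_centered) / sd_y.
cv_glm_once <- function(counts, y, k, folds) {
  X <- t(counts)
  n <- nrow(X); u <- ncol(X)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  cs_all <- colSums(X)
  sy_all <- sum(y)
  pred <- numeric(n)
  betas <- matrix(0, k, u)
  for (f in seq_len(k)) {
    te <- which(folds == f)
    Xte <- X[te, , drop = FALSE]
    n_tr <- n - length(te)
    cs <- cs_all - colSums(Xte)
    mu <- cs / n_tr
    ysum <- sy_all - sum(y[te])
    my <- ysum / n_tr
    G <- XtX - crossprod(Xte) - tcrossprod(cs) / n_tr
    b <- Xty - crossprod(Xte, y[te]) - cs * my
    sdv2 <- diag(G) / (n_tr - 1)
    y_tr <- y[-te]
    sy <- sd(y_tr)
    if (sy == 0) stop("constant strength vector in a training fold")
    cf <- tryCatch(solve(G, b),
                   error = function(e) qr.coef(qr(G), b))
    cf[is.na(cf)] <- 0
    betas[f, ] <- cf * sqrt(pmax(sdv2, 0)) / sy
    pred[te] <- (Xte %*% cf - sum(mu * cf)) / sy
  }
  list(pred = pred, beta = colMeans(betas))
}

#' Fit a cross-validated GLM predicting tSC strength from spike counts
#'
#' Identity-link Gaussian GLM (ordinary least squares) with k-fold
#' cross-validation: per fold, counts and strengths are z-scored by
#' training-set statistics, the model is fit on training cycles and
#' evaluated on held-out cycles; every cycle is tested exactly once.
#' Prediction accuracy is the Pearson correlation between observed and
#' concatenated out-of-fold predicted strengths.
#'
#' @param counts units x cycles matrix from [cycle_spike_counts()].
#' @param strengths per-cycle strength vector for one tSC.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the random fold partition.
#' @return object of class `glm_result`: list with `cv_r`, `beta` (mean
#'   over folds, one per unit), `pred`, `folds`, `k`, `seed`.
#' @export
fit_tsc_glm <- function(counts, strengths, k = 10L, seed = 1L) {
  n <- ncol(counts)
  stopifnot(length(strengths) == n, n >= 2L * k)
  if (sd(strengths) == 0) stop("constant strength vector: r undefined")
  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  fit <- cv_glm_once(counts, strengths, k, folds)
  structure(list(cv_r = cor(fit$pred, strengths), beta = fit$beta,
                 pred = fit$pred, folds = folds, k = k, seed = seed),
            class = "glm_result")
}

#' Circular-shift null for a tSC GLM
#'
#' Circularly shifts the cycle axis of the spike-count matrix (all units
#' together, preserving inter-unit correlations and per-unit
#' autocorrelation), re-runs the full cross-validation per shift, and
#' standardizes the original prediction against the null distribution:
#' `r_hat = (r - mean(r_null)) / sd(r_null)`.  Significant iff the
#' original `cv_r` exceeds the null's 99th percentile.
#'
#' @param counts units x cycles matrix.
#' @param strengths strength vector.
#' @param n_shift number of circular shifts (default 1000).
#' @param k folds.
#' @param seed RNG seed.
#' @return list with `glm` (the original fit), `null_r`, `r_hat`,
#'   `q99`, `significant`.
#' @export
shift_null <- function(counts, strengths, n_shift = 1000L, k = 10L,
                       seed = 1L) {
  orig <- fit_tsc_glm(counts, strengths, k = k, seed = seed)
  n <- ncol(counts)
  set.seed(seed + 1L)
  null_r <- numeric(n_shift)
  for (b in seq_len(n_shift)) {
    sh <- sample.int(n - 1L, 1L)
    idx <- c((sh + 1L):n, seq_len(sh))
    folds <- sample(rep(seq_len(k), length.out = n))
    fit <- cv_glm_once(counts[, idx, drop = FALSE], strengths, k, folds)
    null_r[b] <- cor(fit$pred, strengths)
  }
  sdn <- sd(null_r)
  q99 <- quantile(null_r, 0.99, names = FALSE)
  list(glm = orig, null_r = null_r,
       r_hat = if (sdn > 0) (orig$cv_r - mean(null_r)) / sdn else NA_real_,
       q99 = q99, significant = orig$cv_r > q99)
}

#' Cross-tSC transfer of GLM weights
#'
#' Predicts tSC j's strength with the weights fitted for tSC i
#' (z-scoring counts and strengths globally), standardizes each
#' prediction by the matching null mean/SD when nulls are supplied, and
#' normalizes rows by the matched (i = j) value.
#'
#' @param models list of [fit_tsc_glm()] results, one per tSC.
#' @param counts units x cycles matrix.
#' @param strengths_matrix cycles x tSC strength matrix.
#' @param nulls optional list of [shift_null()] results (for r-hat
#'   standardization).
#' @return list with `r` (model i x target j Pearson matrix) and
#'   `normalized` (rows divided by the diagonal).
#' @export
cross_tsc_prediction <- function(models, counts, strengths_matrix,
                                 nulls = NULL) {
  m <- length(models)
  stopifnot(ncol(strengths_matrix) == m)
  Xs <- scale(t(counts))
  Xs[!is.finite(Xs)] <- 0
  R <- matrix(NA_real_, m, m)
  for (i in seq_len(m)) {
    pred <- Xs %*% models[[i]]$beta
    for (j in seq_len(m)) R[i, j] <- cor(pred, strengths_matrix[, j])
  }
  if (!is.null(nulls)) {
    for (i in seq_len(m)) {
      mu <- mean(nulls[[i]]$null_r); sdv <- sd(nulls[[i]]$null_r)
      R[i, ] <- (R[i, ] - mu) / sdv
    }
  }
  norm <- sweep(R, 2L, diag(R), "/")
  list(r = R, normalized = norm)
}

#' Speed controls for tSC GLMs
#'
#' (a) Re-fits CV GLMs restricted to cycles inside narrow instantaneous
#' speed bins, each against its own shift null, averaged over non-empty
#' bins; (b) compares three GLMs with speed as an added regressor:
#' original speed + shuffled spikes, original spikes + shuffled speed,
#' original speed + original spikes (shuffles = circular shifts, means
#' over `n_real` realizations).
#'
#' @param counts units x cycles matrix.
#' @param strengths strength vector.
#' @param speed per-cycle speed, cm/s.
#' @param bins list of speed-bin bounds (default the five 2-cm/s bins
#'   from 1 to 11 cm/s).
#' @param n_shift shifts per bin null.
#' @param n_real shuffle realizations for the regressor comparison.
#' @param k folds.
#' @param seed RNG seed.
#' @return list with `per_bin` (data frame: bin, n, r, null_mean, r_hat)
#'   and `conditions` (named numeric: r for speed_only, spikes_only,
#'   speed_plus_spikes).
#' @export
speed_controls <- function(counts, strengths, speed,
                           bins = list(c(1, 3), c(3, 5), c(5, 7),
                                       c(7, 9), c(9, 11)),
                           n_shift = 200L, n_real = 1000L, k = 10L,
                           seed = 1L) {
  per_bin <- list()
  for (b in seq_along(bins)) {
    sel <- which(speed >= bins[[b]][1] & speed < bins[[b]][2])
    if (length(sel) < 3L * k) {
      warning("speed bin ", b, " has too few cycles; skipped")
      next
    }
    sn <- shift_null(counts[, sel, drop = FALSE], strengths[sel],
                     n_shift = n_shift, k = k, seed = seed + b)
    per_bin[[length(per_bin) + 1L]] <-
      data.frame(bin = paste(bins[[b]], collapse = "-"),
                 n = length(sel), r = sn$glm$cv_r,
                 null_mean = mean(sn$null_r), r_hat = sn$r_hat)
  }
  per_bin <- if (length(per_bin)) do.call(rbind, per_bin) else NULL

  # condition GLMs: same number of regressors (units + speed)
  set.seed(seed + 100L)
  n <- ncol(counts)
  fit_cond <- function(cnt, sp, sd_seed) {
    fit_tsc_glm(rbind(cnt, speed = sp), strengths, k = k,
                seed = sd_seed)$cv_r
  }
  shifts <- sample.int(n - 1L, min(n_real, n - 1L), replace = n_real > n - 1L)
  r1 <- mean(vapply(seq_along(shifts), function(i) {
    idx <- c((shifts[i] + 1L):n, seq_len(shifts[i]))
    fit_cond(counts[, idx, drop = FALSE], speed, seed + 200L + i)
  }, numeric(1)))
  r2 <- mean(vapply(seq_along(shifts), function(i) {
    idx <- c((shifts[i] + 1L):n, seq_len(shifts[i]))
    fit_cond(counts, speed[idx], seed + 400L + i)
  }, numeric(1)))
  r3 <- fit_cond(counts, speed, seed + 600L)
  list(per_bin = per_bin,
       conditions = c(speed_only = r1, spikes_only = r2,
                      speed_plus_spikes = r3))
}

#' Skaggs spatial information (bits per spike)
#'
#' `sum_i P_i * (R_i / R) * log2(R_i / R)` with the `0 * log(0) = 0`
#' convention, where `P_i` is occupancy probability and `R_i` the rate
#' in bin i, and `R = sum_i P_i R_i`.
#'
#' @param occupancy occupancy probabilities (will be renormalized).
#' @param rates mean firing rate per spatial bin, Hz.
#' @return bits/spike (0 when the overall rate is 0).
#' @export
unit_spatial_information <- function(occupancy, rates) {
  stopifnot(length(occupancy) == length(rates), all(occupancy >= 0),
            all(rates >= 0))
  P <- occupancy / sum(occupancy)
  R <- sum(P * rates)
  if (R == 0) return(0)
  x <- rates / R
  sum(ifelse(x > 0, P * x * log2(x), 0))
}

#' Correlate per-unit GLM weights with a per-unit covariate (Spearman)
#' @param beta per-unit GLM weights.
#' @param covariate per-unit covariate (speed modulation or spatial
#'   information).
#' @return Spearman rho.
#' @export
weight_covariate_correlation <- function(beta, covariate) {
  cor(beta, covariate, method = "spearman")
}
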