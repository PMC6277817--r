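# Theta-nested spectral components (tSCs): per-cycle Morlet spectral
# signatures of the supra-theta signal, PCA + FastICA extraction of
# frequency-weight components, per-cycle strengths (projections),
# MAD-based strength thresholds, per-sample strength time courses and
# phase/speed profiles.

#' Per-cycle spectral signatures of the supra-theta signal
#'
#' Morlet wavelet amplitude (10-200 Hz, 1-Hz steps by default) averaged
#' trough-to-trough within each detected theta cycle.
#'
#' @param supra supra-theta composite signal (from [classify_imfs()]).
#' @param cycles a [detect_theta_cycles()] table.
#' @param fs sampling rate, Hz.
#' @param freqs frequency grid, Hz.
#' @param omega0 Morlet width parameter.
#' @return object of class `signature_matrix`: numeric matrix n_cycles x
#'   n_freqs with attributes `freqs` and `cycle_id`.
#' @export
spectral_signatures <- function(supra, cycles, fs, freqs = 10:200,
                                omega0 = 5) {
  if (nrow(cycles) == 0L) stop("no cycles supplied")
  n <- length(supra)
  inside <- cycles$trough_start >= 1L & cycles$trough_end <= n
  if (any(!inside))
    warning(sum(!inside), " cycle(s) extend beyond the signal; dropped")
  cyc <- cycles[inside, , drop = FALSE]
  # map samples -> cycle row (cycles are non-overlapping half-open spans)
  grp <- rep(NA_integer_, n)
  for (j in seq_len(nrow(cyc)))
    grp[cyc$trough_start[j]:(cyc$trough_end[j] - 1L)] <- j
  sel <- which(!is.na(grp))
  g <- grp[sel]
  cnt <- tabulate(g, nbins = nrow(cyc))
  sig <- matrix(0, nrow(cyc), length(freqs))
  morlet_apply(supra, fs, freqs, omega0, function(i, amp) {
    sig[, i] <<- rowsum(amp[sel], g)[, 1L] / cnt
  })
  structure(sig, freqs = as.numeric(freqs), cycle_id = cyc$cycle_id,
            class = c("signature_matrix", "matrix"))
}

# Symmetric FastICA on whitened data Z (n x d).  Contrasts: "skew"
# (g(u) = u^2, maximizes |skewness|; suited to one-sided burst-like
# sources) and "logcosh" (g = tanh, classic heavy-tail contrast).
fast_ica_sym <- function(Z, n_comp, seed, contrast = c("skew", "logcosh"),
                         max_iter = 500, tol = 1e-7) {
  contrast <- match.arg(contrast)
  d <- ncol(Z)
  set.seed(seed)
  W <- matrix(rnorm(n_comp * d), n_comp, d)
  sym_decorrelate <- function(W) {
    s <- W %*% t(W)
    e <- eigen(s, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), n_comp) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WX <- Z %*% t(W)                      # n x n_comp
    if (contrast == "skew") {
      G <- WX^2
      gp <- 2 * WX
    } else {
      G <- tanh(WX)
      gp <- 1 - G^2
    }
    W1 <- t(G) %*% Z / nrow(Z) - diag(colMeans(gp), n_comp) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) return(list(W = W, converged = TRUE, iter = it))
  }
  list(W = W, converged = FALSE, iter = max_iter)
}

#' Extract theta-nested spectral components by PCA + FastICA
#'
#' Signatures are centered, reduced to `n_pcs` principal components,
#' whitened and unmixed by symmetric FastICA (logcosh contrast).  The
#' tSC weight vectors are the ICA mixing patterns mapped back to
#' frequency space (the spectral shapes the components contribute to
#' the data).  Because FastICA has local optima, the default fit is a
#' consensus over `n_restarts` random initializations: patterns pooled
#' across restarts are clustered by absolute cosine similarity
#' (average-linkage) into `n_comp` clusters and each cluster's
#' centrotype (the member most similar to its cluster) is kept, with a
#' per-component stability index.  `n_restarts = 1` gives a single
#' plain FastICA fit.  Each component's sign is fixed so its mean
#' projection onto the raw signatures is positive; components are
#' ordered by ascending peak frequency.  Per-component strength
#' thresholds (see [tsc_threshold()]) are computed from the training
#' signatures.
#'
#' @param sigs a [spectral_signatures()] matrix.
#' @param n_pcs number of principal components retained (default 5).
#' @param n_comp number of independent components (default `n_pcs`).
#' @param n_restarts FastICA restarts pooled into the consensus
#'   (default 30).
#' @param contrast FastICA contrast: `"skew"` (default; matches the
#'   one-sided, burst-like distribution of per-cycle strengths) or
#'   `"logcosh"`.
#' @param seed RNG seed for FastICA initialization (recorded in the
#'   model; non-convergent restarts are dropped).
#' @return object of class `tsc_model`: list with `components` (n_comp x
#'   n_freqs weight matrix), `freqs`, `peak_freqs`, `pca` (rotation,
#'   center, sdev), `thresholds`, `stability`, `n_pcs`, `seed`.
#' @export
extract_tscs <- function(sigs, n_pcs = 5L, n_comp = n_pcs,
                         n_restarts = 30L, contrast = c("skew", "logcosh"),
                         seed = 1L) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(sigs, "signature_matrix") || is.matrix(sigs))
  freqs <- attr(sigs, "freqs")
  if (is.null(freqs)) freqs <- seq_len(ncol(sigs))
  X <- unclass(sigs)
  if (nrow(X) < 10 * n_pcs)
    stop("need at least 10 x n_pcs cycles to fit the model")
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pcs)
  Z <- sweep(pc$x, 2L, pc$sdev[seq_len(n_pcs)], "/")     # whitened
  rot_t <- t(pc$rotation[, seq_len(n_pcs), drop = FALSE])
  back <- diag(pc$sdev[seq_len(n_pcs)], n_pcs) %*% rot_t
  fit_one <- function(s) {
    res <- fast_ica_sym(Z, n_comp, seed = s, contrast = contrast)
    if (!res$converged) return(NULL)
    A <- res$W %*% back
    sgn <- ifelse(colMeans(X %*% t(A)) >= 0, 1, -1)
    A * sgn
  }
  pats <- list()
  for (r in seq_len(max(n_restarts, 1L))) {
    A <- fit_one(seed + r - 1L)
    if (!is.null(A)) pats[[length(pats) + 1L]] <- A
  }
  if (!length(pats) && contrast == "skew") {
    # sources with little skewness leave the skew fixed point without a
    # stable solution; fall back to the heavy-tail contrast
    warning("skew-contrast FastICA did not converge; falling back to ",
            "contrast = \"logcosh\"")
    contrast <- "logcosh"
    for (r in seq_len(max(n_restarts, 1L))) {
      A <- fit_one(seed + r - 1L)
      if (!is.null(A)) pats[[length(pats) + 1L]] <- A
    }
  }
  if (!length(pats))
    stop("FastICA failed to converge in every restart")
  if (length(pats) == 1L) {
    comps <- pats[[1L]]
    stability <- rep(NA_real_, n_comp)
  } else {
    P <- do.call(rbind, pats)
    Pn <- P / sqrt(rowSums(P^2))
    S <- abs(Pn %*% t(Pn))
    cl <- stats::cutree(stats::hclust(stats::as.dist(1 - S),
                                      method = "average"), k = n_comp)
    cent <- integer(n_comp)
    stability <- numeric(n_comp)
    for (k in seq_len(n_comp)) {
      m <- which(cl == k)
      within <- colMeans(S[m, m, drop = FALSE])
      cent[k] <- m[which.max(within)]
      between <- if (length(m) < nrow(S))
        mean(S[m, -m, drop = FALSE]) else 0
      stability[k] <- mean(S[m, m]) - between
    }
    comps <- P[cent, , drop = FALSE]
  }
  peak <- freqs[apply(comps, 1L, which.max)]
  ord <- order(peak)
  comps <- comps[ord, , drop = FALSE]
  peak <- peak[ord]
  stability <- stability[ord]
  rownames(comps) <- paste0("tSC", seq_len(n_comp))
  model <- structure(list(components = comps, freqs = freqs,
                          peak_freqs = peak,
                          pca = list(rotation = pc$rotation,
                                     center = pc$center, sdev = pc$sdev),
                          thresholds = NULL, stability = stability,
                          n_pcs = n_pcs, seed = seed),
                     class = "tsc_model")
  st <- tsc_strength(model, sigs)
  model$thresholds <- apply(st$strengths, 2L, tsc_threshold)
  model
}

#' @export
print.tsc_model <- function(x, ...) {
  cat(sprintf("<tsc_model> %d components, peak freqs (Hz): %s\n",
              nrow(x$components),
              paste(x$peak_freqs, collapse = ", ")))
  invisible(x)
}

#' Per-cycle tSC strengths
#'
#' Strength = inner product of each (uncentered) cycle signature with
#' each component weight vector.  Optional z-scoring records its
#' normalization provenance (`"none"`, `"all"` or `"baseline"`).
#'
#' @param model a [extract_tscs()] model.
#' @param sigs signature matrix.
#' @param zscore `"none"`, `"all"` (all-cycles mean/SD) or `"baseline"`.
#' @param baseline_mask logical mask of baseline cycles (for
#'   `zscore = "baseline"`).
#' @return object of class `strength_table`: list with `strengths`
#'   (n_cycles x n_comp), `above_threshold` (flags on raw strengths),
#'   `normalization`, `cycle_id`.
#' @export
tsc_strength <- function(model, sigs, zscore = c("none", "all", "baseline"),
                         baseline_mask = NULL) {
  zscore <- match.arg(zscore)
  X <- unclass(sigs)
  raw <- X %*% t(model$components)
  colnames(raw) <- rownames(model$components)
  above <- NULL
  if (!is.null(model$thresholds))
    above <- sweep(raw, 2L, model$thresholds, ">")
  out <- raw
  if (zscore == "all") {
    out <- scale(raw)
  } else if (zscore == "baseline") {
    if (is.null(baseline_mask)) stop("baseline_mask required")
    out <- baseline_zscore(raw, baseline_mask)
  }
  structure(list(strengths = out, raw = raw, above_threshold = above,
                 normalization = zscore,
                 cycle_id = attr(sigs, "cycle_id")),
            class = "strength_table")
}

#' MAD-based strength threshold
#'
#' `threshold = 2 * median(|p - median(p)|) / 0.6745 + median(p)`; the
#' MAD term is a robust estimate of the SD, so the threshold sits two
#' robust SDs above the median.
#'
#' @param p numeric vector of strengths (length >= 3).
#' @return scalar threshold.
#' @export
tsc_threshold <- function(p) {
  if (length(p) < 3L) stop("need at least 3 values")
  med <- median(p)
  2 * median(abs(p - med)) / 0.6745 + med
}

#' Per-sample tSC strength time course
#'
#' Projects the instantaneous Morlet amplitude vector (same grid as the
#' signatures) of the supra-theta signal onto each component, giving a
#' strength series at the LFP resolution; optionally z-scored per
#' component.
#'
#' @param model tSC model.
#' @param supra supra-theta signal.
#' @param fs sampling rate, Hz.
#' @param zscore z-score each component's series (default TRUE).
#' @return matrix n_comp x n_samples.
#' @export
strength_timecourse <- function(model, supra, fs, zscore = TRUE) {
  n <- length(supra)
  k <- nrow(model$components)
  out <- matrix(0, k, n)
  morlet_apply(supra, fs, model$freqs, 5, function(i, amp) {
    out <<- out + model$components[, i] %o% amp
  })
  if (zscore) out <- t(scale(t(out)))
  rownames(out) <- rownames(model$components)
  out
}

#' Bin a strength time course by theta phase
#'
#' @param timecourse matrix from [strength_timecourse()].
#' @param phase a [theta_phase()] series.
#' @param n_bins number of phase bins (default 60).
#' @return list with `bins` (bin-center degrees), `profile` (n_comp x
#'   n_bins mean strength) and `peak_phase` (degrees per component).
#' @export
strength_phase_profile <- function(timecourse, phase, n_bins = 60L) {
  ok <- which(phase$valid)
  b <- pmin(floor((phase$phase[ok] + 180) / (360 / n_bins)) + 1L, n_bins)
  centers <- -180 + (seq_len(n_bins) - 0.5) * 360 / n_bins
  prof <- t(vapply(seq_len(nrow(timecourse)), function(k) {
    as.numeric(rowsum(timecourse[k, ok], b)[, 1L]) / tabulate(b, n_bins)
  }, numeric(n_bins)))
  list(bins = centers, profile = prof,
       peak_phase = centers[apply(prof, 1L, which.max)])
}

#' Phase-by-frequency amplitude profile
#'
#' Mean Morlet amplitude per (theta phase bin, frequency) over the
#' selected cycles; used for raw-LFP phase-amplitude maps and reused for
#' CSD laminar profiles.
#'
#' @param signal signal to analyze (raw LFP, supra-theta or a CSD trace).
#' @param phase a [theta_phase()] series aligned with `signal`.
#' @param cycle_subset cycle ids to include (default all valid samples).
#' @param fs sampling rate, Hz.
#' @param freqs frequency grid, Hz.
#' @param n_bins number of phase bins.
#' @param omega0 Morlet width.
#' @return matrix n_bins x n_freqs with attributes `bins`, `freqs`.
#' @export
phase_amplitude_profile <- function(signal, phase, cycle_subset = NULL,
                                    fs, freqs = 10:200, n_bins = 60L,
                                    omega0 = 5) {
  keep <- phase$valid
  if (!is.null(cycle_subset)) {
    if (!length(cycle_subset)) stop("empty cycle subset")
    keep <- keep & !is.na(phase$cycle) & phase$cycle %in% cycle_subset
  }
  sel <- which(keep)
  if (!length(sel)) stop("no samples selected")
  b <- pmin(floor((phase$phase[sel] + 180) / (360 / n_bins)) + 1L, n_bins)
  cnt <- tabulate(b, n_bins)
  out <- matrix(0, n_bins, length(freqs))
  morlet_apply(signal, fs, freqs, omega0, function(i, amp) {
    out[, i] <<- rowsum(amp[sel], b)[, 1L] / cnt
  })
  attr(out, "bins") <- -180 + (seq_len(n_bins) - 0.5) * 360 / n_bins
  attr(out, "freqs") <- as.numeric(freqs)
  out
}

#' Speed modulation of tSC strength
#'
#' Pearson correlation between per-cycle strength and per-cycle speed,
#' with a two-sided bootstrap p value obtained by resampling cycles with
#' replacement.
#'
#' @param strengths a [tsc_strength()] table.
#' @param cycles the matching cycle table (provides `speed`).
#' @param n_boot bootstrap draws.
#' @param seed RNG seed.
#' @return data frame with `tsc`, `r`, `p_boot`.
#' @export
speed_modulation <- function(strengths, cycles, n_boot = 1000L, seed = 1L) {
  sp <- cycles$speed[match(strengths$cycle_id, cycles$cycle_id)]
  ok <- !is.na(sp)
  S <- strengths$strengths[ok, , drop = FALSE]
  sp <- sp[ok]
  set.seed(seed)
  n <- length(sp)
  out <- lapply(seq_len(ncol(S)), function(k) {
    r <- cor(S[, k], sp)
    boot <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      suppressWarnings(cor(S[i, k], sp[i]))
    }, numeric(1))
    boot <- boot[is.finite(boot)]
    p <- 2 * min(sum(boot <= 0) + 1, sum(boot >= 0) + 1) / (length(boot) + 1)
    data.frame(tsc = colnames(S)[k], r = r, p_boot = min(p, 1))
  })
  do.call(rbind, out)
}

#' Balance sessions before a joint tSC extraction
#'
#' When components are compared across sessions (e.g. familiar vs novel
#' environments), each session contributes the same number of spectral
#' signatures — the minimum cycle count across sessions — so no session
#' dominates the fit.  Rows are subsampled without replacement; the seed
#' is recorded in the result's attributes.
#'
#' @param sig_list named list of [spectral_signatures()] matrices.
#' @param seed RNG seed for the subsampling.
#' @return one stacked `signature_matrix` with attributes `session`
#'   (label per row), `seed`, and per-session `cycle_id`s preserved.
#' @export
subsample_sessions <- function(sig_list, seed = 1L) {
  stopifnot(length(sig_list) >= 2L)
  n_min <- min(vapply(sig_list, nrow, integer(1)))
  set.seed(seed)
  rows <- lapply(sig_list, function(s)
    sort(sample.int(nrow(s), n_min)))
  out <- do.call(rbind, Map(function(s, r) unclass(s)[r, , drop = FALSE],
                            sig_list, rows))
  structure(out,
            freqs = attr(sig_list[[1L]], "freqs"),
            cycle_id = unlist(Map(function(s, r)
              attr(s, "cycle_id")[r], sig_list, rows), use.names = FALSE),
            session = rep(names(sig_list), each = n_min),
            seed = seed,
            class = c("signature_matrix", "matrix"))
}

#' Serialize / load a tSC model as JSON
#' @param model tSC model.
#' @param path file path.
#' @export
write_tsc_model <- function(model, path) {
  jsonlite::write_json(
    list(components = unname(apply(model$components, 1L, as.numeric,
                                   simplify = FALSE)),
         freqs = model$freqs, peak_freqs = model$peak_freqs,
         thresholds = as.numeric(model$thresholds),
         n_pcs = model$n_pcs, seed = model$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tsc_model
#' @export
read_tsc_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  comps <- j$components
  if (is.list(comps)) comps <- do.call(rbind, comps)
  rownames(comps) <- paste0("tSC", seq_len(nrow(comps)))
  structure(list(components = comps, freqs = j$freqs,
                 peak_freqs = j$peak_freqs, pca = NULL,
                 thresholds = j$thresholds, n_pcs = j$n_pcs,
                 seed = j$seed),
            class = "tsc_model")
}
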