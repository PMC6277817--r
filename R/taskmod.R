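# Task-stage modulation of tSC strength: baseline z-scoring, stage ANOVA
# with speed and recording-day covariates, matched-cycle stage controls,
# maze zone assignment and the predefined-band Butterworth control.

#' Z-score strengths against a baseline session
#'
#' All cycles are standardized using the mean and SD of the baseline
#' cycles only, so stage effects read in baseline-SD units.
#'
#' @param strengths numeric vector or matrix (cycles x tSC).
#' @param baseline_mask logical mask of baseline cycles.
#' @return normalized strengths, same shape.
#' @export
baseline_zscore <- function(strengths, baseline_mask) {
  S <- as.matrix(strengths)
  stopifnot(length(baseline_mask) == nrow(S), any(baseline_mask))
  mu <- colMeans(S[baseline_mask, , drop = FALSE])
  sdv <- apply(S[baseline_mask, , drop = FALSE], 2L, sd)
  if (any(sdv == 0)) stop("zero baseline SD")
  out <- sweep(sweep(S, 2L, mu), 2L, sdv, "/")
  if (is.vector(strengths)) out <- out[, 1L]
  out
}

#' Stage ANOVA of normalized tSC strength
#'
#' Ordinary least squares of baseline-normalized strength on stage
#' dummies (baseline as reference), speed, and recording-day dummies;
#' isolates the stage offset from speed and inter-day variability.
#'
#' @param strength_z baseline-normalized strengths (one tSC).
#' @param stage per-cycle stage label; the level named `"baseline"` (or
#'   the first level) is the reference.
#' @param speed per-cycle speed, cm/s.
#' @param day per-cycle recording-day id (optional).
#' @return list with `beta_stage` (named, one per non-reference stage),
#'   `ci_stage` (95%), `p_stage`, `beta_speed`, `fit`.
#' @export
stage_anova <- function(strength_z, stage, speed, day = NULL) {
  stage <- factor(stage)
  if ("baseline" %in% levels(stage)) stage <- stats::relevel(stage, "baseline")
  df <- data.frame(y = strength_z, stage = stage)
  has_speed <- sd(speed) > 0
  if (has_speed) df$speed <- speed
  if (!is.null(day) && length(unique(day)) > 1L)
    df$day <- factor(day)
  fit <- lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  idx <- grep("^stage", rownames(sm))
  list(beta_stage = setNames(sm[idx, 1L], sub("^stage", "",
                                              rownames(sm)[idx])),
       ci_stage = ci[idx, , drop = FALSE],
       p_stage = sm[idx, 4L],
       beta_speed = if (has_speed) sm["speed", 1L] else NA_real_,
       fit = fit)
}

#' Stage-matched control comparisons
#'
#' Matches one cycle from each comparison stage to every cycle of the
#' reference stage (the stage with fewest cycles, typically the memory
#' probe) within speed and location tolerances, and recomputes the mean
#' strength difference per control draw.
#'
#' @param cycles cycle table with `stage`, `speed`, `x`, `y`.
#' @param strengths per-cycle strengths (one tSC), aligned with
#'   `cycles`.
#' @param reference_stage stage whose cycles are the matching targets.
#' @param stages stages to compare against the reference (default all
#'   others).
#' @param n_controls control draws.
#' @param speed_tol,dist_tol matching tolerances.
#' @param seed RNG seed.
#' @return data frame: `stage`, `mean_diff` (reference minus matched
#'   stage mean, averaged over controls), `ci_lo`, `ci_hi` (2.5/97.5
#'   percentiles over controls), `n_matched`.
#' @export
stage_matched_control <- function(cycles, strengths,
                                  reference_stage = "probe",
                                  stages = NULL, n_controls = 200L,
                                  speed_tol = 0.5, dist_tol = 5,
                                  seed = 1L) {
  stopifnot(length(strengths) == nrow(cycles))
  ref_ids <- cycles$cycle_id[cycles$stage == reference_stage]
  if (!length(ref_ids)) stop("no cycles in the reference stage")
  if (is.null(stages))
    stages <- setdiff(unique(cycles$stage), reference_stage)
  s_of <- setNames(strengths, cycles$cycle_id)
  ref_mean <- mean(s_of[as.character(ref_ids)])
  out <- lapply(stages, function(st) {
    pool <- cycles$cycle_id[cycles$stage == st]
    ctrl <- matched_cycle_control(cycles, ref_ids, pool,
                                  n_controls = n_controls,
                                  speed_tol = speed_tol,
                                  dist_tol = dist_tol, seed = seed)
    diffs <- apply(ctrl, 1L, function(ids)
      ref_mean - mean(s_of[as.character(ids)]))
    data.frame(stage = st, mean_diff = mean(diffs),
               ci_lo = quantile(diffs, 0.025, names = FALSE),
               ci_hi = quantile(diffs, 0.975, names = FALSE),
               n_matched = length(ref_ids))
  })
  do.call(rbind, out)
}

#' Leave-k-days-out robustness sweep of the stage model
#'
#' Refits [stage_anova()] on every combination of recording days with
#' `leave_out` days removed, to check that a stage effect does not hinge
#' on one or two days.
#'
#' @param strength_z baseline-normalized strengths.
#' @param stage,speed,day per-cycle covariates as in [stage_anova()].
#' @param leave_out how many days to drop per combination (default 2).
#' @return data frame with one row per combination: the dropped days,
#'   the first stage coefficient and its CI bounds.
#' @export
stage_robustness_sweep <- function(strength_z, stage, speed, day,
                                   leave_out = 2L) {
  days <- sort(unique(day))
  stopifnot(length(days) > leave_out)
  combos <- utils::combn(days, leave_out, simplify = FALSE)
  out <- lapply(combos, function(drop) {
    keep <- !(day %in% drop)
    res <- stage_anova(strength_z[keep], stage[keep], speed[keep],
                       day[keep])
    data.frame(dropped = paste(drop, collapse = "+"),
               beta = unname(res$beta_stage[1L]),
               ci_lo = res$ci_stage[1L, 1L],
               ci_hi = res$ci_stage[1L, 2L])
  })
  do.call(rbind, out)
}

#' Define a maze as a graph of track segments
#'
#' @param nodes data frame `id`, `x`, `y` (cm).
#' @param edges data frame `from`, `to` (node ids).
#' @param goal goal node id.
#' @param departures departure node ids.
#' @param barriers list of barrier segments, each
#'   `c(x1, y1, x2, y2)` in cm.
#' @return object of class `maze_graph`.
#' @export
maze_graph <- function(nodes, edges, goal, departures, barriers = list()) {
  stopifnot(all(c(edges$from, edges$to, goal, departures) %in% nodes$id))
  structure(list(nodes = nodes, edges = edges, goal = goal,
                 departures = departures, barriers = barriers),
            class = "maze_graph")
}

#' Write / read a maze graph as JSON
#' @param maze a [maze_graph()].
#' @param path file path.
#' @export
write_maze_graph <- function(maze, path) {
  jsonlite::write_json(
    list(nodes = maze$nodes, edges = maze$edges, goal = maze$goal,
         departures = maze$departures,
         barriers = lapply(maze$barriers, as.numeric)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_maze_graph
#' @export
read_maze_graph <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  barriers <- if (is.null(j$barriers)) list() else
    lapply(seq_len(NROW(j$barriers)), function(i)
      if (is.matrix(j$barriers)) j$barriers[i, ] else j$barriers[[i]])
  maze_graph(j$nodes, j$edges, j$goal, j$departures, barriers)
}

point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx^2 + dy^2
  t <- if (L2 == 0) 0 else pmin(pmax(((px - x1) * dx + (py - y1) * dy) / L2,
                                     0), 1)
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Assign maze zones to positions
#'
#' Positions are snapped to the nearest point of the track polyline;
#' goal and departure zones use geodesic (along-track) distance up to
#' `path_tol` (20 cm), barrier zones use Euclidean distance up to
#' `eucl_tol` (10 cm).  When definitions overlap the precedence is
#' goal > departure > barrier.
#'
#' @param x,y positions, cm.
#' @param maze a [maze_graph()].
#' @param path_tol path-distance threshold for goal/departure zones, cm.
#' @param eucl_tol Euclidean threshold for barrier zones, cm.
#' @return character vector in `{"goal", "departure", "barrier",
#'   "none"}`.
#' @export
zone_assignment <- function(x, y, maze, path_tol = 20, eucl_tol = 10) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("zone_assignment requires the igraph package")
  nd <- maze$nodes
  ed <- maze$edges
  i1 <- match(ed$from, nd$id); i2 <- match(ed$to, nd$id)
  elen <- sqrt((nd$x[i2] - nd$x[i1])^2 + (nd$y[i2] - nd$y[i1])^2)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$from), to = as.character(ed$to),
               weight = elen),
    directed = FALSE,
    vertices = data.frame(name = as.character(nd$id)))
  D <- igraph::distances(g)
  targets <- list(goal = as.character(maze$goal),
                  departure = as.character(maze$departures))

  n <- length(x)
  zone <- rep("none", n)
  # snap each position to the globally nearest edge point, then geodesic
  # distance = along-edge distance to an endpoint + graph distance
  path_dist <- function(tg) {
    nE <- nrow(ed)
    snap <- matrix(Inf, n, nE)
    tot <- matrix(Inf, n, nE)
    for (e in seq_len(nE)) {
      x1 <- nd$x[i1[e]]; y1 <- nd$y[i1[e]]
      x2 <- nd$x[i2[e]]; y2 <- nd$y[i2[e]]
      dx <- x2 - x1; dy <- y2 - y1
      L2 <- dx^2 + dy^2
      t <- if (L2 == 0) rep(0, n) else
        pmin(pmax(((x - x1) * dx + (y - y1) * dy) / L2, 0), 1)
      snap[, e] <- sqrt((x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2)
      d1 <- min(D[as.character(ed$from[e]), tg])
      d2 <- min(D[as.character(ed$to[e]), tg])
      tot[, e] <- pmin(t * sqrt(L2) + d1, (1 - t) * sqrt(L2) + d2)
    }
    sel <- max.col(-snap, ties.method = "first")
    tot[cbind(seq_len(n), sel)]
  }
  d_goal <- path_dist(targets$goal)
  d_dep <- path_dist(targets$departure)
  d_bar <- rep(Inf, n)
  for (b in maze$barriers)
    d_bar <- pmin(d_bar, point_segment_distance(x, y, b[1], b[2], b[3],
                                                b[4]))
  zone[d_bar <= eucl_tol] <- "barrier"
  zone[d_dep <= path_tol] <- "departure"
  zone[d_goal <= path_tol] <- "goal"
  zone
}

#' Per-cycle amplitude of predefined gamma bands (Butterworth control)
#'
#' Zero-phase 2nd-order Butterworth band-pass of the raw LFP (slow
#' gamma 22-55 Hz, mid gamma 60-100 Hz by default), Hilbert amplitude,
#' averaged within each cycle's trough-to-trough bounds; a linear-filter
#' control feeding the same stage/zone machinery as the tSC strengths.
#'
#' @param raw raw LFP vector.
#' @param cycles cycle table.
#' @param fs sampling rate, Hz.
#' @param bands named list of band bounds, Hz.
#' @param order Butterworth prototype order.
#' @return matrix cycles x bands of mean amplitudes.
#' @export
band_amplitude_control <- function(raw, cycles, fs,
                                   bands = list(slow_gamma = c(22, 55),
                                                mid_gamma = c(60, 100)),
                                   order = 2L) {
  out <- matrix(NA_real_, nrow(cycles), length(bands),
                dimnames = list(cycles$cycle_id, names(bands)))
  for (b in seq_along(bands)) {
    bf <- butter_design(order, bands[[b]], fs, "pass")
    amp <- Mod(analytic_signal(filtfilt_iir(bf$b, bf$a, raw)))
    for (j in seq_len(nrow(cycles)))
      out[j, b] <- mean(amp[cycles$trough_start[j]:
                              (cycles$trough_end[j] - 1L)])
  }
  out
}
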