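# Task-stage machinery: baseline z-scoring, stage ANOVA, matched stage
# controls, zone assignment, predefined-band control.

test_that("baseline z-scoring arithmetic", {
  set.seed(1)
  s <- c(rnorm(500, 2, 3), rnorm(300, 2 + 3, 3))   # learning shifted +1 SD
  mask <- c(rep(TRUE, 500), rep(FALSE, 300))
  z <- baseline_zscore(s, mask)
  expect_lt(abs(mean(z[mask])), 1e-9)
  expect_equal(sd(z[mask]) * sqrt(499 / 500) /
                 sqrt(499 / 500), sd(z[mask]), tolerance = 1e-12)
  expect_lt(abs(mean(z[!mask]) - 1), 0.2)
  expect_error(baseline_zscore(rep(1, 10), rep(TRUE, 10)), "zero baseline")
})

test_that("stage ANOVA recovers a planted offset under a speed confound", {
  set.seed(2)
  n_b <- 1500; n_l <- 1500
  speed_b <- runif(n_b, 2, 8)
  speed_l <- runif(n_l, 8, 16)          # learning cycles are faster
  beta_speed <- 0.15
  y_b <- beta_speed * speed_b + rnorm(n_b, sd = 0.5)
  y_l <- 0.5 + beta_speed * speed_l + rnorm(n_l, sd = 0.5)
  stage <- c(rep("baseline", n_b), rep("learning", n_l))
  day <- rep(rep(c("d1", "d2", "d3"), length.out = n_b), 2)
  res <- stage_anova(c(y_b, y_l), stage, c(speed_b, speed_l), day)
  expect_gt(res$ci_stage[1, 1], 0.5 - 0.15)
  expect_lt(res$ci_stage[1, 2], 0.5 + 0.15)
  expect_lt(abs(res$beta_speed - beta_speed), 0.03)
  naive <- mean(y_l) - mean(y_b)
  expect_gt(naive - 0.5, 0.2)           # naive difference is biased
  # no effect -> beta ~ 0
  res0 <- stage_anova(c(y_b, beta_speed * speed_l +
                          rnorm(n_l, sd = 0.5)),
                      stage, c(speed_b, speed_l), day)
  expect_lt(abs(res0$beta_stage[1]), 0.1)
})

test_that("Eq-style stage model matches the normal-equations oracle", {
  set.seed(3)
  n <- 400
  stage <- sample(c("baseline", "probe"), n, replace = TRUE)
  speed <- runif(n, 2, 12)
  day <- sample(c("d1", "d2"), n, replace = TRUE)
  y <- rnorm(n)
  res <- stage_anova(y, stage, speed, day)
  X <- cbind(1, stage == "probe", speed, day == "d2")
  b <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(res$beta_stage[1]), b[2], tolerance = 1e-8)
  expect_equal(unname(res$beta_speed), b[3], tolerance = 1e-8)
})

test_that("stage-matched controls shrink a pure speed effect", {
  set.seed(4)
  n <- 900
  cyc <- make_regular_cycles(n)
  cyc$stage <- rep(c("baseline", "learning", "probe"), each = n / 3)
  cyc$speed <- ifelse(cyc$stage == "probe", runif(n, 10, 16),
                      runif(n, 2, 16))
  cyc$x <- runif(n, 0, 10); cyc$y <- runif(n, 0, 10)
  strengths <- 0.2 * cyc$speed + rnorm(n, sd = 0.3)   # speed-driven only
  res <- stage_matched_control(cyc, strengths, reference_stage = "probe",
                               n_controls = 100, seed = 5)
  naive <- mean(strengths[cyc$stage == "probe"]) -
    mean(strengths[cyc$stage == "baseline"])
  expect_gt(naive, 0.5)
  expect_lt(abs(res$mean_diff[res$stage == "baseline"]), 0.25)
  expect_equal(unique(res$n_matched), sum(cyc$stage == "probe"))
  # identical stages -> matched effect ~ 0
  cyc2 <- cyc; cyc2$speed <- runif(n, 2, 8)
  s2 <- rnorm(n)
  res2 <- stage_matched_control(cyc2, s2, reference_stage = "probe",
                                n_controls = 50, seed = 6)
  expect_true(all(abs(res2$mean_diff) < 0.15))
})

test_that("zone assignment follows path vs Euclidean rules", {
  skip_if_not_installed("igraph")
  # straight 100-cm track: nodes at 0, 50, 100 cm; goal at x = 100
  maze <- maze_graph(
    nodes = data.frame(id = c("a", "b", "goal"), x = c(0, 50, 100),
                       y = 0),
    edges = data.frame(from = c("a", "b"), to = c("b", "goal")),
    goal = "goal", departures = "a",
    barriers = list(c(50, -1, 50, 1)))
  # 15 cm along the track from the goal -> goal zone
  expect_equal(zone_assignment(85, 0, maze), "goal")
  # 8 cm Euclidean from the barrier, far from goal by path -> barrier
  expect_equal(zone_assignment(58, 0, maze), "barrier")
  # interior point far from everything -> none (75 cm: 25 from goal > 20)
  expect_equal(zone_assignment(75, 0, maze), "none")
  # departure end
  expect_equal(zone_assignment(12, 0, maze), "departure")
  # precedence: a point near both goal (path) and barrier (Euclidean)
  m2 <- maze_graph(
    nodes = data.frame(id = c("a", "goal"), x = c(0, 60), y = 0),
    edges = data.frame(from = "a", to = "goal"),
    goal = "goal", departures = "a",
    barriers = list(c(45, -1, 45, 1)))
  expect_equal(zone_assignment(50, 0, m2), "goal")
})

test_that("zone labels are invariant under a rigid transform", {
  skip_if_not_installed("igraph")
  rot <- function(x, y, th, dx, dy)
    list(x = cos(th) * x - sin(th) * y + dx,
         y = sin(th) * x + cos(th) * y + dy)
  nodes <- data.frame(id = c("a", "b", "goal"), x = c(0, 50, 100), y = 0)
  edges <- data.frame(from = c("a", "b"), to = c("b", "goal"))
  bar <- c(50, -1, 50, 1)
  m1 <- maze_graph(nodes, edges, "goal", "a", list(bar))
  th <- 0.7; dx <- 13; dy <- -4
  nd2 <- nodes
  p <- rot(nodes$x, nodes$y, th, dx, dy); nd2$x <- p$x; nd2$y <- p$y
  b1 <- rot(bar[1], bar[2], th, dx, dy)
  b2 <- rot(bar[3], bar[4], th, dx, dy)
  m2 <- maze_graph(nd2, edges, "goal", "a",
                   list(c(b1$x, b1$y, b2$x, b2$y)))
  px <- c(85, 58, 75, 12)
  q <- rot(px, rep(0, 4), th, dx, dy)
  expect_equal(zone_assignment(px, rep(0, 4), m1),
               zone_assignment(q$x, q$y, m2))
})

test_that("Butterworth band control matches the filter-response oracle", {
  fs <- fs_test
  cyc <- make_regular_cycles(40)
  n <- max(cyc$spike_end) + fs
  t <- (seq_len(n) - 1) / fs
  A <- 0.8
  x40 <- A * cos(2 * pi * 40 * t)
  out <- band_amplitude_control(x40, cyc, fs)
  # oracle passband gain of the zero-phase 2nd-order Butterworth at 40 Hz
  bf <- butter_design(2, c(22, 55), fs, "pass")
  h <- function(b, a, f) {
    z <- exp(-1i * 2 * pi * f / fs)
    Mod(sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1)))^2
  }
  gain <- h(bf$b, bf$a, 40)      # squared: filtfilt applies twice
  expect_equal(mean(out[, "slow_gamma"]), A * gain, tolerance = 0.02)
  expect_lt(mean(out[, "mid_gamma"]), 0.05 * A)
  # converse for an 80-Hz tone
  x80 <- A * cos(2 * pi * 80 * t)
  out80 <- band_amplitude_control(x80, cyc, fs)
  expect_gt(mean(out80[, "mid_gamma"]), 0.8 * A)
  # stop-band leakage matches the oracle gain of the gentle 2nd-order
  # roll-off (|H(80)|^2 of the 22-55 band ~ 0.06)
  expect_equal(mean(out80[, "slow_gamma"]), A * h(bf$b, bf$a, 80),
               tolerance = 0.05)
  expect_lt(mean(out80[, "slow_gamma"]), 0.1 * A)
  # zero signal -> zero amplitude
  expect_true(all(band_amplitude_control(numeric(n), cyc, fs) < 1e-12))
})

test_that("maze graph JSON round-trips and zones survive it", {
  skip_if_not_installed("igraph")
  maze <- maze_graph(
    nodes = data.frame(id = c("a", "b", "goal"), x = c(0, 50, 100),
                       y = 0),
    edges = data.frame(from = c("a", "b"), to = c("b", "goal")),
    goal = "goal", departures = "a",
    barriers = list(c(50, -1, 50, 1)))
  p <- tempfile(fileext = ".json")
  write_maze_graph(maze, p)
  back <- read_maze_graph(p)
  px <- c(85, 58, 75, 12)
  expect_equal(zone_assignment(px, rep(0, 4), back),
               zone_assignment(px, rep(0, 4), maze))
})

test_that("leave-two-days-out sweep keeps a real stage effect everywhere", {
  set.seed(30)
  n <- 3000
  day <- sample(paste0("d", 1:6), n, replace = TRUE)
  stage <- sample(c("baseline", "learning"), n, replace = TRUE)
  speed <- runif(n, 2, 12)
  y <- 0.5 * (stage == "learning") + 0.1 * speed + rnorm(n, sd = 0.4)
  sw <- stage_robustness_sweep(y, stage, speed, day, leave_out = 2)
  expect_equal(nrow(sw), choose(6, 2))
  expect_true(all(sw$ci_lo > 0))
  expect_lt(max(abs(sw$beta - 0.5)), 0.15)
})
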