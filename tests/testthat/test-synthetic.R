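test_that("center-out targets sit at equal angular spacing", {
  kin <- generate_center_out_kinematics(n_trials = 40, n_targets = 8,
                                        seed = 2)
  # target of each trial = hand position furthest from home
  angles <- vapply(seq_len(nrow(kin$trials)), function(i) {
    rows <- kin$hand$t >= kin$trials$start_s[i] &
      kin$hand$t <= kin$trials$end_s[i]
    seg <- kin$hand[rows, ]
    far <- which.max(seg$x^2 + seg$y^2)
    atan2(seg$y[far], seg$x[far])
  }, numeric(1))
  deg <- round(((angles %% (2 * pi)) * 180 / pi)) %% 360
  expect_true(all(deg %in% seq(0, 315, by = 45)))
  expect_setequal(unique(deg), seq(0, 315, by = 45))
})

test_that("reach profile is minimum-jerk: analytic peak speed, zero at ends", {
  dt <- 0.002
  kin <- generate_center_out_kinematics(n_trials = 4, reach_time_s = 0.6,
                                        radius_cm = 8, dt_s = dt, seed = 1)
  v <- sqrt(diff(kin$hand$x)^2 + diff(kin$hand$y)^2) / dt
  expect_equal(max(v), 1.875 * 8 / 0.6, tolerance = 1e-3)
  for (i in seq_len(nrow(kin$trials))) {
    i0 <- which.min(abs(kin$hand$t - kin$trials$start_s[i]))
    i1 <- which.min(abs(kin$hand$t - kin$trials$end_s[i]))
    # velocity at trial boundaries vanishes (finite difference is O(dt^2))
    expect_lt(abs(kin$hand$x[min(i0 + 1, nrow(kin$hand))] - kin$hand$x[i0]) / dt, 0.01)
    expect_lt(abs(kin$hand$y[i1] - kin$hand$y[i1 - 1]) / dt, 0.01)
  }
  expect_error(generate_center_out_kinematics(4, dt_s = 0), "positive")
  expect_error(generate_center_out_kinematics(4, n_targets = 1), "2 targets")
})

test_that("sequential kinematics stay in the workspace and hit their targets", {
  kin <- generate_sequential_kinematics(n_trials = 15, workspace_cm = 10,
                                        seed = 4)
  expect_true(all(abs(kin$hand$x) <= 10 + 1e-9))
  expect_true(all(abs(kin$hand$y) <= 10 + 1e-9))
  kin2 <- generate_sequential_kinematics(n_trials = 15, workspace_cm = 10,
                                         seed = 4)
  expect_identical(kin, kin2)
  # each segment's displacement equals the distance between its endpoints,
  # and the trajectory is continuous across segments
  for (i in seq_len(nrow(kin$trials))) {
    rows <- which(kin$hand$t >= kin$trials$start_s[i] - 1e-12 &
                    kin$hand$t <= kin$trials$end_s[i] + 1e-12)
    p0 <- c(kin$hand$x[rows[1]], kin$hand$y[rows[1]])
    p1 <- c(kin$hand$x[rows[length(rows)]], kin$hand$y[rows[length(rows)]])
    path <- cbind(kin$hand$x[rows], kin$hand$y[rows])
    # minimum-jerk segments are straight lines: path length = displacement
    plen <- sum(sqrt(rowSums(diff(path)^2)))
    expect_equal(plen, sqrt(sum((p1 - p0)^2)), tolerance = 1e-6)
  }
})

test_that("constant-rate units produce Poisson-consistent spike counts", {
  hand <- data.frame(t = seq(0, 100, by = 0.01), x = 0, y = 0)
  pop <- generate_tuned_population(
    hand, n_units = 1, frac_nonlinear = 0,
    rate_params = list(baseline_hz = c(10, 10), depth_hz_per_cms = c(0, 0),
                       speed_gain = c(0, 0)),
    seed = 9)
  n_spk <- length(pop$units[[1]])
  expect_lt(abs(n_spk - 1000), 3 * sqrt(1000))
  # all-zero rate -> no spikes
  pop0 <- generate_tuned_population(
    hand, n_units = 2, frac_nonlinear = 0,
    rate_params = list(baseline_hz = c(0, 0), depth_hz_per_cms = c(0, 0),
                       speed_gain = c(0, 0)),
    seed = 9)
  expect_true(all(lengths(pop0$units) == 0))
  expect_error(generate_tuned_population(hand, 0), "at least 1")
})

test_that("binned counts of a constant-rate unit have Poisson dispersion", {
  hand <- data.frame(t = seq(0, 150, by = 0.01), x = 0, y = 0)
  pop <- generate_tuned_population(
    hand, n_units = 1, frac_nonlinear = 0,
    rate_params = list(baseline_hz = c(30, 30), depth_hz_per_cms = c(0, 0),
                       speed_gain = c(0, 0)),
    seed = 5)
  s <- new_session(pop$units, hand,
                   data.frame(start_s = 0, end_s = 150, label = "T1"))
  counts <- bin_spikes(s, 0.05)$counts[, 1]
  expect_gte(length(counts), 2000)
  disp <- stats::var(counts) / mean(counts)
  expect_gt(disp, 0.8)
  expect_lt(disp, 1.2)
})

test_that("tuning regression on long sessions recovers generating parameters", {
  # 500 s of sequential reaching, linear units only
  kin <- generate_sequential_kinematics(n_trials = ceiling(500 / 0.7),
                                        seed = 31)
  # parameter ranges keeping the drive strictly positive, so the rectifier
  # never engages and the generating model is exactly linear
  pop <- generate_tuned_population(
    kin$hand, n_units = 6, frac_nonlinear = 0,
    rate_params = list(baseline_hz = c(15, 20), depth_hz_per_cms = c(0.2, 0.4),
                       speed_gain = c(0.2, 0.4)),
    seed = 31)
  s <- new_session(pop$units, kin$hand, kin$trials)
  bd <- preprocess_session(s, smooth_sd_s = 0)  # unsmoothed for recovery
  FR <- bd$Z^2  # undo the square-root transform
  for (k in seq_len(6)) {
    co <- stats::coef(stats::lm(FR[, k] ~ bd$X[, 1] + bd$X[, 2] + bd$X[, 3]))
    gt <- pop$ground_truth[k, ]
    truth <- c(gt$baseline_hz,
               gt$depth_hz_per_cms * cos(gt$pref_direction_rad),
               gt$depth_hz_per_cms * sin(gt$pref_direction_rad),
               gt$speed_gain)
    # relative error on the dominant coefficients
    expect_lt(max(abs(co - truth)) / max(abs(truth)), 0.15)
  }
})

test_that("session-level generation is seed-deterministic and config-checked", {
  a <- make_synthetic_session(synth_config(n_units = 8, n_trials = 6), seed = 77)
  b <- make_synthetic_session(synth_config(n_units = 8, n_trials = 6), seed = 77)
  expect_identical(unclass(a$session), unclass(b$session))
  expect_identical(a$ground_truth, b$ground_truth)
  expect_error(make_synthetic_session(list(task = "jump"), seed = 1),
               "invalid config")
  expect_error(make_synthetic_session(synth_config(n_units = 0), seed = 1),
               "invalid config")
})
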