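# Synthetic reaching sessions with known cosine-tuned ground truth.
#
# The simulator emulates the structure of public M1 reaching datasets:
# 50-ms-binnable spike trains from tens to low hundreds of units, cosine
# velocity tuning with Poisson spiking, and either center-out (8 targets on a
# circle) or sequential random-target kinematics. Every generated session
# carries its generating parameters so downstream stages have
# parameter-recovery tests.

# Minimum-jerk position profile on [0, 1]: s(u) = 10u^3 - 15u^4 + 6u^5.
# Peak speed of a point-to-point reach of length d over T is 1.875 * d / T.
min_jerk_s <- function(u) u^3 * (10 - 15 * u + 6 * u^2)

# One minimum-jerk segment from p0 to p1 over duration T, sampled at offsets
# ts in [0, T] relative to segment start. Returns an n x 2 matrix.
min_jerk_segment <- function(p0, p1, T, ts) {
  u <- pmin(pmax(ts / T, 0), 1)
  s <- min_jerk_s(u)
  cbind(p0[1] + (p1[1] - p0[1]) * s, p0[2] + (p1[2] - p0[2]) * s)
}

#' Center-out reaching kinematics
#'
#' Generates a hand-position series for repeated out-and-back minimum-jerk
#' reaches from the home position (0, 0) to targets equally spaced on a
#' circle (45 degree intervals for 8 targets). Each trial consists of one
#' outward leg and one return leg, each of duration `reach_time_s`, so hand
#' velocity is zero at both trial boundaries.
#'
#' @param n_trials number of trials; targets cycle in a pseudorandom order.
#' @param n_targets number of radial targets (>= 2), default 8.
#' @param reach_time_s duration of each leg (s), default 0.6.
#' @param radius_cm target distance from home (cm), default 8.
#' @param dt_s hand sampling period (s), default 0.01.
#' @param seed RNG seed controlling the target order.
#' @return list with `hand` (data.frame t, x, y) and `trials`
#'   (start_s, end_s, label = "T<k>").
#' @export
generate_center_out_kinematics <- function(n_trials, n_targets = 8,
                                           reach_time_s = 0.6, radius_cm = 8,
                                           dt_s = 0.01, seed = 1) {
  if (dt_s <= 0) stop("dt_s must be positive", call. = FALSE)
  if (n_targets < 2) stop("need at least 2 targets", call. = FALSE)
  angles <- 2 * pi * (seq_len(n_targets) - 1) / n_targets
  order_idx <- with_seed(derive_seed(seed, "targets"), {
    idx <- integer(0)
    while (length(idx) < n_trials) idx <- c(idx, sample.int(n_targets))
    idx[seq_len(n_trials)]
  })
  trial_T <- 2 * reach_time_s
  n_per_leg <- round(reach_time_s / dt_s)
  total_n <- 2 * n_per_leg * n_trials + 1
  t_grid <- (seq_len(total_n) - 1) * dt_s
  pos <- matrix(0, total_n, 2)
  trials <- data.frame(start_s = numeric(n_trials), end_s = numeric(n_trials),
                       label = character(n_trials), stringsAsFactors = FALSE)
  for (i in seq_len(n_trials)) {
    th <- angles[order_idx[i]]
    tgt <- radius_cm * c(cos(th), sin(th))
    t0 <- (i - 1) * trial_T
    out_rows <- which(t_grid >= t0 - 1e-12 & t_grid < t0 + reach_time_s - 1e-12)
    back_rows <- which(t_grid >= t0 + reach_time_s - 1e-12 &
                         t_grid <= t0 + trial_T + 1e-12)
    pos[out_rows, ] <- min_jerk_segment(c(0, 0), tgt, reach_time_s,
                                        t_grid[out_rows] - t0)
    pos[back_rows, ] <- min_jerk_segment(tgt, c(0, 0), reach_time_s,
                                         t_grid[back_rows] - t0 - reach_time_s)
    trials$start_s[i] <- t0
    trials$end_s[i] <- t0 + trial_T
    trials$label[i] <- paste0("T", order_idx[i])
  }
  list(hand = data.frame(t = t_grid, x = pos[, 1], y = pos[, 2]),
       trials = trials)
}

#' Sequential random-target kinematics
#'
#' Generates a continuous series of minimum-jerk reaches between targets drawn
#' uniformly from a square workspace, mimicking a sequential reaching task.
#' Each trial is one target-to-target segment, labelled `"sequence"`.
#'
#' @param n_trials number of reach segments.
#' @param workspace_cm half-width of the square workspace centred on (0, 0);
#'   default 10.
#' @param reach_time_s segment duration (s), default 0.7.
#' @param dt_s hand sampling period (s), default 0.01.
#' @param seed RNG seed controlling target positions.
#' @return list with `hand` and `trials` as in
#'   [generate_center_out_kinematics()].
#' @export
generate_sequential_kinematics <- function(n_trials, workspace_cm = 10,
                                           reach_time_s = 0.7, dt_s = 0.01,
                                           seed = 1) {
  if (dt_s <= 0) stop("dt_s must be positive", call. = FALSE)
  targets <- with_seed(derive_seed(seed, "seq-targets"), {
    matrix(runif(2 * (n_trials + 1), -workspace_cm, workspace_cm),
           ncol = 2)
  })
  targets[1, ] <- c(0, 0)  # start at workspace centre
  n_per_seg <- round(reach_time_s / dt_s)
  total_n <- n_per_seg * n_trials + 1
  t_grid <- (seq_len(total_n) - 1) * dt_s
  pos <- matrix(0, total_n, 2)
  trials <- data.frame(start_s = numeric(n_trials), end_s = numeric(n_trials),
                       label = rep("sequence", n_trials),
                       stringsAsFactors = FALSE)
  for (i in seq_len(n_trials)) {
    t0 <- (i - 1) * reach_time_s
    rows <- which(t_grid >= t0 - 1e-12 & t_grid <= t0 + reach_time_s + 1e-12)
    pos[rows, ] <- min_jerk_segment(targets[i, ], targets[i + 1, ],
                                    reach_time_s, t_grid[rows] - t0)
    trials$start_s[i] <- t0
    trials$end_s[i] <- t0 + reach_time_s
  }
  list(hand = data.frame(t = t_grid, x = pos[, 1], y = pos[, 2]),
       trials = trials)
}

# Instantaneous firing rate (Hz) of one unit under the cosine tuning model,
# given velocity samples. Nonlinear units pass the rectified drive through a
# saturating tanh so their rate flattens at high drive.
unit_rate <- function(vx, vy, speed, p) {
  lam <- p$baseline_hz + p$depth_hz_per_cms * (vx * cos(p$pref_direction_rad) +
           vy * sin(p$pref_direction_rad)) + p$speed_gain * speed
  lam <- pmax(lam, 0)
  if (isTRUE(p$nonlinear)) {
    sat <- p$sat_hz
    lam <- sat * tanh(lam / sat)
  }
  lam
}

#' Simulate a cosine-tuned spiking population
#'
#' Draws per-unit tuning parameters and generates spike trains from an
#' inhomogeneous Poisson process by thinning: candidate events are drawn at
#' each unit's peak rate and accepted with probability rate(t)/peak. Each
#' unit's rate is `max(0, b + d * (vx cos(phi) + vy sin(phi)) + g * |v|)`;
#' a fraction of units additionally saturate (tanh squashing), giving
#' nonlinear tuning that a linear model cannot fully capture.
#'
#' @param hand data.frame `t`, `x`, `y` of hand positions on a uniform grid.
#' @param n_units number of units to simulate.
#' @param frac_nonlinear fraction of units with saturating rates, default 0.3.
#' @param rate_params list overriding tuning-parameter ranges: `baseline_hz`
#'   (range, default c(2, 12)), `depth_hz_per_cms` (default c(0.4, 1.2)),
#'   `speed_gain` (default c(0.05, 0.4)), `sat_hz` (saturation ceiling,
#'   default 25), `frac_untuned` (units with zero depth and speed gain,
#'   default 0).
#' @param seed RNG seed for tuning parameters and spikes.
#' @return list with `units` (spike-time vectors) and `ground_truth`
#'   (data.frame of per-unit baseline_hz, pref_direction_rad,
#'   depth_hz_per_cms, speed_gain, nonlinear).
#' @export
generate_tuned_population <- function(hand, n_units, frac_nonlinear = 0.3,
                                      rate_params = list(), seed = 1) {
  if (n_units < 1) stop("n_units must be at least 1", call. = FALSE)
  rp <- utils::modifyList(list(baseline_hz = c(2, 12),
                               depth_hz_per_cms = c(0.4, 1.2),
                               speed_gain = c(0.05, 0.4),
                               sat_hz = 25, frac_untuned = 0), rate_params)
  dt <- diff(hand$t[1:2])
  vx <- c(diff(hand$x), 0) / dt
  vy <- c(diff(hand$y), 0) / dt
  speed <- sqrt(vx^2 + vy^2)
  dur <- max(hand$t)
  gt <- with_seed(derive_seed(seed, "tuning"), {
    n_nl <- round(frac_nonlinear * n_units)
    n_un <- round(rp$frac_untuned * n_units)
    data.frame(
      baseline_hz = runif(n_units, rp$baseline_hz[1], rp$baseline_hz[2]),
      pref_direction_rad = runif(n_units, 0, 2 * pi),
      depth_hz_per_cms = runif(n_units, rp$depth_hz_per_cms[1],
                               rp$depth_hz_per_cms[2]),
      speed_gain = runif(n_units, rp$speed_gain[1], rp$speed_gain[2]),
      nonlinear = seq_len(n_units) %in% sample.int(n_units, n_nl),
      untuned = seq_len(n_units) %in% sample.int(n_units, n_un)
    )
  })
  gt$depth_hz_per_cms[gt$untuned] <- 0
  gt$speed_gain[gt$untuned] <- 0
  gt$sat_hz <- rp$sat_hz
  units <- with_seed(derive_seed(seed, "spikes"), {
    lapply(seq_len(n_units), function(k) {
      p <- as.list(gt[k, ])
      lam <- unit_rate(vx, vy, speed, p)
      lam_max <- max(lam)
      if (lam_max <= 0) return(numeric(0))
      n_cand <- rpois(1, lam_max * dur)
      if (n_cand == 0) return(numeric(0))
      tt <- sort(runif(n_cand, 0, dur))
      lam_at <- stats::approx(hand$t, lam, xout = tt, rule = 2)$y
      tt[runif(n_cand) < lam_at / lam_max]
    })
  })
  list(units = units, ground_truth = gt)
}

#' Configuration for a synthetic session
#'
#' @param task `"center_out"` or `"sequential"`.
#' @param n_units population size, default 60.
#' @param n_trials number of trials, default 100.
#' @param frac_nonlinear fraction of saturating units, default 0.3.
#' @param rate_params see [generate_tuned_population()].
#' @param n_targets,reach_time_s,radius_cm,workspace_cm,dt_s task geometry;
#'   see the kinematics generators.
#' @return a named list understood by [make_synthetic_session()].
#' @export
synth_config <- function(task = c("center_out", "sequential"), n_units = 60,
                         n_trials = 100, frac_nonlinear = 0.3,
                         rate_params = list(), n_targets = 8,
                         reach_time_s = 0.6, radius_cm = 8, workspace_cm = 10,
                         dt_s = 0.01) {
  list(task = match.arg(task), n_units = n_units, n_trials = n_trials,
       frac_nonlinear = frac_nonlinear, rate_params = rate_params,
       n_targets = n_targets, reach_time_s = reach_time_s,
       radius_cm = radius_cm, workspace_cm = workspace_cm, dt_s = dt_s)
}

#' Benchmark conditions for the nonlinear-population decoding comparison
#'
#' A center-out session whose tuned units all saturate strongly (tanh ceiling
#' 10 Hz against drives of tens of Hz), giving the population a deeply
#' nonlinear velocity code. These are the conditions under which the
#' representation comparison (deep vs linear canonical variables vs raw
#' rates) is run: with a predominantly linear population code the three
#' representations are statistically indistinguishable, so the benchmark
#' stresses the regime the nonlinear method is designed for.
#'
#' @param n_trials number of center-out trials, default 200.
#' @param n_units population size, default 30.
#' @return a [synth_config()] list.
#' @export
nonlinear_benchmark_config <- function(n_trials = 200, n_units = 30) {
  synth_config(n_units = n_units, n_trials = n_trials, frac_nonlinear = 1,
               rate_params = list(sat_hz = 10, depth_hz_per_cms = c(1.5, 2.5),
                                  baseline_hz = c(2, 8)))
}

#' Generate a complete synthetic session
#'
#' Combines task kinematics and a tuned Poisson population into a validated
#' [new_session()] container plus its generating ground truth. One seed
#' governs targets, tuning parameters and spikes, and is recorded in the
#' session metadata.
#'
#' @param config a list from [synth_config()].
#' @param seed master RNG seed.
#' @return list with `session` (a `canokin_session`) and `ground_truth`.
#' @export
make_synthetic_session <- function(config = synth_config(), seed = 1) {
  if (is.null(config$task) || !config$task %in% c("center_out", "sequential"))
    stop("invalid config: task must be center_out or sequential", call. = FALSE)
  if (is.null(config$n_units) || config$n_units < 1)
    stop("invalid config: n_units", call. = FALSE)
  kin <- if (config$task == "center_out") {
    generate_center_out_kinematics(config$n_trials, config$n_targets,
                                   config$reach_time_s, config$radius_cm,
                                   config$dt_s, seed = seed)
  } else {
    generate_sequential_kinematics(config$n_trials, config$workspace_cm,
                                   config$reach_time_s, config$dt_s,
                                   seed = seed)
  }
  pop <- generate_tuned_population(kin$hand, config$n_units,
                                   config$frac_nonlinear, config$rate_params,
                                   seed = seed)
  s <- new_session(pop$units, kin$hand, kin$trials,
                   id = sprintf("synthetic-%s-seed%d", config$task, seed))
  s$meta$seed <- seed
  s$meta$task <- config$task
  list(session = s, ground_truth = pop$ground_truth)
}
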